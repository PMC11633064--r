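# Successive stage training: AdamW with decoupled weight decay, warm-up +
# cosine-annealed learning rate, balanced patch sampling, validation-loss
# model selection. Earlier stages are frozen (evaluation mode, no gradient)
# while a later stage trains.

#' Training configuration
#'
#' @param stage_id 1, 2 or 3.
#' @param max_epochs maximum number of epochs.
#' @param learning_rate base learning rate; defaults to 0.005 for stage 1
#'   and 0.002 for stages 2 and 3.
#' @param weight_decay AdamW decoupled weight decay.
#' @param batch_size patches per mini-batch.
#' @param warmup_epochs linear warm-up length; defaults to 5 percent of
#'   `max_epochs`.
#' @param patches_per_epoch random patches drawn per epoch (an epoch is not
#'   an exhaustive tiling).
#' @param patch_size cubic patch edge length; must be divisible by
#'   `2^(levels - 1)`.
#' @param levels,width,hidden architecture descriptor of the stage networks.
#' @param val_patches size of the fixed validation patch set.
#' @param seed master seed for initialization and sampling.
#' @return a `train_config` list.
#' @export
train_config <- function(stage_id, max_epochs = 500L, learning_rate = NULL,
                         weight_decay = 0.01, batch_size = 4L,
                         warmup_epochs = NULL, patches_per_epoch = 256L,
                         patch_size = 64L, levels = 4L, width = 16L,
                         hidden = 64L, val_patches = 32L, seed = 1L) {
  if (is.null(learning_rate)) {
    learning_rate <- if (stage_id == 1) 0.005 else 0.002
  }
  if (is.null(warmup_epochs)) warmup_epochs <- ceiling(0.05 * max_epochs)
  cfg <- list(stage_id = as.integer(stage_id),
              max_epochs = as.integer(max_epochs),
              learning_rate = learning_rate, weight_decay = weight_decay,
              batch_size = as.integer(batch_size),
              warmup_epochs = as.integer(warmup_epochs),
              patches_per_epoch = as.integer(patches_per_epoch),
              patch_size = as.integer(patch_size),
              levels = as.integer(levels), width = as.integer(width),
              hidden = as.integer(hidden),
              val_patches = as.integer(val_patches), seed = as.integer(seed))
  stopifnot(cfg$learning_rate > 0, cfg$batch_size >= 1,
            cfg$warmup_epochs < cfg$max_epochs,
            cfg$patch_size %% 2^(cfg$levels - 1) == 0)
  structure(cfg, class = "train_config")
}

#' Warm-up + cosine-annealing learning-rate schedule
#'
#' Linear ramp from 0 to the base rate over `warmup_epochs`, then
#' `base * 0.5 * (1 + cos(pi * (epoch - w) / (max_epochs - w)))`. Epochs are
#' 0-based; the schedule is continuous at the warm-up/annealing junction.
#'
#' @param epoch 0-based epoch index, `0 <= epoch < max_epochs`.
#' @param config a [train_config()].
#' @return the learning rate for that epoch.
#' @export
lr_schedule <- function(epoch, config) {
  stopifnot(epoch >= 0, epoch < config$max_epochs)
  base <- config$learning_rate
  w <- config$warmup_epochs
  if (epoch < w) return(base * epoch / w)
  base * 0.5 * (1 + cos(pi * (epoch - w) / (config$max_epochs - w)))
}

.has_fracture <- function(scan) nrow(scan$records) > 0
.has_nondisplaced <- function(scan) any(scan$records$kind == "nondisplaced")

# binary mask of a scan's nondisplaced fracture voxels
.nondisplaced_mask <- function(scan) {
  ids <- scan$records$index[scan$records$kind == "nondisplaced"]
  arr <- array(as.numeric(scan$fracture$data %in% ids &
                            scan$fracture$data > 0), dim(scan$fracture$data))
  mf_mask(arr, scan$fracture$spacing)
}

.any_fracture_prob <- function(scan) {
  mf_prob(array(as.numeric(scan$fracture$data > 0), dim(scan$fracture$data)),
          scan$fracture$spacing)
}

## ---- per-stage mini-batch builders ----

# Stage 1: half the patches centred on a random mandible voxel with jitter,
# half uniform, so empty background does not dominate.
.stage1_batch <- function(scans, n, ps) {
  xs <- vector("list", n); tm <- vector("list", n)
  tpos <- matrix(0, 3, n)
  for (i in seq_len(n)) {
    sc <- scans[[sample.int(length(scans), 1)]]
    shape <- dim(sc$volume$data)
    if (runif(1) < 0.5) {
      fg <- which(sc$mandible$data > 0)
      v <- fg[sample.int(length(fg), 1)]
      centre <- as.integer(arrayInd(v, shape)) - 1L
      o <- .jittered_origin(centre, ps, shape, ps %/% 4L)
    } else {
      o <- as.integer(floor(runif(3) * pmax(shape - ps + 1L, 1L)))
    }
    xs[[i]] <- gap_channels(extract_patch(sc$volume, o, ps))
    tm[[i]] <- extract_patch(sc$mandible, o, ps)
    tpos[, i] <- relative_position(o, ps, shape)
  }
  list(x = .stack_patches(xs), tmask = .stack_patches(tm), tpos = tpos)
}

# Build the stage-2 context tensor from intensity patches and a frozen
# stage-1 forward pass.
.stage2_context <- function(s1, patches) {
  gp <- lapply(patches, gap_channels)
  s1o <- stage1_forward(s1, gp, training = FALSE)
  x1 <- .stack_patches(patches)
  list(ctx = .cat_ch(.cat_ch(x1, s1o$feat), s1o$logits), s1o = s1o)
}

.stage2_batch <- function(scans, soft_targets, n, ps, s1) {
  k <- sample.int(length(scans), 1)
  sc <- scans[[k]]
  pairs <- sample_balanced_patches(sc$volume, soft_targets[[k]], n, ps)
  patches <- lapply(pairs, `[[`, "patch")
  tgt <- .stack_patches(lapply(pairs, `[[`, "target"))
  c2 <- .stage2_context(s1, patches)
  list(ctx = c2$ctx, target = tgt, patches = patches)
}

.stage3_batch <- function(scans, any_fracs, n, ps, s1, s2) {
  k <- sample.int(length(scans), 1)
  sc <- scans[[k]]
  pairs <- sample_balanced_patches(sc$volume, any_fracs[[k]], n, ps)
  patches <- lapply(pairs, `[[`, "patch")
  labels <- vapply(pairs, function(p) as.numeric(sum(p$target$data) > 0),
                   numeric(1))
  c2 <- .stage2_context(s1, patches)
  s2o <- stage2_forward(s2, c2$ctx, patches, training = FALSE)
  ctx3 <- .cat_ch(c2$ctx, s2o$logits_b)
  list(ctx = ctx3, labels = labels)
}

## ---- per-stage loss + gradient steps ----

.stage1_step <- function(params, batch, training = TRUE) {
  u <- unet_fw(params$unet, batch$x, training)
  h <- head_fw(params$head, u$deep, training)
  pos <- sigmoid(h$out)
  probs <- sigmoid(u$logits)
  loss <- bce_loss(probs, batch$tmask) + smooth_l1_loss(pos, batch$tpos)
  if (!training) return(list(loss = loss))
  glog <- array((probs - batch$tmask) / length(batch$tmask), dim(u$logits))
  gpos <- matrix(.smooth_l1_grad(pos, batch$tpos), 3) * pos * (1 - pos)
  hb <- head_bw(params$head, h$cache, gpos)
  ub <- unet_bw(params$unet, u$cache, glog, g_deep = hb$g_deep)
  list(loss = loss, grads = list(unet = ub$grads, head = hb$grads))
}

.stage2_step <- function(params, batch, training = TRUE) {
  fa <- unet_fw(params$unet_a, batch$ctx, training)
  ctxb <- .cat_ch(batch$ctx, fa$logits)
  fb <- unet_fw(params$unet_b, ctxb, training)
  pa <- sigmoid(fa$logits)
  pb <- sigmoid(fb$logits)
  loss <- bce_loss(pa, batch$target) + bce_loss(pb, batch$target)
  if (!training) return(list(loss = loss))
  gb <- array((pb - batch$target) / length(batch$target), dim(fb$logits))
  bb <- unet_bw(params$unet_b, fb$cache, gb)
  nc <- dim(batch$ctx)[4]
  g_loga <- bb$gx[, , , nc + 1, , drop = FALSE] +
    (pa - batch$target) / length(batch$target)
  ab <- unet_bw(params$unet_a, fa$cache, array(g_loga, dim(fa$logits)))
  list(loss = loss, grads = list(unet_a = ab$grads, unet_b = bb$grads))
}

.stage3_step <- function(params, batch, training = TRUE) {
  e <- .enc_fw(params$enc, batch$ctx, training)
  h <- head_fw(params$head, e$deep, training)
  p <- sigmoid(h$out)
  loss <- bce_loss(p, batch$labels)
  if (!training) return(list(loss = loss))
  gout <- matrix((p - batch$labels) / length(batch$labels), 1)
  hb <- head_bw(params$head, h$cache, gout)
  gsk <- vector("list", length(params$enc))
  gsk[[length(gsk)]] <- hb$g_deep
  eb <- .enc_bw(params$enc, e$caches, gsk)
  list(loss = loss, grads = list(enc = eb$grads, head = hb$grads))
}

#' Train one stage
#'
#' Stage 1 trains on scans with complete (nonfractured) mandibles; stages 2
#' and 3 train on scans with fractures, with class balance enforced by
#' [sample_balanced_patches()]. Earlier stages are run frozen in evaluation
#' mode. The returned model carries the parameters of the epoch with the
#' lowest validation loss.
#'
#' @param stage_id 1, 2 or 3.
#' @param data list with `train` and `val`: lists of scans as produced by
#'   [phantom_dataset()] (fields `volume`, `mandible`, `fracture`,
#'   `records`).
#' @param config a [train_config()].
#' @param prior_stages list of already-trained earlier stages (`s1` for
#'   stage 2; `s1` and `s2` for stage 3).
#' @return list with `model`, `history` (one row per epoch: learning rate,
#'   training and validation loss), `best_epoch`.
#' @export
train_stage <- function(stage_id, data, config, prior_stages = NULL) {
  stopifnot(inherits(config, "train_config"), stage_id == config$stage_id)
  if (stage_id > 1 && is.null(prior_stages$s1)) {
    stop("stage ", stage_id, " requires a trained stage 1")
  }
  if (stage_id > 2 && is.null(prior_stages$s2)) {
    stop("stage 3 requires a trained stage 2")
  }
  ps <- config$patch_size
  pick <- function(scans) {
    if (stage_id == 1) Filter(Negate(.has_fracture), scans)
    else if (stage_id == 2) Filter(.has_nondisplaced, scans)
    else Filter(.has_fracture, scans)
  }
  tr <- pick(data$train)
  va <- pick(data$val)
  if (length(tr) == 0) stop("no eligible training scans for stage ", stage_id)
  if (length(va) == 0) {
    warning("no eligible validation scans for stage ", stage_id,
            "; validating on training scans")
    va <- tr
  }

  set.seed(config$seed + 1000L * stage_id)
  feat_ch <- if (stage_id > 1) prior_stages$s1$descriptor$feat_ch else NULL
  model <- switch(stage_id,
    stage1_init(config$levels, config$width, config$hidden),
    stage2_init(feat_ch, config$levels, config$width),
    stage3_init(feat_ch, config$levels, config$width, config$hidden))

  soft_tr <- soft_va <- any_tr <- any_va <- NULL
  if (stage_id == 2) {
    soft_tr <- lapply(tr, function(s) soften_fracture_target(.nondisplaced_mask(s)))
    soft_va <- lapply(va, function(s) soften_fracture_target(.nondisplaced_mask(s)))
  }
  if (stage_id == 3) {
    any_tr <- lapply(tr, .any_fracture_prob)
    any_va <- lapply(va, .any_fracture_prob)
  }

  make_batch <- function(scans, soft, anyf, n) {
    switch(stage_id,
      .stage1_batch(scans, n, ps),
      .stage2_batch(scans, soft, n, ps, prior_stages$s1),
      .stage3_batch(scans, anyf, n, ps, prior_stages$s1, prior_stages$s2))
  }
  step <- switch(stage_id, .stage1_step, .stage2_step, .stage3_step)

  # fixed validation batches
  set.seed(config$seed + 1000L * stage_id + 1L)
  n_val_batches <- max(1L, config$val_patches %/% config$batch_size)
  val_batches <- lapply(seq_len(n_val_batches), function(i) {
    make_batch(va, soft_va, any_va, config$batch_size)
  })

  params <- unclass(model)
  params$descriptor <- NULL
  opt <- adamw_state()
  history <- data.frame(epoch = integer(0), lr = numeric(0),
                        train_loss = numeric(0), val_loss = numeric(0))
  best <- list(loss = Inf, params = params, epoch = NA_integer_)
  n_batches <- max(1L, config$patches_per_epoch %/% config$batch_size)

  set.seed(config$seed + 1000L * stage_id + 2L)
  for (epoch in seq_len(config$max_epochs) - 1L) {
    lr <- lr_schedule(epoch, config)
    tr_losses <- numeric(n_batches)
    for (b in seq_len(n_batches)) {
      batch <- make_batch(tr, soft_tr, any_tr, config$batch_size)
      st <- step(params, batch, training = TRUE)
      tr_losses[b] <- st$loss
      if (!is.finite(st$loss)) stop("non-finite training loss at epoch ", epoch)
      if (lr > 0) {
        upd <- adamw_step(params, st$grads, opt, lr, config$weight_decay)
        params <- upd$params
        opt <- upd$state
      } else {
        # warm-up epoch 0: still absorb batch-norm running statistics
        upd <- adamw_step(params, st$grads, opt, 0, 0)
        params <- upd$params
        opt <- upd$state
      }
    }
    val_losses <- vapply(val_batches, function(b) {
      step(params, b, training = FALSE)$loss
    }, numeric(1))
    vl <- mean(val_losses)
    if (!is.finite(vl)) stop("non-finite validation loss at epoch ", epoch)
    history <- rbind(history, data.frame(
      epoch = epoch, lr = lr, train_loss = mean(tr_losses), val_loss = vl))
    if (vl < best$loss) best <- list(loss = vl, params = params, epoch = epoch)
  }

  out <- best$params
  out$descriptor <- model$descriptor
  class(out) <- class(model)
  # keep list order consistent with the constructor
  out <- structure(out[c("descriptor", setdiff(names(out), "descriptor"))],
                   class = class(model))
  list(model = out, history = history, best_epoch = best$epoch)
}

#' Train all three stages successively
#'
#' Convenience wrapper running stages 1, 2, 3 in order with the given
#' per-stage configs, freezing each stage before the next trains.
#'
#' @param data list with `train` and `val` scan lists.
#' @param configs list of three [train_config()] objects.
#' @return list with `s1`, `s2`, `s3` (best models) and `histories`.
#' @export
train_all_stages <- function(data, configs) {
  r1 <- train_stage(1L, data, configs[[1]])
  r2 <- train_stage(2L, data, configs[[2]], prior_stages = list(s1 = r1$model))
  r3 <- train_stage(3L, data, configs[[3]],
                    prior_stages = list(s1 = r1$model, s2 = r2$model))
  list(s1 = r1$model, s2 = r2$model, s3 = r3$model,
       histories = list(r1$history, r2$history, r3$history),
       best_epochs = c(r1$best_epoch, r2$best_epoch, r3$best_epoch))
}
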