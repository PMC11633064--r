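# The three stage models as architecture contracts.
#
# Stage 1: U-shaped network with a shared encoder predicting a mandible
# segmentation per patch plus a GAP + 2-FC head regressing the patch's
# relative position. Stage 2: cascade of two U-shaped networks segmenting
# fracture lines from the patch intensities concatenated with stage-1
# decoder features and logits; the second network additionally receives the
# first network's logits. Stage 3: encoder + GAP + 2-FC classifier deciding
# whether the patch contains any fracture.
#
# Forward functions are S3 generics so that ground-truth oracle stand-ins
# (used to test the scan-level plumbing independently of training) can be
# dropped in anywhere a trained stage is expected.

.stack_patches <- function(patches) {
  d <- dim(patches[[1]]$data)  # (ps, ps, ps, C)
  x <- array(0, c(d, length(patches)))
  for (i in seq_along(patches)) x[, , , , i] <- patches[[i]]$data
  x
}

# slice a full-grid array at a patch's absolute origin, zero-padded
.gt_patch <- function(grid, patch) {
  ps <- dim(patch$data)[2]
  o <- patch$abs_origin
  sh <- dim(grid)
  out <- array(0, c(ps, ps, ps))
  ve <- pmin(ps, sh - o)
  if (any(ve <= 0)) return(out)
  out[seq_len(ve[1]), seq_len(ve[2]), seq_len(ve[3])] <-
    grid[o[1] + seq_len(ve[1]), o[2] + seq_len(ve[2]), o[3] + seq_len(ve[3])]
  out
}

#' Initialize a stage-1 model
#'
#' @param levels encoder depth (resolution levels).
#' @param width base channel width, doubled per level.
#' @param hidden hidden units of the position head.
#' @param seed optional seed for parameter initialization.
#' @return an `mf_stage1` model. Its decoder carries `width` feature
#'   channels to stages 2 and 3.
#' @export
stage1_init <- function(levels = 4L, width = 16L, hidden = 64L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- list(stage_id = 1L, in_ch = 4L, levels = as.integer(levels),
            width = as.integer(width), hidden = as.integer(hidden),
            feat_ch = as.integer(width))
  deep_ch <- width * 2^(levels - 1)
  structure(list(descriptor = d, unet = unet_init(d),
                 head = head_init(deep_ch, 3L, hidden)),
            class = "mf_stage1")
}

#' Initialize a stage-2 model (cascade of two U-shaped networks)
#'
#' Input channels: patch intensity + stage-1 decoder features + stage-1
#' mandible logits; the second network additionally receives the first
#' network's logits.
#'
#' @param feat_ch number of stage-1 decoder feature channels.
#' @inheritParams stage1_init
#' @return an `mf_stage2` model.
#' @export
stage2_init <- function(feat_ch = 16L, levels = 4L, width = 16L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  in_ch <- 2L + as.integer(feat_ch)
  d <- list(stage_id = 2L, in_ch = in_ch, levels = as.integer(levels),
            width = as.integer(width), feat_ch = as.integer(feat_ch))
  da <- list(in_ch = in_ch, levels = d$levels, width = d$width)
  db <- list(in_ch = in_ch + 1L, levels = d$levels, width = d$width)
  structure(list(descriptor = d, unet_a = unet_init(da), unet_b = unet_init(db)),
            class = "mf_stage2")
}

#' Initialize a stage-3 model (encoder + GAP + 2 FC classifier)
#'
#' Input channels: patch intensity + stage-1 decoder features + stage-1
#' mandible logits + stage-2 logits.
#'
#' @inheritParams stage2_init
#' @param hidden hidden units of the classifier head.
#' @return an `mf_stage3` model.
#' @export
stage3_init <- function(feat_ch = 16L, levels = 4L, width = 16L,
                        hidden = 64L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  in_ch <- 3L + as.integer(feat_ch)
  d <- list(stage_id = 3L, in_ch = in_ch, levels = as.integer(levels),
            width = as.integer(width), hidden = as.integer(hidden),
            feat_ch = as.integer(feat_ch))
  deep_ch <- width * 2^(levels - 1)
  structure(list(descriptor = d, enc = .enc_init(d),
                 head = head_init(deep_ch, 1L, hidden)),
            class = "mf_stage3")
}

#' Stage-1 forward pass
#'
#' @param model an `mf_stage1` model or a stage-1 oracle.
#' @param patches list of 4-channel `mf_patch` objects (see [gap_channels()]).
#' @param training logical; caches intermediates and uses batch statistics
#'   when `TRUE`.
#' @return list with `logits` (1 x patch^3 x N), `position` (3 x N, in
#'   `[0, 1]`), `feat` (decoder features), `deep` (deepest encoder
#'   features), and a training `cache`.
#' @export
stage1_forward <- function(model, patches, training = FALSE) {
  UseMethod("stage1_forward")
}

#' @export
stage1_forward.mf_stage1 <- function(model, patches, training = FALSE) {
  x <- .stack_patches(patches)
  if (dim(x)[4] != 4L) stop("stage 1 expects 4-channel patches")
  u <- unet_fw(model$unet, x, training)
  h <- head_fw(model$head, u$deep, training)
  list(logits = u$logits, position = sigmoid(h$out), feat = u$feat,
       deep = u$deep, cache = if (training) list(unet = u$cache, head = h$cache))
}

#' Stage-2 forward pass
#'
#' @param model an `mf_stage2` model or oracle.
#' @param ctx 5-d context tensor: patch intensity, stage-1 decoder features
#'   and stage-1 mandible logits, channel-wise concatenated.
#' @param patches the underlying intensity patches (used by oracles for
#'   their grid coordinates).
#' @inheritParams stage1_forward
#' @return list with `logits_a`, `logits_b` (the final fracture probability
#'   map is `sigmoid(logits_b)`), and a training `cache`.
#' @export
stage2_forward <- function(model, ctx, patches = NULL, training = FALSE) {
  UseMethod("stage2_forward")
}

#' @export
stage2_forward.mf_stage2 <- function(model, ctx, patches = NULL,
                                     training = FALSE) {
  if (dim(ctx)[4] != model$descriptor$in_ch) {
    stop("stage 2 context has ", dim(ctx)[4], " channels, expected ",
         model$descriptor$in_ch)
  }
  a <- unet_fw(model$unet_a, ctx, training)
  ctx_b <- .cat_ch(ctx, a$logits)
  b <- unet_fw(model$unet_b, ctx_b, training)
  list(logits_a = a$logits, logits_b = b$logits,
       cache = if (training) list(a = a$cache, b = b$cache, ctx = ctx))
}

#' Stage-3 forward pass
#'
#' @param model an `mf_stage3` model or oracle.
#' @param ctx 5-d context tensor: patch intensity, stage-1 decoder features,
#'   stage-1 mandible logits and stage-2 logits, channel-wise concatenated.
#' @inheritParams stage2_forward
#' @return list with `logits` (1 x N); the fracture probability is
#'   `sigmoid(logits)`.
#' @export
stage3_forward <- function(model, ctx, patches = NULL, training = FALSE) {
  UseMethod("stage3_forward")
}

#' @export
stage3_forward.mf_stage3 <- function(model, ctx, patches = NULL,
                                     training = FALSE) {
  if (dim(ctx)[4] != model$descriptor$in_ch) {
    stop("stage 3 context has ", dim(ctx)[4], " channels, expected ",
         model$descriptor$in_ch)
  }
  e <- .enc_fw(model$enc, ctx, training)
  h <- head_fw(model$head, e$deep, training)
  list(logits = h$out,
       cache = if (training) list(enc = e$caches, head = h$cache))
}

## ---- ground-truth oracle stand-ins ----

.ORACLE_LOGIT <- 12

#' Ground-truth oracle stand-ins for the three stages
#'
#' Build stage objects that replace the trained networks with the phantom
#' ground truth: the stage-1 oracle emits saturated mandible logits from the
#' ground-truth mask (and no feature channels), the stage-2 oracle emits the
#' ground-truth fracture mask as saturated logits, and the stage-3 oracle
#' classifies a patch as positive when it contains any ground-truth fracture
#' voxel. They exercise the scan-level tiling, fusion and proposal plumbing
#' independently of training.
#'
#' @param mandible_gt binary mandible [mf_mask()] over the full scan grid.
#' @param fracture_gt fracture [mf_mask()] over the full scan grid (any
#'   nonzero voxel is fracture).
#' @return objects usable wherever a trained stage is accepted.
#' @export
oracle_stage1 <- function(mandible_gt) {
  structure(list(descriptor = list(stage_id = 1L, feat_ch = 0L),
                 gt = .as_grid_array(mandible_gt) > 0,
                 shape = dim(.as_grid_array(mandible_gt))),
            class = "mf_stage1_oracle")
}

#' @rdname oracle_stage1
#' @export
oracle_stage2 <- function(fracture_gt) {
  structure(list(descriptor = list(stage_id = 2L),
                 gt = .as_grid_array(fracture_gt) > 0),
            class = "mf_stage2_oracle")
}

#' @rdname oracle_stage1
#' @export
oracle_stage3 <- function(fracture_gt) {
  structure(list(descriptor = list(stage_id = 3L),
                 gt = .as_grid_array(fracture_gt) > 0),
            class = "mf_stage3_oracle")
}

#' @export
stage1_forward.mf_stage1_oracle <- function(model, patches, training = FALSE) {
  ps <- dim(patches[[1]]$data)[1]
  N <- length(patches)
  logits <- array(0, c(ps, ps, ps, 1, N))
  pos <- matrix(0, 3, N)
  for (i in seq_len(N)) {
    g <- .gt_patch(model$gt, patches[[i]])
    logits[, , , 1, i] <- (2 * g - 1) * .ORACLE_LOGIT
    pos[, i] <- relative_position(patches[[i]]$abs_origin, ps, model$shape)
  }
  list(logits = logits, position = pos,
       feat = array(0, c(ps, ps, ps, 0, N)),
       deep = NULL, cache = NULL)
}

#' @export
stage2_forward.mf_stage2_oracle <- function(model, ctx, patches = NULL,
                                            training = FALSE) {
  ps <- dim(patches[[1]]$data)[1]
  N <- length(patches)
  logits <- array(0, c(ps, ps, ps, 1, N))
  for (i in seq_len(N)) {
    g <- .gt_patch(model$gt, patches[[i]])
    logits[, , , 1, i] <- (2 * g - 1) * .ORACLE_LOGIT
  }
  list(logits_a = logits, logits_b = logits, cache = NULL)
}

#' @export
stage3_forward.mf_stage3_oracle <- function(model, ctx, patches = NULL,
                                            training = FALSE) {
  N <- length(patches)
  out <- matrix(0, 1, N)
  for (i in seq_len(N)) {
    g <- .gt_patch(model$gt, patches[[i]])
    out[1, i] <- if (any(g > 0)) .ORACLE_LOGIT else -.ORACLE_LOGIT
  }
  list(logits = out, cache = NULL)
}

## ---- checkpoints ----

#' Save / load a stage checkpoint
#'
#' A checkpoint is a single file per stage embedding the architecture
#' descriptor. `load_checkpoint()` refuses a checkpoint whose descriptor
#' differs from the expected one.
#'
#' @param model a stage model.
#' @param path checkpoint file path.
#' @param descriptor optional descriptor the checkpoint must match.
#' @return `load_checkpoint()` returns the model.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path, descriptor = NULL) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  model <- readRDS(path)
  if (!is.null(descriptor) && !identical(model$descriptor, descriptor)) {
    stop("checkpoint descriptor does not match the constructed model")
  }
  model
}
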