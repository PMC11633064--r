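# Compact 3D CNN stack: conv blocks (3x3x3 conv + batch norm + leaky ReLU),
# 2x2x2 max pooling, transposed-conv upsampling, U-shaped networks, an
# encoder-only variant, and GAP + two-fully-connected heads. Forward passes
# cache what the hand-written backward passes need; tensors are arrays with
# dim = c(X, Y, Z, C, N) (spatial fastest, then channel, then batch).

.LRELU_SLOPE <- 0.01
.BN_EPS <- 1e-5
.BN_MOMENTUM <- 0.1

.he_mat <- function(nrow, fan_in) {
  matrix(rnorm(nrow * fan_in, sd = sqrt(2 / fan_in)), nrow, fan_in)
}

.lrelu <- function(x) pmax(x, 0) + .LRELU_SLOPE * pmin(x, 0)
.lrelu_grad <- function(x) ifelse(x > 0, 1, .LRELU_SLOPE)

#' Logistic sigmoid
#' @param x numeric array or vector.
#' @return values in (0, 1), same shape as `x`.
#' @export
sigmoid <- function(x) 1 / (1 + exp(-x))

# Concatenate two tensors along the channel (4th) dimension.
.cat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(length(da) == 5, all(da[-4] == db[-4]))
  out <- array(0, c(da[1:3], da[4] + db[4], da[5]))
  if (da[4] > 0) out[, , , seq_len(da[4]), ] <- a
  if (db[4] > 0) out[, , , da[4] + seq_len(db[4]), ] <- b
  out
}

## ---- conv block: conv3x3x3 -> batch norm -> leaky ReLU ----

.cb_init <- function(cin, cout) {
  list(
    w = .he_mat(cout, cin * 27), b = numeric(cout),
    g = rep(1, cout), be = numeric(cout),
    rm = numeric(cout), rv = rep(1, cout)
  )
}

.cb_fw <- function(p, x, training) {
  z <- conv3d_fw(x, p$w, p$b)
  bn <- bn_act_fw(z, p$g, p$be, p$rm, p$rv, training,
                  .BN_MOMENTUM, .BN_EPS, .LRELU_SLOPE)
  cache <- if (training) {
    list(x = x, xhat = bn$xhat, invstd = bn$invstd, y = bn$y,
         rm_new = bn$rm_new, rv_new = bn$rv_new, dims = dim(z))
  } else NULL
  list(y = bn$y, cache = cache)
}

.cb_bw <- function(p, cache, gy) {
  bn <- bn_act_bw(gy, cache$y, cache$xhat, cache$invstd, p$g, .LRELU_SLOPE)
  cb <- conv3d_bw(cache$x, p$w, bn$gz, TRUE)
  list(gx = cb$gx,
       grads = list(w = cb$gw, b = cb$gb, g = bn$gg, be = bn$gbe,
                    rm_new = cache$rm_new, rv_new = cache$rv_new))
}

.maxpool_bw <- function(gy, idx, in_dims) {
  gx <- numeric(prod(in_dims))
  gx[idx] <- gy
  array(gx, in_dims)
}

## ---- encoder (shared by U-net and the stage-3 classifier) ----

.enc_widths <- function(d) d$width * 2^(seq_len(d$levels) - 1)

.enc_init <- function(d) {
  w <- .enc_widths(d)
  enc <- vector("list", d$levels)
  cin <- d$in_ch
  for (l in seq_len(d$levels)) {
    enc[[l]] <- list(c1 = .cb_init(cin, w[l]), c2 = .cb_init(w[l], w[l]))
    cin <- w[l]
  }
  enc
}

# Returns per-level outputs (skips), the deepest features, and caches.
.enc_fw <- function(enc, x, training) {
  L <- length(enc)
  skips <- vector("list", L)
  caches <- vector("list", L)
  h <- x
  for (l in seq_len(L)) {
    r1 <- .cb_fw(enc[[l]]$c1, h, training)
    r2 <- .cb_fw(enc[[l]]$c2, r1$y, training)
    skips[[l]] <- r2$y
    pool <- NULL
    if (l < L) {
      pool <- maxpool3d_fw(r2$y)
      h <- pool$y
    }
    caches[[l]] <- list(c1 = r1$cache, c2 = r2$cache,
                        pool_idx = pool$idx, in_dims = dim(r2$y))
  }
  list(skips = skips, deep = skips[[L]], caches = caches)
}

# g_skips: list of gradients w.r.t. each level's output (NULL allowed);
# the deepest level's gradient is g_skips[[L]]. Returns gx and grads.
.enc_bw <- function(enc, caches, g_skips) {
  L <- length(enc)
  grads <- vector("list", L)
  g_pooled <- NULL   # gradient flowing into level l's pooled output
  for (l in rev(seq_len(L))) {
    g <- g_skips[[l]]
    if (!is.null(g_pooled)) {
      gp <- .maxpool_bw(g_pooled, caches[[l]]$pool_idx, caches[[l]]$in_dims)
      g <- if (is.null(g)) gp else g + gp
    }
    if (is.null(g)) g <- array(0, caches[[l]]$in_dims)
    b2 <- .cb_bw(enc[[l]]$c2, caches[[l]]$c2, g)
    b1 <- .cb_bw(enc[[l]]$c1, caches[[l]]$c1, b2$gx)
    grads[[l]] <- list(c1 = b1$grads, c2 = b2$grads)
    g_pooled <- b1$gx
  }
  list(gx = g_pooled, grads = grads)
}

## ---- U-shaped network ----

# descriptor d: list(in_ch, levels, width)
unet_init <- function(d) {
  w <- .enc_widths(d)
  up <- vector("list", max(d$levels - 1, 0))
  dec <- vector("list", max(d$levels - 1, 0))
  for (l in seq_len(d$levels - 1)) {
    up[[l]] <- list(w = .he_mat(w[l], w[l + 1] * 8), b = numeric(w[l]))
    dec[[l]] <- list(c1 = .cb_init(2 * w[l], w[l]), c2 = .cb_init(w[l], w[l]))
  }
  list(enc = .enc_init(d), up = up, dec = dec,
       out = list(w = .he_mat(1, w[1]), b = 0))
}

# 1x1x1 output convolution (channel mixing per voxel).
.out_fw <- function(p, feat) {
  d <- dim(feat)
  vox <- prod(d[1:3]); C <- d[4]; N <- d[5]
  fm <- array(feat, c(vox, C, N))
  logits <- array(0, c(d[1:3], 1, N))
  for (n in seq_len(N)) {
    logits[, , , 1, n] <- fm[, , n] %*% t(p$w) + p$b
  }
  logits
}

.out_bw <- function(p, feat, g_logits) {
  d <- dim(feat)
  vox <- prod(d[1:3]); C <- d[4]; N <- d[5]
  fm <- array(feat, c(vox, C, N))
  glm <- array(g_logits, c(vox, 1, N))
  gw <- matrix(0, 1, C)
  gb <- 0
  gfeat <- array(0, d)
  gf <- array(gfeat, c(vox, C, N))
  for (n in seq_len(N)) {
    gw <- gw + t(glm[, , n]) %*% fm[, , n]
    gb <- gb + sum(glm[, , n])
    gf[, , n] <- glm[, , n] %*% p$w
  }
  list(gw = gw, gb = gb, gfeat = array(gf, d))
}

# Forward pass; returns logits (1 channel), feat (decoder output, width
# channels), deep (deepest encoder features) and, when training, a cache.
unet_fw <- function(p, x, training = FALSE) {
  e <- .enc_fw(p$enc, x, training)
  L <- length(p$enc)
  h <- e$deep
  dcaches <- vector("list", max(L - 1, 0))
  for (l in rev(seq_len(L - 1))) {
    u <- upconv3d_fw(h, p$up[[l]]$w, p$up[[l]]$b)
    ct <- .cat_ch(u, e$skips[[l]])
    r1 <- .cb_fw(p$dec[[l]]$c1, ct, training)
    r2 <- .cb_fw(p$dec[[l]]$c2, r1$y, training)
    dcaches[[l]] <- list(h_in = h, c1 = r1$cache, c2 = r2$cache,
                         n_up = dim(u)[4])
    h <- r2$y
  }
  feat <- h
  logits <- .out_fw(p$out, feat)
  cache <- if (training) list(enc = e$caches, dec = dcaches, feat = feat) else NULL
  list(logits = logits, feat = feat, deep = e$deep, cache = cache)
}

# Backward pass. g_logits matches the logits shape; g_feat and g_deep are
# optional extra gradients flowing into the decoder output and the deepest
# encoder features (used when later stages consume them — during stage-1
# training they are NULL).
unet_bw <- function(p, cache, g_logits, g_feat = NULL, g_deep = NULL) {
  ob <- .out_bw(p$out, cache$feat, g_logits)
  gfeat <- ob$gfeat
  if (!is.null(g_feat)) gfeat <- gfeat + g_feat
  L <- length(p$enc)
  g_skips <- vector("list", L)
  gup <- vector("list", max(L - 1, 0))
  gdec <- vector("list", max(L - 1, 0))
  gh <- gfeat
  for (l in seq_len(L - 1)) {
    dc <- cache$dec[[l]]
    b2 <- .cb_bw(p$dec[[l]]$c2, dc$c2, gh)
    b1 <- .cb_bw(p$dec[[l]]$c1, dc$c1, b2$gx)
    gdec[[l]] <- list(c1 = b1$grads, c2 = b2$grads)
    nu <- dc$n_up
    g_ct <- b1$gx
    g_u <- g_ct[, , , seq_len(nu), , drop = FALSE]
    g_skips[[l]] <- g_ct[, , , nu + seq_len(dim(g_ct)[4] - nu), ,
                         drop = FALSE]
    ub <- upconv3d_bw(dc$h_in, p$up[[l]]$w, g_u)
    gup[[l]] <- list(w = ub$gw, b = ub$gb)
    gh <- ub$gx
  }
  g_skips[[L]] <- gh
  if (!is.null(g_deep)) g_skips[[L]] <- g_skips[[L]] + g_deep
  eb <- .enc_bw(p$enc, cache$enc, g_skips)
  list(gx = eb$gx,
       grads = list(enc = eb$grads, up = gup, dec = gdec,
                    out = list(w = ob$gw, b = ob$gb)))
}

## ---- GAP + two fully connected layers head ----

head_init <- function(cin, n_out, hidden = 64) {
  list(fc1 = list(w = .he_mat(hidden, cin), b = numeric(hidden)),
       fc2 = list(w = .he_mat(n_out, hidden), b = numeric(n_out)))
}

# deep: (X, Y, Z, C, N) -> output (n_out x N) pre-activation.
head_fw <- function(p, deep, training = FALSE) {
  d <- dim(deep)
  vox <- prod(d[1:3]); C <- d[4]; N <- d[5]
  gap <- matrix(colMeans(matrix(deep, nrow = vox)), C, N)
  z1 <- p$fc1$w %*% gap + p$fc1$b
  h1 <- .lrelu(z1)
  out <- p$fc2$w %*% h1 + p$fc2$b
  cache <- if (training) list(gap = gap, z1 = z1, h1 = h1, deep_dims = d) else NULL
  list(out = out, cache = cache)
}

head_bw <- function(p, cache, g_out) {
  gw2 <- g_out %*% t(cache$h1)
  gb2 <- rowSums(g_out)
  gh1 <- t(p$fc2$w) %*% g_out
  gz1 <- gh1 * .lrelu_grad(cache$z1)
  gw1 <- gz1 %*% t(cache$gap)
  gb1 <- rowSums(gz1)
  ggap <- t(p$fc1$w) %*% gz1   # C x N
  d <- cache$deep_dims
  vox <- prod(d[1:3])
  g_deep <- array(rep(as.numeric(ggap) / vox, each = vox), d)
  list(g_deep = g_deep,
       grads = list(fc1 = list(w = gw1, b = gb1),
                    fc2 = list(w = gw2, b = gb2)))
}

## ---- losses ----

#' Binary cross-entropy
#'
#' Mean of `-(t*log(p) + (1-t)*log(1-p))` with probabilities clamped to
#' `[eps, 1-eps]`.
#'
#' @param probabilities numeric array/vector of predicted probabilities.
#' @param targets numeric array/vector of targets in `[0, 1]`, same shape.
#' @param eps clamping constant keeping probabilities away from 0 and 1.
#' @return scalar loss.
#' @export
bce_loss <- function(probabilities, targets, eps = 1e-7) {
  if (length(probabilities) != length(targets)) {
    stop("bce_loss: shape mismatch between probabilities and targets")
  }
  if (any(targets < 0 | targets > 1)) stop("bce_loss: targets outside [0, 1]")
  p <- pmin(pmax(as.numeric(probabilities), eps), 1 - eps)
  t <- as.numeric(targets)
  -mean(t * log(p) + (1 - t) * log(1 - p))
}

#' Smooth L1 loss
#'
#' Mean over components of `0.5 d^2 / beta` for `|d| < beta` and
#' `|d| - 0.5 beta` otherwise, `d = pred - target`.
#'
#' @param pred,target numeric vectors of equal length.
#' @param beta transition point between the quadratic and linear regime.
#' @return scalar loss.
#' @export
smooth_l1_loss <- function(pred, target, beta = 1.0) {
  d <- as.numeric(pred) - as.numeric(target)
  mean(ifelse(abs(d) < beta, 0.5 * d^2 / beta, abs(d) - 0.5 * beta))
}

.smooth_l1_grad <- function(pred, target, beta = 1.0) {
  d <- as.numeric(pred) - as.numeric(target)
  ifelse(abs(d) < beta, d / beta, sign(d)) / length(d)
}

## ---- AdamW ----

adamw_state <- function() list(t = 0, m = list())

# One AdamW step. grads mirrors the params tree; leaves named rm_new/rv_new
# are running batch-norm statistics and are assigned directly (no gradient
# step, no decay). Decoupled weight decay applies to weight matrices only.
adamw_step <- function(params, grads, state, lr, weight_decay = 0.01,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  t <- state$t
  sget <- function(s, k) {
    if (is.numeric(k)) {
      if (k <= length(s)) s[[k]] else NULL
    } else {
      s[[k]]
    }
  }
  walk <- function(p, g, s) {
    keys <- if (is.null(names(g))) seq_along(g) else names(g)
    for (nm in keys) {
      gv <- g[[nm]]
      if (is.null(gv)) next
      if (identical(nm, "rm_new")) { p$rm <- gv; next }
      if (identical(nm, "rv_new")) { p$rv <- gv; next }
      if (is.list(gv)) {
        sv <- sget(s, nm)
        r <- walk(p[[nm]], gv, if (is.null(sv)) list() else sv)
        p[[nm]] <- r$p
        s[[nm]] <- r$s
      } else {
        if (is.null(sget(s, nm))) s[[nm]] <- list(m = 0 * gv, v = 0 * gv)
        s[[nm]]$m <- beta1 * s[[nm]]$m + (1 - beta1) * gv
        s[[nm]]$v <- beta2 * s[[nm]]$v + (1 - beta2) * gv * gv
        mhat <- s[[nm]]$m / (1 - beta1^t)
        vhat <- s[[nm]]$v / (1 - beta2^t)
        wd <- if (nm == "w") weight_decay else 0
        p[[nm]] <- p[[nm]] - lr * (mhat / (sqrt(vhat) + eps) + wd * p[[nm]])
      }
    }
    list(p = p, s = s)
  }
  r <- walk(params, grads, state$m)
  list(params = r$p, state = list(t = t, m = r$s))
}
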