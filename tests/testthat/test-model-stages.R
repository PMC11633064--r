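test_that("convolution kernels match naive double-precision oracles", {
  set.seed(17)
  x <- array(rnorm(4 * 4 * 4 * 2 * 2), c(4, 4, 4, 2, 2))
  w <- matrix(rnorm(3 * 2 * 27, sd = .2), 3, 2 * 27)
  b <- rnorm(3)
  y <- mf_ns$conv3d_fw(x, w, b)
  expect_equal(y, naive_conv3d(x, w, b), tolerance = 1e-5)
  gy <- array(rnorm(length(y)), dim(y))
  bw <- mf_ns$conv3d_bw(x, w, gy, TRUE)
  nb <- naive_conv3d_bw(x, w, gy)
  expect_equal(bw$gx, nb$gx, tolerance = 1e-4)
  expect_equal(bw$gw, nb$gw, tolerance = 1e-4)
  expect_equal(bw$gb, nb$gb, tolerance = 1e-4)
})

test_that("U-net backward matches finite differences through batch norm", {
  set.seed(19)
  d <- list(in_ch = 2, levels = 2, width = 2)
  p <- mf_ns$unet_init(d)
  xin <- array(rnorm(4 * 4 * 4 * 2 * 2), c(4, 4, 4, 2, 2))
  tgt <- array((runif(4 * 4 * 4 * 1 * 2) > .5) * 1, c(4, 4, 4, 1, 2))
  loss_fn <- function(p) {
    o <- mf_ns$unet_fw(p, xin, training = TRUE)
    bce_loss(sigmoid(o$logits), tgt)
  }
  o <- mf_ns$unet_fw(p, xin, training = TRUE)
  gl <- array((sigmoid(o$logits) - tgt) / length(tgt), dim(o$logits))
  gr <- mf_ns$unet_bw(p, o$cache, gl)
  # spot-check a few leaves; tolerance reflects single-precision conv kernels
  leaves <- list(
    list(get = function(p) p$enc[[1]]$c1$w,
         set = function(p, v) { p$enc[[1]]$c1$w <- matrix(v, 2); p },
         g = as.numeric(gr$grads$enc[[1]]$c1$w)),
    list(get = function(p) p$up[[1]]$w,
         set = function(p, v) { p$up[[1]]$w <- matrix(v, 2); p },
         g = as.numeric(gr$grads$up[[1]]$w)),
    list(get = function(p) p$dec[[1]]$c2$g,
         set = function(p, v) { p$dec[[1]]$c2$g <- v; p },
         g = gr$grads$dec[[1]]$c2$g))
  for (lf in leaves) {
    v <- lf$get(p)
    ii <- sample(seq_along(v), min(4, length(v)))
    for (i in ii) {
      eps <- 1e-3
      fd <- (loss_fn(lf$set(p, replace(v, i, v[i] + eps))) -
               loss_fn(lf$set(p, replace(v, i, v[i] - eps)))) / (2 * eps)
      expect_equal(fd, lf$g[i], tolerance = 0.05)
    }
  }
})

test_that("loss functions reproduce closed-form values", {
  expect_equal(bce_loss(rep(0.5, 10), rep(0.5, 10)), log(2), tolerance = 1e-9)
  expect_lt(bce_loss(c(1, 0), c(1, 0)), 1e-5)
  # hand-computed 3-element case
  expect_equal(bce_loss(c(0.2, 0.7, 0.9), c(0, 1, 1)),
               mean(-log(c(0.8, 0.7, 0.9))), tolerance = 1e-9)
  expect_equal(round(bce_loss(c(0.2, 0.7, 0.9), c(0, 1, 1)), 4), 0.2284)
  expect_error(bce_loss(c(0.5, 0.5), 0.5), "shape")
  expect_error(bce_loss(0.5, 2), "targets")

  expect_equal(smooth_l1_loss(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(smooth_l1_loss(c(2, 2, 2), c(1, 1, 1)), 0.5)
  expect_equal(smooth_l1_loss(c(3, 1, 1), c(1, 1, 1)), 0.5)
  # BCE is minimized at p = t (scalar grid search)
  t0 <- 0.3
  ps <- seq(0.05, 0.95, by = 0.05)
  ls <- vapply(ps, function(p) bce_loss(p, t0), numeric(1))
  expect_equal(ps[which.min(ls)], t0)
})

test_that("stage forwards are deterministic, shape-preserving and typed", {
  set.seed(23)
  s1 <- stage1_init(levels = 2, width = 2, hidden = 8, seed = 1)
  v <- mf_volume(array(runif(16^3), c(16, 16, 16)))
  patches <- lapply(list(c(0L, 0L, 0L), c(8L, 8L, 8L)), function(o) {
    gap_channels(extract_patch(v, o, 8))
  })
  o1 <- stage1_forward(s1, patches)
  o1b <- stage1_forward(s1, patches)
  expect_identical(o1$logits, o1b$logits)
  expect_identical(o1$position, o1b$position)
  expect_equal(dim(o1$logits), c(8, 8, 8, 1, 2))
  expect_true(all(is.finite(o1$logits)) && all(is.finite(o1$position)))
  expect_true(all(o1$position >= 0 & o1$position <= 1))

  raw <- lapply(patches, function(p) {
    p$data <- p$data[, , , 1, drop = FALSE]
    p
  })
  x1 <- mf_ns$.stack_patches(raw)
  ctx2 <- mf_ns$.cat_ch(mf_ns$.cat_ch(x1, o1$feat), o1$logits)
  s2 <- stage2_init(feat_ch = 2, levels = 2, width = 2, seed = 2)
  o2 <- stage2_forward(s2, ctx2)
  expect_equal(dim(o2$logits_a), dim(o2$logits_b))
  expect_equal(dim(o2$logits_b), c(8, 8, 8, 1, 2))
  expect_identical(o2$logits_b, stage2_forward(s2, ctx2)$logits_b)
  expect_error(stage2_forward(s2, x1), "channels")

  ctx3 <- mf_ns$.cat_ch(ctx2, o2$logits_b)
  s3 <- stage3_init(feat_ch = 2, levels = 2, width = 2, hidden = 8, seed = 3)
  o3 <- stage3_forward(s3, ctx3)
  expect_equal(dim(o3$logits), c(1, 2))
  expect_true(all(is.finite(o3$logits)))
  expect_error(stage3_forward(s3, ctx2), "channels")
})

test_that("the stage-2 cascade trains jointly (first network receives gradient)", {
  set.seed(29)
  s2 <- stage2_init(feat_ch = 1, levels = 2, width = 2, seed = 4)
  ctx <- array(rnorm(8 * 8 * 8 * 3 * 2), c(8, 8, 8, 3, 2))
  tgt <- array((runif(8 * 8 * 8 * 1 * 2) > .9) * 1, c(8, 8, 8, 1, 2))
  st <- mf_ns$.stage2_step(list(unet_a = s2$unet_a, unet_b = s2$unet_b),
                           list(ctx = ctx, target = tgt), training = TRUE)
  expect_gt(max(abs(st$grads$unet_a$enc[[1]]$c1$w)), 0)
  expect_gt(max(abs(st$grads$unet_b$enc[[1]]$c1$w)), 0)
})

test_that("the stage-3 classifier separates bright from dark patches", {
  set.seed(31)
  s3 <- stage3_init(feat_ch = 0, levels = 2, width = 2, hidden = 8, seed = 5)
  # 3-channel context stand-in: all-bright vs all-dark toy patches
  mk <- function(level) array(level + rnorm(8^3 * 3, sd = .05), c(8, 8, 8, 3, 1))
  xs <- lapply(1:8, function(i) mk(if (i %% 2) 1 else 0))
  labels <- rep(c(1, 0), 4)
  params <- list(enc = s3$enc, head = s3$head)
  opt <- mf_ns$adamw_state()
  for (it in 1:25) {
    batch <- list(ctx = mf_ns$.cat_ch(xs[[(it %% 8) + 1]],
                                      array(0, c(8, 8, 8, 0, 1))),
                  labels = labels[(it %% 8) + 1])
    st <- mf_ns$.stage3_step(params, batch, training = TRUE)
    upd <- mf_ns$adamw_step(params, st$grads, opt, 0.02)
    params <- upd$params
    opt <- upd$state
  }
  preds <- vapply(xs, function(x) {
    e <- mf_ns$.enc_fw(params$enc, x, FALSE)
    as.numeric(sigmoid(mf_ns$head_fw(params$head, e$deep)$out))
  }, numeric(1))
  expect_equal(as.numeric(preds > 0.5), labels)
})

test_that("one AdamW step on a fixed batch decreases the loss", {
  set.seed(37)
  d <- list(in_ch = 1, levels = 2, width = 2)
  p <- mf_ns$unet_init(d)
  x <- array(rnorm(8^3 * 2), c(8, 8, 8, 1, 2))
  tgt <- array((x > 0.5) * 1, dim(x))
  opt <- mf_ns$adamw_state()
  step <- function(p, opt) {
    o <- mf_ns$unet_fw(p, x, training = TRUE)
    pr <- sigmoid(o$logits)
    loss <- bce_loss(pr, tgt)
    gr <- mf_ns$unet_bw(p, o$cache, array((pr - tgt) / length(tgt), dim(pr)))
    upd <- mf_ns$adamw_step(p, gr$grads, opt, 1e-3, weight_decay = 0)
    list(p = upd$params, opt = upd$state, loss = loss)
  }
  s1 <- step(p, opt)
  s2 <- step(s1$p, s1$opt)
  # after a few steps the loss on the fixed batch is below the initial loss
  for (i in 1:5) s2 <- step(s2$p, s2$opt)
  expect_lt(s2$loss, s1$loss)
})

test_that("checkpoints embed the descriptor and refuse mismatches", {
  dir <- withr::local_tempdir()
  s1 <- stage1_init(levels = 2, width = 2, hidden = 8, seed = 6)
  path <- file.path(dir, "s1.rds")
  save_checkpoint(s1, path)
  back <- load_checkpoint(path, descriptor = s1$descriptor)
  expect_identical(back$descriptor, s1$descriptor)
  other <- stage1_init(levels = 2, width = 4, hidden = 8, seed = 7)
  expect_error(load_checkpoint(path, descriptor = other$descriptor),
               "descriptor")
  expect_error(load_checkpoint(file.path(dir, "nope.rds")), "not found")
})
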