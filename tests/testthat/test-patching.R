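test_that("patch_grid tiles every voxel with clamped, sorted origins", {
  expect_equal(patch_grid(c(64, 64, 64), 64, 32), matrix(0L, 1, 3,
               dimnames = list(NULL, c("x", "y", "z"))))
  g <- patch_grid(c(96, 64, 64), 64, 32)
  expect_equal(sort(unique(g[, 1])), c(0L, 32L))
  expect_equal(nrow(g), 2L)
  g63 <- patch_grid(c(63, 63, 63), 64, 32)
  expect_equal(nrow(g63), 1L)
  expect_equal(as.integer(g63), c(0L, 0L, 0L))
  # coverage property over random shapes
  set.seed(5)
  for (trial in 1:10) {
    shape <- sample(10:90, 3, replace = TRUE)
    ps <- 32L; st <- sample(c(8L, 16L, 32L), 1)
    g <- patch_grid(shape, ps, st)
    covered <- array(FALSE, shape)
    for (r in seq_len(nrow(g))) {
      hi <- pmin(g[r, ] + ps, shape)
      covered[(g[r, 1] + 1):hi[1], (g[r, 2] + 1):hi[2], (g[r, 3] + 1):hi[3]] <- TRUE
    }
    expect_true(all(covered))
    expect_true(all(g >= 0) && all(t(g) <= pmax(shape - ps, 0)))
  }
})

test_that("extract_patch copies interior regions and zero-pads the border", {
  set.seed(7)
  v <- mf_volume(array(runif(40^3), c(40, 40, 40)))
  p <- extract_patch(v, c(4, 8, 2), 16)
  expect_equal(array(p$data[, , , 1], rep(16, 3)),
               v$data[5:20, 9:24, 3:18])
  expect_equal(p$valid_extent, rep(16L, 3))
  # corner origin: 1 valid voxel, rest zeros
  pc <- extract_patch(v, c(39, 39, 39), 16)
  expect_equal(pc$valid_extent, rep(1L, 3))
  expect_equal(sum(pc$data != 0), 1L)
  expect_equal(pc$data[1, 1, 1, 1], v$data[40, 40, 40])
  expect_error(extract_patch(v, c(40, 0, 0), 16), "outside")
  # conservation: coverage-weighted sum over tiled mask patches equals mask sum
  m <- mf_prob(array(rbinom(40^3, 1, .05), c(40, 40, 40)))
  g <- patch_grid(dim(m$data), 16, 8)
  cnt <- array(0, dim(m$data)); tot <- 0
  for (r in seq_len(nrow(g))) {
    pp <- extract_patch(m, g[r, ], 16)
    tot <- tot + sum(pp$data)
    hi <- pmin(g[r, ] + 16, dim(m$data))
    cnt[(g[r, 1] + 1):hi[1], (g[r, 2] + 1):hi[2], (g[r, 3] + 1):hi[3]] <-
      cnt[(g[r, 1] + 1):hi[1], (g[r, 2] + 1):hi[2], (g[r, 3] + 1):hi[3]] + 1
  }
  expect_equal(tot, sum(m$data * cnt))
})

test_that("gap_channels computes per-patch percentile windows", {
  # constant patch: the three window channels collapse to zero
  pc <- extract_patch(mf_volume(array(0.5, c(8, 8, 8))), c(0, 0, 0), 8)
  g <- gap_channels(pc)
  expect_equal(dim(g$data)[4], 4L)
  expect_true(all(g$data[, , , 2:4] == 0))
  # hand-checked brute-force percentile windows on an 8-voxel patch
  vals <- c(0.05, 0.1, 0.2, 0.35, 0.5, 0.65, 0.8, 0.95)
  pv <- extract_patch(mf_volume(array(vals, c(2, 2, 2))), c(0, 0, 0), 2)
  gv <- gap_channels(pv)
  q <- quantile(vals, c(0, .3, .4, .6, .7, 1), names = FALSE)
  wins <- list(c(q[1], q[3]), c(q[2], q[5]), c(q[4], q[6]))
  for (w in 1:3) {
    expected <- (pmin(pmax(vals, wins[[w]][1]), wins[[w]][2]) - wins[[w]][1]) /
      (wins[[w]][2] - wins[[w]][1])
    expect_equal(as.numeric(gv$data[, , , w + 1]), expected)
  }
  # each window channel is monotone in the input and re-windowing is identity
  set.seed(9)
  pr <- extract_patch(mf_volume(array(runif(512), c(8, 8, 8))), c(0, 0, 0), 8)
  gr <- gap_channels(pr)
  for (w in 2:4) {
    o <- order(as.numeric(pr$data[, , , 1]))
    expect_true(all(diff(as.numeric(gr$data[, , , w])[o]) >= -1e-12))
    ch <- as.numeric(gr$data[, , , w])
    expect_equal(pmin(pmax(ch, 0), 1), ch)  # already in [0, 1]
  }
})

test_that("relative_position maps origins to [0, 1] patch centres", {
  expect_equal(relative_position(c(32, 32, 32), 64, c(128, 128, 128)),
               rep(63.5 / 127, 3))
  expect_equal(relative_position(c(0, 0, 0), 64, c(128, 128, 128)),
               rep(31.5 / 127, 3))
  # degenerate axis of dimension 1 -> 0.5
  expect_equal(relative_position(c(0, 0, 0), 1, c(1, 5, 9))[1], 0.5)
  # clamped far corner stays within bounds
  expect_true(all(relative_position(c(64, 64, 64), 64, c(100, 100, 100)) <= 1))
})

test_that("soften_fracture_target dilates, smooths and renormalizes", {
  empty <- soften_fracture_target(mf_mask(array(0L, c(8, 8, 8))))
  expect_true(all(empty$data == 0))
  one <- array(0L, c(9, 9, 9)); one[5, 5, 5] <- 1L
  soft <- soften_fracture_target(mf_mask(one), dilation_radius_vox = 1,
                                 sigma_vox = 0)
  expect_equal(sum(soft$data == 1), 7L)  # 6-neighbourhood ball of one voxel
  expect_equal(sum(soft$data > 0), 7L)
  # dilation + smoothing never shrinks the positive set, output in [0, 1]
  set.seed(11)
  m <- mf_mask(array(rbinom(9^3, 1, .02), c(9, 9, 9)))
  s <- soften_fracture_target(m, 1, 0.5)
  expect_gte(sum(s$data > 0), sum(m$data > 0))
  expect_true(all(s$data >= 0 & s$data <= 1))
  if (any(m$data > 0)) expect_equal(max(s$data), 1)
})

test_that("sample_balanced_patches balances positives and negatives", {
  set.seed(13)
  vol <- mf_volume(array(runif(48^3), c(48, 48, 48)))
  tgt <- array(0, c(48, 48, 48)); tgt[20:24, 20:24, 20:24] <- 1
  tgt <- mf_prob(tgt)
  pairs <- sample_balanced_patches(vol, tgt, 8, patch_size = 16, seed = 3)
  pos <- vapply(pairs, function(p) sum(p$target$data) > 0, logical(1))
  expect_equal(sum(pos), 4L)
  expect_equal(sum(!pos), 4L)
  # determinism under the seed
  pairs2 <- sample_balanced_patches(vol, tgt, 8, patch_size = 16, seed = 3)
  o1 <- t(vapply(pairs, function(p) p$patch$origin, integer(3)))
  o2 <- t(vapply(pairs2, function(p) p$patch$origin, integer(3)))
  expect_identical(o1, o2)
  # every positive patch really contains target mass
  for (p in pairs[pos]) expect_gt(sum(p$target$data), 0)
  # degenerate: no positives anywhere
  expect_warning(
    sample_balanced_patches(vol, mf_prob(array(0, c(48, 48, 48))), 4,
                            patch_size = 16, seed = 4),
    "no positive")
})
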