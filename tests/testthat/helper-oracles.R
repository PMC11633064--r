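# Shared fixtures and independent brute-force oracles for the test suite.
# Oracles are deliberately naive and kept independent of the package's
# implementation paths.

mf_ns <- asNamespace("mandfrac")

# A desk-scale phantom spec (48-cube) for fast unit tests.
small_spec <- function(...) {
  args <- utils::modifyList(
    list(shape = c(48L, 48L, 48L), arch_radius_mm = 6,
         bone_radius_mm = 2.4, cortical_thickness_mm = 0.8,
         displacement_mm = 1.6, min_separation_deg = 70),
    list(...))
  do.call(phantom_spec, args)
}

# Naive 3x3x3 same-padding convolution (layout X,Y,Z,C,N; w col = c*27+off).
naive_conv3d <- function(x, w, b) {
  d <- dim(x)
  y <- array(0, c(d[1:3], nrow(w), d[5]))
  for (n in seq_len(d[5])) for (k in seq_len(d[3])) for (j in seq_len(d[2]))
    for (i in seq_len(d[1])) {
      col <- numeric(d[4] * 27)
      for (c in seq_len(d[4])) for (dc in -1:1) for (db in -1:1)
        for (da in -1:1) {
          off <- (da + 1) + 3 * (db + 1) + 9 * (dc + 1)
          ii <- i + da; jj <- j + db; kk <- k + dc
          col[(c - 1) * 27 + off + 1] <-
            if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2] &&
                kk >= 1 && kk <= d[3]) x[ii, jj, kk, c, n] else 0
        }
      y[i, j, k, , n] <- as.numeric(w %*% col) + b
    }
  y
}

# Analytic double-precision backward of the same convolution.
naive_conv3d_bw <- function(x, w, gy) {
  d <- dim(x)
  Cout <- nrow(w)
  gx <- array(0, dim(x)); gw <- matrix(0, Cout, d[4] * 27)
  gb <- numeric(Cout)
  for (n in seq_len(d[5])) for (co in seq_len(Cout)) {
    gb[co] <- gb[co] + sum(gy[, , , co, n])
    for (c in seq_len(d[4])) for (dc in -1:1) for (db in -1:1)
      for (da in -1:1) {
        off <- (c - 1) * 27 + (da + 1) + 3 * (db + 1) + 9 * (dc + 1) + 1
        for (k in seq_len(d[3])) for (j in seq_len(d[2]))
          for (i in seq_len(d[1])) {
            ii <- i + da; jj <- j + db; kk <- k + dc
            if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2] &&
                kk >= 1 && kk <= d[3]) {
              gw[co, off] <- gw[co, off] + gy[i, j, k, co, n] * x[ii, jj, kk, c, n]
              gx[ii, jj, kk, c, n] <- gx[ii, jj, kk, c, n] +
                gy[i, j, k, co, n] * w[co, off]
            }
          }
      }
  }
  list(gx = gx, gw = gw, gb = gb)
}

# Brute-force connected-component labeling by repeated flood fill in R.
naive_label3d <- function(mask, connectivity = 26) {
  d <- dim(mask)
  off <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  off <- off[rowSums(abs(off)) > 0, ]
  if (connectivity == 6) off <- off[rowSums(abs(off)) == 1, ]
  if (connectivity == 18) off <- off[rowSums(abs(off)) <= 2, ]
  lab <- array(0L, d)
  nxt <- 0L
  for (s in which(mask != 0)) {
    if (lab[s] != 0) next
    nxt <- nxt + 1L
    queue <- s
    lab[s] <- nxt
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      pos <- arrayInd(v, d)
      for (r in seq_len(nrow(off))) {
        p <- pos + c(off$dx[r], off$dy[r], off$dz[r])
        if (any(p < 1) || any(p > d)) next
        w <- p[1] + (p[2] - 1) * d[1] + (p[3] - 1) * d[1] * d[2]
        if (mask[w] != 0 && lab[w] == 0) {
          lab[w] <- nxt
          queue <- c(queue, w)
        }
      }
    }
  }
  lab
}

# Brute-force FROC over abstract per-scan detections. Each scan is a list
# with `gt` (number of ground-truth lesions) and `props`: data frame with
# columns conf and hit (0 = false positive, or the 1-based index of the
# lesion the proposal overlaps). Greedy matching by descending confidence.
naive_froc <- function(scans) {
  confs <- sort(unique(unlist(lapply(scans, function(s) s$props$conf))),
                decreasing = TRUE)
  total_gt <- sum(vapply(scans, `[[`, numeric(1), "gt"))
  rows <- lapply(c(Inf, confs), function(tau) {
    tp <- 0; fp <- 0
    for (s in scans) {
      keep <- s$props[s$props$conf >= tau, , drop = FALSE]
      keep <- keep[order(keep$conf, decreasing = TRUE), , drop = FALSE]
      taken <- logical(s$gt)
      for (r in seq_len(nrow(keep))) {
        h <- keep$hit[r]
        if (h > 0 && !taken[h]) taken[h] <- TRUE
        else fp <- fp + 1
      }
      tp <- tp + sum(taken)
    }
    c(tau = tau, sens = tp / total_gt, fps = fp / length(scans))
  })
  do.call(rbind, rows)
}

naive_froc_auc <- function(curve, rates = c(1 / 16, 1 / 8, 1 / 4, 1 / 2, 1)) {
  mean(vapply(rates, function(r) {
    ok <- curve[, "fps"] <= r
    if (any(ok)) max(curve[ok, "sens"]) else 0
  }, numeric(1)))
}

# Build a labeled ground-truth mask plus proposal list realizing an abstract
# detection layout on a small grid: lesion g occupies a 2x2x2 block at
# x-offset 8*g; a proposal hitting g overlaps that block, a false positive
# sits in untouched space.
abstract_to_masks <- function(scan) {
  shape <- c(8L * (scan$gt + nrow(scan$props) + 2L), 8L, 8L)
  gt <- array(0L, shape)
  for (g in seq_len(scan$gt)) gt[8 * (g - 1) + 1:2, 1:2, 1:2] <- g
  props <- lapply(seq_len(nrow(scan$props)), function(r) {
    h <- scan$props$hit[r]
    vox <- if (h > 0) {
      which(gt == h)[1:2]
    } else {
      base <- 8 * (scan$gt + r) # clear of all lesions and other FPs
      base + seq_len(2)
    }
    list(voxels = sort(vox), shape = shape, source = "stage2",
         confidence = scan$props$conf[r], size = length(vox))
  })
  list(proposals = props, gt = mf_mask(gt))
}
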