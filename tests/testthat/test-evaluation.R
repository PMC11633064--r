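test_that("dice and iou follow the overlap formulas and their identity", {
  a <- array(0, c(5, 5, 5)); a[1:2, 1:5, 1] <- 1   # |a| = 10
  b <- array(0, c(5, 5, 5)); b[1:2, 1:4, 1] <- 1; b[3, 1:2, 1] <- 1 # |b| = 10, overlap 8
  expect_equal(dice(a, b), 0.8)
  expect_equal(iou(a, b), 8 / 12)
  expect_equal(dice(a, a), 1.0)
  expect_equal(iou(a, a), 1.0)
  z <- array(0, c(5, 5, 5))
  expect_equal(dice(z, z), 1.0)
  expect_equal(iou(z, z), 1.0)
  disj <- array(0, c(5, 5, 5)); disj[5, 5, 5] <- 1
  expect_equal(dice(a, disj), 0.0)
  expect_error(dice(a, array(0, c(4, 4, 4))), "mismatch")
  # identity iou = dice / (2 - dice) on random mask pairs
  set.seed(43)
  for (i in 1:25) {
    x <- array(rbinom(64, 1, runif(1, .1, .9)), c(4, 4, 4))
    y <- array(rbinom(64, 1, runif(1, .1, .9)), c(4, 4, 4))
    d <- dice(x, y)
    expect_equal(iou(x, y), d / (2 - d), tolerance = 1e-12)
  }
})

test_that("match_detections applies the greedy single-match rule", {
  gt <- array(0L, c(30, 6, 6))
  gt[2:4, 2:4, 2:4] <- 1L
  gt[20:22, 2:4, 2:4] <- 2L
  mk <- function(vox, conf) list(voxels = sort(vox), shape = dim(gt),
                                 source = "stage2", confidence = conf,
                                 size = length(vox))
  # perfect one-to-one
  m <- match_detections(list(mk(which(gt == 1), .9), mk(which(gt == 2), .8)), gt)
  expect_equal(c(m$tp, m$fp, m$fn), c(2L, 0L, 0L))
  # one proposal spanning both fractures: single match -> 1 TP + 1 FN
  m2 <- match_detections(list(mk(which(gt > 0), .9)), gt)
  expect_equal(c(m2$tp, m2$fp, m2$fn), c(1L, 0L, 1L))
  # proposal touching nothing is a false positive
  far <- mk(which(array(seq_len(30 * 36), c(30, 6, 6)) == 30 * 36), .5)
  m3 <- match_detections(list(far), gt, gt_dilation_vox = 1)
  expect_equal(c(m3$tp, m3$fp, m3$fn), c(0L, 1L, 2L))
  # dilation absorbs a 2-voxel boundary miss
  near <- mk(which(slice.index(gt, 1) == 6 & slice.index(gt, 2) %in% 2:4 &
                     slice.index(gt, 3) %in% 2:4), .9)
  expect_equal(match_detections(list(near), gt, gt_dilation_vox = 2)$tp, 1L)
  expect_equal(match_detections(list(near), gt, gt_dilation_vox = 0)$tp, 0L)
})

test_that("precision and sensitivity handle the printed and degenerate cases", {
  # per-kind test counts: 33/34 nondisplaced + 11/12 displaced hits, 1 FP
  ps <- precision_sensitivity(detection_result(33 + 11, 1, 2))
  expect_equal(round(ps$precision, 3), 0.978)
  expect_equal(round(ps$sensitivity, 3), 0.957)
  expect_false(any(ps$degenerate))
  deg <- precision_sensitivity(detection_result(0, 0, 0))
  expect_equal(deg$precision, 1.0)
  expect_equal(deg$sensitivity, 1.0)
  expect_true(all(deg$degenerate))
  half <- precision_sensitivity(detection_result(1, 1, 1))
  expect_equal(half$precision, 0.5)
  expect_equal(half$sensitivity, 0.5)
})

test_that("froc enumerates operating points over all confidences", {
  # perfect detector: single interior point at sensitivity 1, 0 FP/scan
  layout <- list(list(gt = 1, props = data.frame(conf = 1, hit = 1)),
                 list(gt = 1, props = data.frame(conf = 1, hit = 1)))
  scans <- lapply(layout, abstract_to_masks)
  cv <- froc(scans)
  expect_equal(cv$sensitivity, c(0, 1))
  expect_equal(cv$fp_per_scan, c(0, 0))
  expect_equal(froc_auc(cv), 1.0)
  # detector emitting nothing collapses to sensitivity 0
  none <- lapply(list(list(gt = 1, props = data.frame(conf = numeric(0),
                                                      hit = numeric(0)))),
                 abstract_to_masks)
  cv0 <- froc(none)
  expect_equal(max(cv0$sensitivity), 0)
  expect_equal(froc_auc(cv0), 0)
  # worked 2-scan example: confidences 0.9 (TP), 0.7 (FP), 0.4 (TP)
  lay2 <- list(list(gt = 1, props = data.frame(conf = c(0.9, 0.7), hit = c(1, 0))),
               list(gt = 1, props = data.frame(conf = 0.4, hit = 1)))
  cv2 <- froc(lapply(lay2, abstract_to_masks))
  expect_equal(cv2$sensitivity, c(0, 0.5, 0.5, 1.0))
  expect_equal(cv2$fp_per_scan, c(0, 0, 0.5, 0.5))
  # no ground truth anywhere is an error
  empty <- abstract_to_masks(list(gt = 0,
                                  props = data.frame(conf = .5, hit = 0)))
  expect_error(froc(list(empty)), "no ground-truth")
})

test_that("froc_auc takes the best sensitivity at or below each FP rate", {
  curve <- data.frame(tau = c(Inf, .9, .5), sensitivity = c(0, 0.8, 1.0),
                      fp_per_scan = c(0, 0, 0.75))
  expect_equal(froc_auc(curve), mean(c(.8, .8, .8, .8, 1.0)))
  expect_equal(froc_auc(curve), 0.84)
})

test_that("evaluate_scans pools counts and splits sensitivity by kind", {
  ph <- generate_phantom(small_spec(n_fractures = 2L,
                                    kinds = c("nondisplaced", "displaced"),
                                    min_separation_deg = 60, seed = 73))
  mk <- function(id, conf) {
    vox <- which(ph$fracture$data == id)
    list(voxels = sort(vox), shape = dim(ph$fracture$data), source = "stage2",
         confidence = conf, size = length(vox))
  }
  # detect only the nondisplaced fracture
  nd_id <- ph$records$index[ph$records$kind == "nondisplaced"]
  res <- list(list(proposals = list(mk(nd_id, .9)), gt = ph$fracture,
                   records = ph$records))
  ev <- evaluate_scans(res)
  expect_equal(ev$counts$tp, 1L)
  expect_equal(ev$counts$fn, 1L)
  expect_equal(unname(ev$per_kind["nondisplaced"]), 1)
  expect_equal(unname(ev$per_kind["displaced"]), 0)
  expect_true(ev$auc >= 0 && ev$auc <= 1)
  # lowering tau never decreases sensitivity or the FP rate
  cv <- ev$froc
  expect_true(all(diff(cv$sensitivity) >= -1e-12))
  expect_true(all(diff(cv$fp_per_scan) >= -1e-12))
  # TP counts at each operating point stay within the ground-truth total
  expect_true(all(cv$sensitivity * attr(cv, "total_gt") <= attr(cv, "total_gt")))
})
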