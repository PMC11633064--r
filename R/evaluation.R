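# Evaluation: overlap metrics, fracture-level detection matching,
# precision/sensitivity, and the free-response ROC curve summarized by
# averaged sensitivity at fixed false-positive rates per scan.

#' Dice coefficient between two binary masks
#'
#' `2 |A intersect B| / (|A| + |B|)`; two empty masks give 1.
#'
#' @param a,b aligned binary masks (`mf_mask` or array; nonzero =
#'   foreground).
#' @return Dice in `[0, 1]`.
#' @export
dice <- function(a, b) {
  a <- .as_grid_array(a) > 0
  b <- .as_grid_array(b) > 0
  if (!all(dim(a) == dim(b))) stop("dice: shape mismatch")
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1.0)
  2 * sum(a & b) / (sa + sb)
}

#' Intersection over union between two binary masks
#'
#' `|A intersect B| / |A union B|`; two empty masks give 1. Satisfies
#' `iou = dice / (2 - dice)`.
#'
#' @inheritParams dice
#' @return IoU in `[0, 1]`.
#' @export
iou <- function(a, b) {
  a <- .as_grid_array(a) > 0
  b <- .as_grid_array(b) > 0
  if (!all(dim(a) == dim(b))) stop("iou: shape mismatch")
  u <- sum(a | b)
  if (u == 0) return(1.0)
  sum(a & b) / u
}

#' Detection-count container
#'
#' Holds fracture-level true-positive, false-positive and false-negative
#' counts, e.g. to evaluate the detection formulas on reported counts.
#'
#' @param tp,fp,fn non-negative integer counts.
#' @param n_scans number of scans the counts were pooled over.
#' @return an `mf_detection` object.
#' @export
detection_result <- function(tp, fp, fn, n_scans = 1L) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  structure(list(tp = tp, fp = fp, fn = fn, n_scans = n_scans,
                 matches = NULL, fn_gt = NULL),
            class = "mf_detection")
}

# Greedy matching of proposals against dilated ground-truth voxel sets.
# gt_sets: named list (by gt id) of voxel index vectors. Proposals are
# visited in descending confidence; each proposal takes the unmatched
# fracture it overlaps most; each side is matched at most once.
.greedy_match <- function(props, gt_sets) {
  ord <- order(vapply(props, `[[`, numeric(1), "confidence"),
               decreasing = TRUE)
  taken <- setNames(rep(FALSE, length(gt_sets)), names(gt_sets))
  matches <- list()
  fp <- integer(0)
  for (i in ord) {
    ov <- vapply(names(gt_sets), function(g) {
      if (taken[[g]]) return(0L)
      length(intersect(props[[i]]$voxels, gt_sets[[g]]))
    }, integer(1))
    if (length(ov) > 0 && max(ov) > 0) {
      g <- names(gt_sets)[which.max(ov)]
      taken[[g]] <- TRUE
      matches[[length(matches) + 1]] <-
        data.frame(proposal = i, gt = as.integer(g), overlap = max(ov))
    } else {
      fp <- c(fp, i)
    }
  }
  list(matches = if (length(matches)) do.call(rbind, matches) else
         data.frame(proposal = integer(0), gt = integer(0),
                    overlap = integer(0)),
       fp = fp, fn_gt = as.integer(names(gt_sets)[!taken]))
}

.gt_sets <- function(gt, gt_dilation_vox) {
  arr <- .as_grid_array(gt)
  ids <- sort(unique(arr[arr > 0]))
  sets <- lapply(ids, function(id) {
    m <- array(as.numeric(arr == id), dim(arr))
    if (gt_dilation_vox > 0) m <- dilate_ball3d_cpp(m, gt_dilation_vox)
    which(m > 0)
  })
  setNames(sets, ids)
}

#' Match fracture proposals against ground truth
#'
#' A proposal hits a fracture if its voxel set intersects the fracture's
#' ground-truth voxels dilated by `gt_dilation_vox` (absorbing one-to-two
#' voxel boundary disagreement on thin planes). Assignment is greedy by
#' descending proposal confidence; each proposal and each fracture is
#' matched at most once. Unmatched proposals are false positives, unmatched
#' fractures false negatives.
#'
#' @param proposals proposal list (see [extract_proposals()]).
#' @param gt labeled ground-truth fracture mask (each fracture its own id).
#' @param gt_dilation_vox dilation radius of the hit criterion.
#' @return an `mf_detection` with counts, the match table and unmatched ids.
#' @export
match_detections <- function(proposals, gt, gt_dilation_vox = 2L) {
  gt_sets <- .gt_sets(gt, gt_dilation_vox)
  m <- .greedy_match(proposals, gt_sets)
  structure(list(tp = nrow(m$matches), fp = length(m$fp),
                 fn = length(m$fn_gt), n_scans = 1L,
                 matches = m$matches, fn_gt = m$fn_gt),
            class = "mf_detection")
}

#' Precision and sensitivity of a detection result
#'
#' `precision = TP / (TP + FP)`, `sensitivity = TP / (TP + FN)`. A zero
#' denominator (no proposals / no fractures) is reported as 1 with the
#' corresponding `degenerate` flag set, so batch evaluation never aborts.
#'
#' @param r an `mf_detection`.
#' @return list with `precision`, `sensitivity` and a 2-element logical
#'   `degenerate` flag vector.
#' @export
precision_sensitivity <- function(r) {
  stopifnot(inherits(r, "mf_detection"))
  dp <- r$tp + r$fp
  ds <- r$tp + r$fn
  list(precision = if (dp > 0) r$tp / dp else 1.0,
       sensitivity = if (ds > 0) r$tp / ds else 1.0,
       degenerate = c(precision = dp == 0, sensitivity = ds == 0))
}

#' Free-response ROC curve
#'
#' For every distinct proposal confidence tau (descending), matching is
#' recomputed on the proposals with confidence at or above tau, pooling true
#' positives over scans; each operating point records the overall
#' sensitivity and the number of false positives per scan. The curve
#' includes the empty-detector endpoint (tau above every confidence).
#'
#' @param scan_results list with one element per scan:
#'   `list(proposals, gt)` where `gt` is the labeled fracture mask.
#'   At least one scan must contain a ground-truth fracture.
#' @param gt_dilation_vox dilation radius of the hit criterion.
#' @return an `mf_froc`: data frame with columns `tau`, `sensitivity`,
#'   `fp_per_scan`, plus attributes `total_gt` and `n_scans`.
#' @export
froc <- function(scan_results, gt_dilation_vox = 2L) {
  n_scans <- length(scan_results)
  prepped <- lapply(scan_results, function(sr) {
    list(props = sr$proposals, gt_sets = .gt_sets(sr$gt, gt_dilation_vox))
  })
  total_gt <- sum(vapply(prepped, function(p) length(p$gt_sets), integer(1)))
  if (total_gt == 0) stop("froc: no ground-truth fractures in any scan")
  confs <- unlist(lapply(prepped, function(p) {
    vapply(p$props, `[[`, numeric(1), "confidence")
  }))
  taus <- c(Inf, sort(unique(confs), decreasing = TRUE))
  rows <- lapply(taus, function(tau) {
    tp <- 0L; fp <- 0L
    for (p in prepped) {
      keep <- Filter(function(pr) pr$confidence >= tau, p$props)
      m <- .greedy_match(keep, p$gt_sets)
      tp <- tp + nrow(m$matches)
      fp <- fp + length(m$fp)
    }
    data.frame(tau = tau, sensitivity = tp / total_gt,
               fp_per_scan = fp / n_scans)
  })
  curve <- do.call(rbind, rows)
  attr(curve, "total_gt") <- total_gt
  attr(curve, "n_scans") <- n_scans
  class(curve) <- c("mf_froc", class(curve))
  curve
}

#' Averaged-sensitivity AUC of a FROC curve
#'
#' For each target false-positive rate, takes the maximum sensitivity among
#' operating points with `fp_per_scan` at or below the target (0 if none),
#' and returns the mean over the targets.
#'
#' @param curve an `mf_froc` from [froc()].
#' @param fp_rates target false positives per scan.
#' @return averaged sensitivity in `[0, 1]`.
#' @export
froc_auc <- function(curve, fp_rates = c(1 / 16, 1 / 8, 1 / 4, 1 / 2, 1)) {
  sens <- vapply(fp_rates, function(r) {
    ok <- curve$fp_per_scan <= r
    if (any(ok)) max(curve$sensitivity[ok]) else 0
  }, numeric(1))
  mean(sens)
}

#' Evaluate fracture detection over a set of scans
#'
#' Pools matching over scans at the pipeline's operating point, computes
#' per-kind sensitivity from the ground-truth fracture kinds, and the FROC
#' curve with its averaged-sensitivity AUC.
#'
#' @param scan_results list with one element per scan:
#'   `list(proposals, gt, records)` (`records` as in [generate_phantom()];
#'   may have zero rows).
#' @param gt_dilation_vox dilation radius of the hit criterion.
#' @return list with `counts` (`mf_detection`), `precision`, `sensitivity`,
#'   `per_kind` sensitivity, `froc` curve and `auc`.
#' @export
evaluate_scans <- function(scan_results, gt_dilation_vox = 2L) {
  tp <- fp <- fn <- 0L
  kind_tp <- c(nondisplaced = 0L, displaced = 0L)
  kind_tot <- c(nondisplaced = 0L, displaced = 0L)
  for (sr in scan_results) {
    m <- match_detections(sr$proposals, sr$gt, gt_dilation_vox)
    tp <- tp + m$tp; fp <- fp + m$fp; fn <- fn + m$fn
    if (!is.null(sr$records) && nrow(sr$records) > 0) {
      for (k in names(kind_tot)) {
        ids <- sr$records$index[sr$records$kind == k]
        kind_tot[k] <- kind_tot[k] + length(ids)
        kind_tp[k] <- kind_tp[k] + sum(m$matches$gt %in% ids)
      }
    }
  }
  res <- detection_result(tp, fp, fn,
                          n_scans = length(scan_results))
  ps <- precision_sensitivity(res)
  with_gt <- Filter(function(sr) any(.as_grid_array(sr$gt) > 0), scan_results)
  curve <- if (length(with_gt) > 0) froc(scan_results, gt_dilation_vox) else NULL
  list(counts = res, precision = ps$precision, sensitivity = ps$sensitivity,
       per_kind = ifelse(kind_tot > 0, kind_tp / kind_tot, NA_real_),
       froc = curve,
       auc = if (!is.null(curve)) froc_auc(curve) else NA_real_)
}
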