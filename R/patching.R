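# Patch extraction and patch-level targets: tiling grids, zero-padded cubic
# patches, per-patch adaptive grayscale windows, relative-position targets,
# softened fracture targets, and balanced patch sampling.

#' Tiling origins for sliding-window patch extraction
#'
#' Origins are spaced `stride` apart along each axis with the last origin
#' clamped to `max(shape - patch_size, 0)` so every voxel is covered by at
#' least one patch; duplicates are removed and origins are sorted
#' lexicographically. Origins are 0-based inclusive corner indices.
#'
#' @param shape integer vector of 3 grid dimensions.
#' @param patch_size cubic patch edge length in voxels.
#' @param stride step between consecutive origins (default half a patch for
#'   50 percent overlap).
#' @return integer matrix with one row per origin and columns (x, y, z).
#' @export
patch_grid <- function(shape, patch_size = 64L, stride = patch_size %/% 2L) {
  stopifnot(length(shape) == 3L, all(shape >= 1L), stride >= 1L)
  ax <- lapply(shape, function(s) {
    last <- max(s - patch_size, 0L)
    sort(unique(c(seq(0L, last, by = stride), last)))
  })
  g <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  g <- g[order(g[, 1], g[, 2], g[, 3]), , drop = FALSE]
  storage.mode(g) <- "integer"
  rownames(g) <- NULL
  g
}

#' Extract a zero-padded cubic patch
#'
#' The region of the parent grid starting at `origin` is copied into a
#' `patch_size` cube; voxels beyond the parent boundary are zero-padded and
#' `valid_extent` records the per-axis count of real voxels. `abs_origin`
#' carries the origin in the coordinates of the outermost parent grid (it
#' differs from `origin` when the grid is a crop).
#'
#' @param v grid object (`mf_volume`, `mf_mask` or `mf_prob`).
#' @param origin 0-based corner voxel index, within the parent grid.
#' @param patch_size cubic patch edge length.
#' @return an `mf_patch`: list with `data` (array of dims
#'   `c(patch_size, patch_size, patch_size, channels)`), `origin`,
#'   `abs_origin`, `valid_extent`.
#' @export
extract_patch <- function(v, origin, patch_size = 64L) {
  stopifnot(inherits(v, "mf_grid"))
  origin <- as.integer(origin)
  shape <- dim(v$data)
  if (any(origin < 0L) || any(origin >= shape)) {
    stop("patch origin outside the parent grid")
  }
  ve <- pmin(patch_size, shape - origin)
  data <- array(0, c(patch_size, patch_size, patch_size, 1L))
  data[seq_len(ve[1]), seq_len(ve[2]), seq_len(ve[3]), 1] <-
    v$data[origin[1] + seq_len(ve[1]), origin[2] + seq_len(ve[2]),
           origin[3] + seq_len(ve[3])]
  structure(
    list(data = data, origin = origin,
         abs_origin = origin + v$index_origin,
         valid_extent = as.integer(ve), parent_shape = shape),
    class = "mf_patch"
  )
}

#' Adaptive grayscale windows for a patch
#'
#' Appends three window channels to a single-channel intensity patch. Each
#' window clips the intensities to a per-patch percentile range — (0, 40),
#' (30, 70) and (60, 100) percent of the valid (non-padded) voxels,
#' emphasizing soft tissue, cancellous bone and cortical bone — and rescales
#' the range to `[0, 1]`. A collapsed window (constant patch) yields an
#' all-zero channel; padded voxels stay zero in every channel.
#'
#' @param p single-channel `mf_patch`.
#' @return `mf_patch` with 4 channels (input + 3 windows).
#' @export
gap_channels <- function(p) {
  stopifnot(inherits(p, "mf_patch"), dim(p$data)[4] == 1L)
  ps <- dim(p$data)[1]
  ve <- p$valid_extent
  valid <- p$data[seq_len(ve[1]), seq_len(ve[2]), seq_len(ve[3]), 1]
  q <- quantile(valid, c(0, .3, .4, .6, .7, 1), names = FALSE)
  ranges <- list(c(q[1], q[3]), c(q[2], q[5]), c(q[4], q[6]))
  out <- array(0, c(ps, ps, ps, 4L))
  out[, , , 1] <- p$data[, , , 1]
  pad_mask <- array(TRUE, c(ps, ps, ps))
  pad_mask[seq_len(ve[1]), seq_len(ve[2]), seq_len(ve[3])] <- FALSE
  for (w in 1:3) {
    lo <- ranges[[w]][1]; hi <- ranges[[w]][2]
    if (hi > lo) {
      ch <- (pmin(pmax(p$data[, , , 1], lo), hi) - lo) / (hi - lo)
      ch[pad_mask] <- 0
      out[, , , w + 1] <- ch
    }
  }
  p$data <- out
  p
}

#' Relative position of a patch within its parent grid
#'
#' Componentwise `(origin + (patch_size - 1) / 2) / (parent_shape - 1)`,
#' clipped to `[0, 1]`; an axis of dimension 1 yields 0.5.
#'
#' @param origin 0-based patch corner index (3 values).
#' @param patch_size cubic patch edge length.
#' @param parent_shape dimensions of the parent grid.
#' @return numeric vector of 3 values in `[0, 1]`.
#' @export
relative_position <- function(origin, patch_size, parent_shape) {
  centre <- origin + (patch_size - 1) / 2
  rel <- ifelse(parent_shape > 1, centre / (parent_shape - 1), 0.5)
  pmin(pmax(rel, 0), 1)
}

#' Soften a binary fracture target
#'
#' Dilates the mask with a Euclidean ball and Gaussian-filters the result to
#' increase the number of positive voxels, then rescales so the peak equals 1
#' (for a nonempty input). An empty mask yields an all-zero map.
#'
#' @param m binary `mf_mask` (any nonzero voxel counts as foreground).
#' @param dilation_radius_vox ball radius in voxels.
#' @param sigma_vox Gaussian standard deviation in voxels (0 skips filtering).
#' @return an `mf_prob` with values in `[0, 1]`.
#' @export
soften_fracture_target <- function(m, dilation_radius_vox = 1, sigma_vox = 0.5) {
  stopifnot(inherits(m, "mf_grid"))
  bin <- array(as.numeric(m$data > 0), dim(m$data))
  if (!any(bin > 0)) return(mf_prob(bin, m$spacing, m$origin))
  d <- if (dilation_radius_vox > 0) dilate_ball3d_cpp(bin, dilation_radius_vox) else bin
  g <- if (sigma_vox > 0) gauss3d_cpp(d, sigma_vox) else d
  g <- g / max(g)
  mf_prob(array(g, dim(m$data)), m$spacing, m$origin)
}

# Random patch origin whose patch is centred near `centre` with +/- jitter,
# clamped so the patch stays inside the grid (assumes shape >= patch_size).
.jittered_origin <- function(centre, patch_size, shape, jitter) {
  o <- centre - patch_size %/% 2 +
    sample.int(2 * jitter + 1, 3, replace = TRUE) - jitter - 1
  pmin(pmax(o, 0L), pmax(shape - patch_size, 0L))
}

#' Sample class-balanced patch pairs
#'
#' Draws exactly `n/2` patches whose target contains at least one positive
#' voxel (each centred on a uniformly drawn positive voxel with random
#' jitter) and `n/2` patches whose target is all zero. Degenerate inputs
#' fall back with a warning: no positive voxels gives an all-negative
#' sample, no all-negative location gives a positive-only sample.
#'
#' @param volume `mf_volume` supplying intensities.
#' @param fracture_target `mf_prob` (or mask) aligned with `volume`.
#' @param n even number of pairs to draw.
#' @param patch_size cubic patch edge length.
#' @param seed optional integer; when given, sampling is a pure function of it.
#' @param jitter maximum voxel jitter of positive-patch centres.
#' @return list of `n` elements, each `list(patch, target, positive)` where
#'   `patch` and `target` are `mf_patch` objects.
#' @export
sample_balanced_patches <- function(volume, fracture_target, n, patch_size = 64L,
                                    seed = NULL, jitter = patch_size %/% 4L) {
  stopifnot(n %% 2 == 0, all(dim(volume$data) == dim(fracture_target$data)))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  shape <- dim(volume$data)
  tgt <- fracture_target$data
  pos_idx <- which(tgt > 0)
  n_pos <- n %/% 2
  n_neg <- n - n_pos
  if (length(pos_idx) == 0) {
    warning("no positive voxels in target; returning an all-negative sample")
    n_pos <- 0; n_neg <- n
  }
  out <- list()
  draw_pos <- function() {
    v <- pos_idx[sample.int(length(pos_idx), 1)]
    centre <- as.integer(arrayInd(v, shape)) - 1L
    o <- .jittered_origin(centre, patch_size, shape, jitter)
    # keep at least one positive voxel inside the patch
    for (try in 1:20) {
      tp <- extract_patch(fracture_target, o, patch_size)
      if (sum(tp$data) > 0) return(o)
      o <- .jittered_origin(centre, patch_size, shape, jitter)
    }
    pmin(pmax(centre - patch_size %/% 2L, 0L), pmax(shape - patch_size, 0L))
  }
  draw_neg <- function() {
    for (try in 1:200) {
      o <- as.integer(floor(runif(3) * pmax(shape - patch_size + 1L, 1L)))
      tp <- extract_patch(fracture_target, o, patch_size)
      if (sum(tp$data) == 0) return(o)
    }
    NULL
  }
  for (i in seq_len(n_pos)) {
    o <- draw_pos()
    out[[length(out) + 1]] <- list(
      patch = extract_patch(volume, o, patch_size),
      target = extract_patch(fracture_target, o, patch_size),
      positive = TRUE
    )
  }
  for (i in seq_len(n_neg)) {
    o <- draw_neg()
    if (is.null(o)) {
      warning("no all-negative patch location found; returning positive-only sample")
      o <- draw_pos()
    }
    tp <- extract_patch(fracture_target, o, patch_size)
    out[[length(out) + 1]] <- list(
      patch = extract_patch(volume, o, patch_size),
      target = tp,
      positive = sum(tp$data) > 0
    )
  }
  out
}
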