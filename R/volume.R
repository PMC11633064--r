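# Volume containers and NIfTI I/O.
#
# Three voxel-grid types share one internal representation: an intensity
# volume (`mf_volume`), an integer label mask (`mf_mask`) and a probability
# map (`mf_prob`). Voxel indices are 0-based with axis order (x, y, z) as
# stored; `index_origin` records where a cropped grid sits inside its parent
# so patch origins can be mapped back to scan coordinates.

.new_grid <- function(data, spacing, origin, class, index_origin = c(0L, 0L, 0L)) {
  if (length(dim(data)) != 3L) stop("grid data must be a 3-d array")
  if (any(dim(data) < 1L)) stop("all grid dimensions must be >= 1")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing must be three strictly positive values (mm)")
  }
  if (any(!is.finite(data))) stop("grid contains non-finite values")
  structure(
    list(data = data, spacing = spacing, origin = as.numeric(origin),
         index_origin = as.integer(index_origin)),
    class = c(class, "mf_grid")
  )
}

#' Construct an intensity volume
#'
#' @param data 3-d numeric array of finite intensities, axis order (x, y, z).
#' @param spacing voxel spacing in mm, three strictly positive values.
#' @param origin world-space position of voxel (0, 0, 0) in mm.
#' @return an `mf_volume` object.
#' @export
mf_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  .new_grid(data, spacing, origin, "mf_volume")
}

#' Construct a label mask
#'
#' Values must be small non-negative integers; 0 is background. Fracture
#' ground-truth masks label each fracture with its own integer id.
#'
#' @inheritParams mf_volume
#' @return an `mf_mask` object.
#' @export
mf_mask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (any(data < 0) || any(data != round(data))) {
    stop("mask values must be non-negative integers")
  }
  .new_grid(data, spacing, origin, "mf_mask")
}

#' Construct a probability map
#'
#' @inheritParams mf_volume
#' @return an `mf_prob` object with all voxel values in `[0, 1]`.
#' @export
mf_prob <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (any(data < -1e-9) || any(data > 1 + 1e-9)) {
    stop("probability values must lie in [0, 1]")
  }
  data[data < 0] <- 0
  data[data > 1] <- 1
  .new_grid(data, spacing, origin, "mf_prob")
}

#' @export
dim.mf_grid <- function(x) dim(x$data)

#' @export
print.mf_grid <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, spacing %s mm\n", class(x)[1],
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x")))
  invisible(x)
}

.as_grid_array <- function(x) {
  if (inherits(x, "mf_grid")) x$data else x
}

#' Read a 3-d volume or mask from a NIfTI file
#'
#' @param path path to a `.nii` or `.nii.gz` file with a 3-d payload.
#' @param kind one of `"intensity"`, `"mask"`, `"prob"`, selecting the
#'   returned container type.
#' @return an [mf_volume()], [mf_mask()] or [mf_prob()] with spacing and
#'   origin taken from the file header.
#' @export
read_volume <- function(path, kind = c("intensity", "mask", "prob")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) {
    stop("expected a 3-d volume, got ", length(d), " dimensions")
  }
  sp <- RNifti::pixdim(img)
  if (length(sp) < 3L || any(!is.finite(sp[1:3])) || any(sp[1:3] <= 0)) {
    stop("non-positive or missing voxel spacing in NIfTI header")
  }
  org <- tryCatch(RNifti::xform(img)[1:3, 4], error = function(e) c(0, 0, 0))
  data <- array(as.numeric(img), d)
  if (any(!is.finite(data))) stop("volume contains non-finite intensities")
  switch(kind,
    intensity = mf_volume(data, sp[1:3], org),
    mask = mf_mask(array(as.integer(round(data)), d), sp[1:3], org),
    prob = mf_prob(data, sp[1:3], org)
  )
}

#' Write a volume, mask or probability map to NIfTI
#'
#' Masks are stored as unsigned 8-bit integers, intensity volumes and
#' probability maps as 32-bit floats.
#'
#' @param v an `mf_volume`, `mf_mask` or `mf_prob`.
#' @param path output path (`.nii` or `.nii.gz`); parent directory must exist.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "mf_grid"))
  if (!dir.exists(dirname(path))) {
    stop("directory does not exist: ", dirname(path))
  }
  img <- RNifti::asNifti(v$data)
  RNifti::pixdim(img) <- v$spacing
  aff <- diag(4)
  diag(aff)[1:3] <- v$spacing
  aff[1:3, 4] <- v$origin
  RNifti::`qform<-`(img, structure(aff, code = 2L))
  dtype <- if (inherits(v, "mf_mask")) "uint8" else "float"
  RNifti::writeNifti(img, path, datatype = dtype)
  invisible(path)
}

#' Resample a grid to isotropic spacing
#'
#' Output dimension along each axis is `round(dim * spacing / target)` with a
#' minimum of 1. Masks use nearest-neighbour interpolation (`order = 0`),
#' intensities and probabilities trilinear (`order = 1`).
#'
#' @param v grid object to resample.
#' @param target_spacing_mm target isotropic spacing, strictly positive.
#' @param order interpolation order, 0 (nearest) or 1 (trilinear); defaults
#'   to 0 for masks and 1 otherwise.
#' @return resampled grid of the same type.
#' @export
resample_isotropic <- function(v, target_spacing_mm,
                               order = if (inherits(v, "mf_mask")) 0L else 1L) {
  stopifnot(inherits(v, "mf_grid"))
  if (!is.finite(target_spacing_mm) || target_spacing_mm <= 0) {
    stop("target_spacing_mm must be strictly positive")
  }
  if (!order %in% c(0L, 1L)) stop("order must be 0 or 1")
  d <- dim(v$data)
  out_dim <- pmax(1L, as.integer(round(d * v$spacing / target_spacing_mm)))
  ratio <- target_spacing_mm / v$spacing
  out <- resample3d_cpp(v$data, out_dim, ratio, as.integer(order))
  cls <- class(v)[1]
  switch(cls,
    mf_volume = mf_volume(out, rep(target_spacing_mm, 3), v$origin),
    mf_mask = mf_mask(out, rep(target_spacing_mm, 3), v$origin),
    mf_prob = mf_prob(out, rep(target_spacing_mm, 3), v$origin)
  )
}

#' Percentile-normalize intensities to [0, 1]
#'
#' Intensities are clipped to the `[low_pct, high_pct]` percentile interval
#' and affinely rescaled to `[0, 1]`. CBCT has no calibrated HU scale, so this
#' robust per-volume normalization is applied before adaptive windowing.
#' A constant volume maps to all zeros.
#'
#' @param v an `mf_volume`.
#' @param low_pct,high_pct clipping percentiles, `0 <= low_pct < high_pct <= 100`.
#' @return normalized `mf_volume` with values in `[0, 1]`.
#' @export
normalize_intensities <- function(v, low_pct = 0.5, high_pct = 99.5) {
  stopifnot(inherits(v, "mf_volume"))
  if (!(low_pct >= 0 && low_pct < high_pct && high_pct <= 100)) {
    stop("need 0 <= low_pct < high_pct <= 100")
  }
  q <- quantile(v$data, c(low_pct, high_pct) / 100, names = FALSE)
  if (q[2] <= q[1]) {
    return(mf_volume(array(0, dim(v$data)), v$spacing, v$origin))
  }
  x <- pmin(pmax(v$data, q[1]), q[2])
  mf_volume(array((x - q[1]) / (q[2] - q[1]), dim(v$data)), v$spacing, v$origin)
}
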