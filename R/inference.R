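# Scan-level inference: sliding-window mandible segmentation, cropping to
# the predicted mandible, stage-2/3 fracture maps, connected-component
# proposal extraction, confidence filtering and stage union.

#' Pipeline configuration
#'
#' Defaults: 64-cube patches with stride 32 (50 percent overlap), both maps
#' binarized at 0.5, components at 26-connectivity, minimum proposal size 10
#' voxels, confidence threshold 0.5, crop margin 10 voxels, and stage-3
#' evidence gated by the predicted mandible dilated by 3 voxels (fracture
#' proposals outside bone are discarded).
#'
#' @param patch_size cubic patch edge length.
#' @param stride tiling stride.
#' @param mandible_threshold probability threshold for the mandible crop.
#' @param crop_margin_vox margin added around the mandible bounding box.
#' @param seg_threshold,cls_threshold binarization thresholds of the
#'   stage-2 and stage-3 maps.
#' @param min_size_vox minimum proposal size in voxels.
#' @param tau confidence threshold for final filtering.
#' @param connectivity voxel connectivity (6, 18 or 26) for components.
#' @param gate_dilation_vox dilation radius of the mandible gate applied to
#'   the stage-3 map.
#' @param batch_size patches per forward batch.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(patch_size = 64L, stride = 32L,
                            mandible_threshold = 0.5, crop_margin_vox = 10L,
                            seg_threshold = 0.5, cls_threshold = 0.5,
                            min_size_vox = 10L, tau = 0.5,
                            connectivity = 26L, gate_dilation_vox = 3L,
                            batch_size = 4L) {
  structure(list(patch_size = as.integer(patch_size),
                 stride = as.integer(stride),
                 mandible_threshold = mandible_threshold,
                 crop_margin_vox = as.integer(crop_margin_vox),
                 seg_threshold = seg_threshold, cls_threshold = cls_threshold,
                 min_size_vox = as.integer(min_size_vox), tau = tau,
                 connectivity = as.integer(connectivity),
                 gate_dilation_vox = as.integer(gate_dilation_vox),
                 batch_size = as.integer(batch_size)),
            class = "pipeline_config")
}

.axis_origins <- function(shape, patch_size, stride) {
  lapply(shape, function(s) {
    last <- max(s - patch_size, 0L)
    sort(unique(c(seq(0L, last, by = stride), last)))
  })
}

# Add patch-shaped values into accumulator arrays over the patch's valid
# region (handles grids smaller than the patch).
.accumulate_patch <- function(acc, cnt, vals, origin, ve) {
  ix <- origin[1] + seq_len(ve[1])
  iy <- origin[2] + seq_len(ve[2])
  iz <- origin[3] + seq_len(ve[3])
  acc[ix, iy, iz] <- acc[ix, iy, iz] + vals[seq_len(ve[1]), seq_len(ve[2]),
                                            seq_len(ve[3])]
  cnt[ix, iy, iz] <- cnt[ix, iy, iz] + 1
  list(acc = acc, cnt = cnt)
}

#' Sliding-window mandible segmentation
#'
#' Tiles the volume, runs the stage-1 forward pass on the adaptive-window
#' channels of every patch, and averages sigmoid probabilities over
#' overlapping patches.
#'
#' @param v resampled, normalized `mf_volume`.
#' @param s1 trained stage-1 model (or oracle).
#' @param config a [pipeline_config()].
#' @return an `mf_prob` mandible probability map aligned with `v`.
#' @export
segment_mandible <- function(v, s1, config = pipeline_config()) {
  shape <- dim(v$data)
  origins <- patch_grid(shape, config$patch_size, config$stride)
  acc <- array(0, shape); cnt <- array(0, shape)
  idx <- seq_len(nrow(origins))
  for (chunk in split(idx, ceiling(idx / config$batch_size))) {
    patches <- lapply(chunk, function(i) {
      gap_channels(extract_patch(v, origins[i, ], config$patch_size))
    })
    out <- stage1_forward(s1, patches, training = FALSE)
    probs <- sigmoid(out$logits)
    for (j in seq_along(chunk)) {
      p <- patches[[j]]
      r <- .accumulate_patch(acc, cnt, array(probs[, , , 1, j],
                                             dim(p$data)[1:3]),
                             p$origin, p$valid_extent)
      acc <- r$acc; cnt <- r$cnt
    }
  }
  mf_prob(acc / pmax(cnt, 1), v$spacing, v$origin)
}

#' Crop a volume to the predicted mandible
#'
#' Takes the bounding box of voxels with probability at or above the
#' threshold, expands it by a margin, and clips to the grid. If the
#' segmentation is empty the full volume is returned with a warning. The
#' crop offset is recorded on the returned grids (`index_origin`) so patch
#' origins and proposals can be mapped back to scan coordinates.
#'
#' @param v `mf_volume` to crop.
#' @param mandible_prob aligned `mf_prob`.
#' @param threshold probability threshold.
#' @param margin_vox margin in voxels.
#' @return list with `volume` (cropped), `mandible` (cropped probability
#'   map) and `offset` (0-based corner of the crop in `v`).
#' @export
crop_to_mandible <- function(v, mandible_prob, threshold = 0.5,
                             margin_vox = 10L) {
  stopifnot(all(dim(v$data) == dim(mandible_prob$data)))
  fg <- which(mandible_prob$data >= threshold)
  shape <- dim(v$data)
  if (length(fg) == 0) {
    warning("empty mandible segmentation; using the full volume")
    lo <- c(1L, 1L, 1L); hi <- shape
  } else {
    ind <- arrayInd(fg, shape)
    lo <- pmax(apply(ind, 2, min) - margin_vox, 1L)
    hi <- pmin(apply(ind, 2, max) + margin_vox, shape)
  }
  sub <- v$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  subm <- mandible_prob$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  offset <- as.integer(lo - 1L)
  cv <- mf_volume(array(sub, hi - lo + 1L), v$spacing, v$origin)
  cv$index_origin <- offset + v$index_origin
  cm <- mf_prob(array(subm, hi - lo + 1L), v$spacing, v$origin)
  cm$index_origin <- cv$index_origin
  list(volume = cv, mandible = cm, offset = offset)
}

# Trilinear interpolation of per-patch values laid out on the rectilinear
# lattice of patch centres, extended to border voxels by clamping into the
# lattice hull.
.lattice_interp <- function(centers, P, shape) {
  axis_iw <- lapply(1:3, function(a) {
    cts <- centers[[a]]
    t <- pmin(pmax(seq_len(shape[a]) - 1, cts[1]), cts[length(cts)])
    if (length(cts) == 1) return(list(k = rep(1L, shape[a]),
                                      w = rep(0, shape[a])))
    k <- findInterval(t, cts, all.inside = TRUE)
    w <- (t - cts[k]) / (cts[k + 1] - cts[k])
    list(k = k, w = w)
  })
  out <- array(0, shape)
  nd <- dim(P)
  for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
    kx <- pmin(axis_iw[[1]]$k + a, nd[1])
    ky <- pmin(axis_iw[[2]]$k + b, nd[2])
    kz <- pmin(axis_iw[[3]]$k + cc, nd[3])
    wx <- if (a == 0) 1 - axis_iw[[1]]$w else axis_iw[[1]]$w
    wy <- if (b == 0) 1 - axis_iw[[2]]$w else axis_iw[[2]]$w
    wz <- if (cc == 0) 1 - axis_iw[[3]]$w else axis_iw[[3]]$w
    W <- array(wx, shape) *
      array(rep(wy, each = shape[1]), shape) *
      array(rep(wz, each = shape[1] * shape[2]), shape)
    out <- out + W * P[kx, ky, kz, drop = FALSE]
  }
  out
}

#' Voxel-level fracture maps from stages 2 and 3
#'
#' `seg_map` is the overlap-averaged sigmoid of the stage-2 second-network
#' logits. `cls_map` carries each patch's stage-3 probability at the patch
#' centre and is interpolated trilinearly over the lattice of centres,
#' extended to border voxels by the nearest lattice value.
#'
#' @param cropped cropped, normalized `mf_volume`.
#' @param s1,s2,s3 trained stage models (or oracles).
#' @param config a [pipeline_config()].
#' @return list of two `mf_prob` maps: `seg` and `cls`.
#' @export
fracture_maps <- function(cropped, s1, s2, s3, config = pipeline_config()) {
  shape <- dim(cropped$data)
  ps <- config$patch_size
  ax <- .axis_origins(shape, ps, config$stride)
  origins <- patch_grid(shape, ps, config$stride)
  acc <- array(0, shape); cnt <- array(0, shape)
  cls_p <- array(0, c(length(ax[[1]]), length(ax[[2]]), length(ax[[3]])))
  idx <- seq_len(nrow(origins))
  for (chunk in split(idx, ceiling(idx / config$batch_size))) {
    patches <- lapply(chunk, function(i) extract_patch(cropped, origins[i, ], ps))
    c2 <- .stage2_context(s1, patches)
    s2o <- stage2_forward(s2, c2$ctx, patches, training = FALSE)
    ctx3 <- .cat_ch(c2$ctx, s2o$logits_b)
    s3o <- stage3_forward(s3, ctx3, patches, training = FALSE)
    probs2 <- sigmoid(s2o$logits_b)
    probs3 <- sigmoid(as.numeric(s3o$logits))
    for (j in seq_along(chunk)) {
      p <- patches[[j]]
      r <- .accumulate_patch(acc, cnt, array(probs2[, , , 1, j], rep(ps, 3)),
                             p$origin, p$valid_extent)
      acc <- r$acc; cnt <- r$cnt
      o <- origins[chunk[j], ]
      cls_p[match(o[1], ax[[1]]), match(o[2], ax[[2]]), match(o[3], ax[[3]])] <-
        probs3[j]
    }
  }
  centers <- lapply(1:3, function(a) ax[[a]] + (ps - 1) / 2)
  cls <- .lattice_interp(centers, cls_p, shape)
  seg <- mf_prob(acc / pmax(cnt, 1), cropped$spacing, cropped$origin)
  seg$index_origin <- cropped$index_origin
  clsm <- mf_prob(pmin(pmax(cls, 0), 1), cropped$spacing, cropped$origin)
  clsm$index_origin <- cropped$index_origin
  list(seg = seg, cls = clsm)
}

#' Extract fracture proposals from a probability map
#'
#' Binarizes the map at a threshold, labels connected components, drops
#' components below the minimum size, and scores each survivor by the mean
#' of `confidence_source` over its voxels. Proposals are sorted by
#' descending confidence.
#'
#' @param map `mf_prob` (or 3-d array).
#' @param threshold binarization threshold.
#' @param connectivity 6, 18 or 26.
#' @param min_size_vox minimum component size in voxels.
#' @param confidence_source aligned probability map scoring the proposals;
#'   defaults to `map` itself.
#' @param source tag recorded on each proposal (`"stage2"` or `"stage3"`).
#' @return list of proposals: `list(voxels, shape, source, confidence, size)`
#'   with `voxels` 1-based linear indices into the map's grid.
#' @export
extract_proposals <- function(map, threshold = 0.5, connectivity = 26L,
                              min_size_vox = 10L, confidence_source = map,
                              source = "stage2") {
  arr <- .as_grid_array(map)
  conf_arr <- .as_grid_array(confidence_source)
  stopifnot(all(dim(arr) == dim(conf_arr)))
  bin <- array(as.numeric(arr >= threshold), dim(arr))
  if (!any(bin > 0)) return(list())
  lab <- label3d_cpp(bin, as.integer(connectivity))
  fg <- which(lab > 0)
  comps <- split(fg, lab[fg])
  props <- list()
  for (vx in comps) {
    if (length(vx) < min_size_vox) next
    props[[length(props) + 1]] <- list(
      voxels = sort(vx), shape = dim(arr), source = source,
      confidence = mean(conf_arr[vx]), size = length(vx))
  }
  props[order(vapply(props, `[[`, numeric(1), "confidence"),
              decreasing = TRUE)]
}

#' Unite stage-2 and stage-3 proposals
#'
#' Proposals whose voxel sets intersect are merged into one proposal (voxel
#' union, source `"merged"`, confidence the maximum of the parents); merging
#' is transitive over the overlap graph. Non-overlapping proposals pass
#' through unchanged. The result is sorted by descending confidence.
#'
#' @param p2,p3 proposal lists in the same coordinate space
#'   (see [extract_proposals()]).
#' @return merged proposal list.
#' @export
unite_proposals <- function(p2, p3) {
  all_p <- c(p2, p3)
  n <- length(all_p)
  if (n == 0) return(list())
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (length(intersect(all_p[[i]]$voxels, all_p[[j]]$voxels)) > 0) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  out <- list()
  for (r in unique(roots)) {
    members <- all_p[roots == r]
    if (length(members) == 1) {
      out[[length(out) + 1]] <- members[[1]]
    } else {
      out[[length(out) + 1]] <- list(
        voxels = sort(unique(unlist(lapply(members, `[[`, "voxels")))),
        shape = members[[1]]$shape, source = "merged",
        confidence = max(vapply(members, `[[`, numeric(1), "confidence")),
        size = length(unique(unlist(lapply(members, `[[`, "voxels")))))
    }
  }
  out[order(vapply(out, `[[`, numeric(1), "confidence"), decreasing = TRUE)]
}

#' Filter proposals by confidence
#'
#' @param props proposal list.
#' @param tau confidence threshold in `[0, 1]`; proposals with confidence
#'   `>= tau` survive, order preserved.
#' @return filtered proposal list.
#' @export
filter_by_confidence <- function(props, tau) {
  stopifnot(tau >= 0, tau <= 1)
  Filter(function(p) p$confidence >= tau, props)
}

# Map proposals from crop coordinates to the parent grid.
.shift_proposals <- function(props, offset, full_shape) {
  lapply(props, function(p) {
    ind <- arrayInd(p$voxels, p$shape)
    ind <- ind + matrix(offset, nrow(ind), 3, byrow = TRUE)
    p$voxels <- sort(ind[, 1] + (ind[, 2] - 1) * full_shape[1] +
                       (ind[, 3] - 1) * full_shape[1] * full_shape[2])
    p$shape <- full_shape
    p
  })
}

# Embed a cropped map into the full grid (zeros outside the crop).
.embed_map <- function(m, offset, full_shape, spacing, origin) {
  out <- array(0, full_shape)
  d <- dim(m$data)
  out[offset[1] + seq_len(d[1]), offset[2] + seq_len(d[2]),
      offset[3] + seq_len(d[3])] <- m$data
  mf_prob(out, spacing, origin)
}

#' Run the full fracture-detection pipeline on one scan
#'
#' Segments the mandible, crops to it, computes the stage-2 and stage-3
#' fracture maps, extracts connected-component proposals from each (the
#' stage-3 map gated by the dilated predicted mandible), unites overlapping
#' proposals across stages, and filters by confidence. Proposals are
#' returned in the original scan's voxel coordinates.
#'
#' @param v resampled, normalized `mf_volume` on the working grid.
#' @param stages list with trained (or oracle) `s1`, `s2`, `s3`.
#' @param config a [pipeline_config()].
#' @return list with `proposals` (confidence-filtered), `all_proposals`
#'   (before filtering), `mandible_map`, `seg_map`, `cls_map` (all full-grid
#'   `mf_prob`) and `offset` (crop corner).
#' @export
run_pipeline <- function(v, stages, config = pipeline_config()) {
  shape <- dim(v$data)
  mand <- segment_mandible(v, stages$s1, config)
  cr <- crop_to_mandible(v, mand, config$mandible_threshold,
                         config$crop_margin_vox)
  maps <- fracture_maps(cr$volume, stages$s1, stages$s2, stages$s3, config)
  gate <- dilate_ball3d_cpp(
    array(as.numeric(cr$mandible$data >= config$mandible_threshold),
          dim(cr$mandible$data)),
    config$gate_dilation_vox)
  cls_gated <- maps$cls
  cls_gated$data <- maps$cls$data * array(gate, dim(maps$cls$data))
  p2 <- extract_proposals(maps$seg, config$seg_threshold, config$connectivity,
                          config$min_size_vox, maps$seg, "stage2")
  p3 <- extract_proposals(cls_gated, config$cls_threshold, config$connectivity,
                          config$min_size_vox, cls_gated, "stage3")
  p2 <- .shift_proposals(p2, cr$offset, shape)
  p3 <- .shift_proposals(p3, cr$offset, shape)
  united <- unite_proposals(p2, p3)
  list(proposals = filter_by_confidence(united, config$tau),
       all_proposals = united,
       mandible_map = mand,
       seg_map = .embed_map(maps$seg, cr$offset, shape, v$spacing, v$origin),
       cls_map = .embed_map(cls_gated, cr$offset, shape, v$spacing, v$origin),
       offset = cr$offset)
}

#' Tabulate proposals
#'
#' @param props proposal list from [run_pipeline()] or
#'   [extract_proposals()].
#' @param spacing voxel spacing in mm used for the centroid in mm.
#' @return data frame with one row per proposal: id, source, confidence,
#'   size, centroid in voxel and mm coordinates.
#' @export
proposals_table <- function(props, spacing = c(1, 1, 1)) {
  if (length(props) == 0) {
    return(data.frame(id = integer(0), source = character(0),
                      confidence = numeric(0), size = integer(0),
                      cx = numeric(0), cy = numeric(0), cz = numeric(0),
                      cx_mm = numeric(0), cy_mm = numeric(0),
                      cz_mm = numeric(0)))
  }
  rows <- lapply(seq_along(props), function(i) {
    p <- props[[i]]
    ind <- arrayInd(p$voxels, p$shape)
    ctr <- colMeans(ind) - 1
    data.frame(id = i, source = p$source, confidence = p$confidence,
               size = p$size, cx = ctr[1], cy = ctr[2], cz = ctr[3],
               cx_mm = ctr[1] * spacing[1], cy_mm = ctr[2] * spacing[2],
               cz_mm = ctr[3] * spacing[3])
  })
  do.call(rbind, rows)
}
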