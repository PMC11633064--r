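# Synthetic mandible phantoms with planted fractures and exact ground truth.
#
# The mandible surrogate is a half-torus ("horseshoe") with a bright cortical
# shell and dimmer cancellous interior on a dark soft-tissue background.
# Nondisplaced fractures are thin low-intensity planes crossing the bone;
# displaced fractures rigidly translate all bone beyond a plane along its
# normal, leaving a gap, with the ground truth marking the one-voxel-thick
# interface band on both new surfaces. Geometry is evaluated by backward
# mapping, so several displaced fractures compose consistently.

#' Phantom specification
#'
#' Defaults define a 96-cube at 0.4 mm spacing: a desk-scale arch whose
#' cortical/cancellous/background intensity means live on the normalized
#' `[0, 1]` scale. Identical spec + seed gives a bit-identical phantom.
#'
#' @param shape grid dimensions (3 integers).
#' @param spacing_mm isotropic voxel spacing in mm.
#' @param arch_radius_mm radius of the arch midline circle.
#' @param bone_radius_mm radius of the bone cross-section.
#' @param cortical_thickness_mm thickness of the bright cortical shell.
#' @param cortical_intensity,cancellous_intensity,background_intensity
#'   intensity means, ordered background < cancellous < cortical.
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param n_fractures number of fractures to plant (0-3).
#' @param displaced_fraction probability a planted fracture is displaced.
#' @param displacement_mm rigid offset magnitude for displaced fractures.
#' @param plane_thickness_mm gap width of nondisplaced fracture planes.
#' @param tilt_deg maximum random tilt of a fracture plane away from the
#'   arch tangent.
#' @param min_separation_deg minimum angular separation between fracture
#'   sites along the arch.
#' @param kinds optional character vector of length `n_fractures` fixing
#'   each fracture's kind (`"nondisplaced"`/`"displaced"`) instead of
#'   drawing from `displaced_fraction`.
#' @param seed integer seed controlling all randomness.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(96L, 96L, 96L), spacing_mm = 0.4,
                         arch_radius_mm = 12, bone_radius_mm = 4,
                         cortical_thickness_mm = 1.2,
                         cortical_intensity = 0.85,
                         cancellous_intensity = 0.45,
                         background_intensity = 0.15,
                         noise_sd = 0.05, n_fractures = 1L,
                         displaced_fraction = 0.28, displacement_mm = 2,
                         plane_thickness_mm = 0.8, tilt_deg = 15,
                         min_separation_deg = 45, kinds = NULL, seed = 1L) {
  spec <- list(
    shape = as.integer(shape), spacing_mm = spacing_mm,
    arch_radius_mm = arch_radius_mm, bone_radius_mm = bone_radius_mm,
    cortical_thickness_mm = cortical_thickness_mm,
    cortical_intensity = cortical_intensity,
    cancellous_intensity = cancellous_intensity,
    background_intensity = background_intensity,
    noise_sd = noise_sd, n_fractures = as.integer(n_fractures),
    displaced_fraction = displaced_fraction,
    displacement_mm = displacement_mm,
    plane_thickness_mm = plane_thickness_mm, tilt_deg = tilt_deg,
    min_separation_deg = min_separation_deg, kinds = kinds,
    seed = as.integer(seed)
  )
  with(spec, {
    stopifnot(length(shape) == 3, all(shape >= 8), spacing_mm > 0,
              background_intensity < cancellous_intensity,
              cancellous_intensity < cortical_intensity,
              plane_thickness_mm > 0, displacement_mm > 0,
              n_fractures >= 0, n_fractures <= 3,
              displaced_fraction >= 0, displaced_fraction <= 1,
              is.null(kinds) || (length(kinds) == n_fractures &&
                all(kinds %in% c("nondisplaced", "displaced"))))
  })
  structure(spec, class = "phantom_spec")
}

# Unit normal near the arch tangent at angle theta, tilted by a random
# rotation of at most tilt_deg.
.fracture_normal <- function(theta, tilt_deg) {
  n <- c(-sin(theta), cos(theta), 0)
  ax <- rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  ang <- runif(1, 0, tilt_deg * pi / 180)
  # Rodrigues rotation of n about ax by ang
  n2 <- n * cos(ang) + .cross3(ax, n) * sin(ang) +
    ax * sum(ax * n) * (1 - cos(ang))
  n2 / sqrt(sum(n2^2))
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Generate a mandible phantom
#'
#' @param spec a [phantom_spec()].
#' @return list with `volume` ([mf_volume()]), `mandible` (binary
#'   [mf_mask()]), `fracture` ([mf_mask()] labeling each fracture with its
#'   index), and `records`, a data frame with one row per planted fracture
#'   (index, kind, plane point and unit normal in mm, ground-truth voxel
#'   count). Fractures whose plane misses the bone are re-sampled up to a
#'   retry cap and then dropped with a warning.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  sh <- spec$shape
  sp <- spec$spacing_mm
  nvox <- prod(sh)
  ctr <- (sh - 1) / 2 * sp
  # voxel centre coordinates in mm
  ix <- (seq_len(sh[1]) - 1) * sp
  iy <- (seq_len(sh[2]) - 1) * sp
  iz <- (seq_len(sh[3]) - 1) * sp
  qx <- array(rep(ix, times = sh[2] * sh[3]), sh)
  qy <- array(rep(rep(iy, each = sh[1]), times = sh[3]), sh)
  qz <- array(rep(iz, each = sh[1] * sh[2]), sh)

  # choose fracture sites along the arch with minimum angular separation
  kinds <- character(0)
  thetas <- numeric(0)
  normals <- list()
  points <- list()
  n_try <- 0
  while (length(thetas) < spec$n_fractures && n_try < 100) {
    n_try <- n_try + 1
    th <- runif(1, 20, 160) * pi / 180
    if (length(thetas) &&
        min(abs(th - thetas)) < spec$min_separation_deg * pi / 180) next
    thetas <- c(thetas, th)
    kinds <- c(kinds, if (!is.null(spec$kinds)) spec$kinds[length(thetas)]
               else if (runif(1) < spec$displaced_fraction) "displaced"
               else "nondisplaced")
    points[[length(thetas)]] <- c(ctr[1] + spec$arch_radius_mm * cos(th),
                                  ctr[2] + spec$arch_radius_mm * sin(th),
                                  ctr[3])
    normals[[length(thetas)]] <- .fracture_normal(th, spec$tilt_deg)
  }
  ord <- order(thetas)
  thetas <- thetas[ord]; kinds <- kinds[ord]
  points <- points[ord]; normals <- normals[ord]

  # backward-map displaced fractures (proximal to distal) and record the
  # plane offset field of every fracture in its own frame
  gap <- array(FALSE, sh)
  s_fields <- vector("list", length(thetas))
  for (i in seq_along(thetas)) {
    n <- normals[[i]]; p0 <- points[[i]]
    s <- n[1] * (qx - p0[1]) + n[2] * (qy - p0[2]) + n[3] * (qz - p0[3])
    s_fields[[i]] <- s
    if (kinds[i] == "displaced") {
      d <- spec$displacement_mm
      gap <- gap | (s > 0 & s <= d)
      mv <- s > d
      qx[mv] <- qx[mv] - d * n[1]
      qy[mv] <- qy[mv] - d * n[2]
      qz[mv] <- qz[mv] - d * n[3]
    }
  }

  rho <- sqrt((qx - ctr[1])^2 + (qy - ctr[2])^2)
  td <- sqrt((rho - spec$arch_radius_mm)^2 + (qz - ctr[3])^2)
  bone <- td <= spec$bone_radius_mm & qy >= ctr[2] & !gap
  cortical <- bone & td >= spec$bone_radius_mm - spec$cortical_thickness_mm

  vol <- array(spec$background_intensity, sh)
  vol[bone] <- spec$cancellous_intensity
  vol[cortical] <- spec$cortical_intensity

  frac <- array(0L, sh)
  records <- list()
  kept <- 0L
  for (i in seq_along(thetas)) {
    s <- s_fields[[i]]; p0 <- points[[i]]
    local <- (qx - p0[1])^2 + (qy - p0[2])^2 + (qz - p0[3])^2 <=
      (2.5 * spec$bone_radius_mm)^2
    if (kinds[i] == "nondisplaced") {
      m <- bone & local & abs(s) <= spec$plane_thickness_mm / 2
      vol[m] <- spec$background_intensity + 0.05
    } else {
      d <- spec$displacement_mm
      m <- bone & local & ((s >= -sp & s <= 0) | (s > d & s <= d + sp))
    }
    cnt <- sum(m)
    if (cnt == 0) {
      warning("fracture plane missed the bone; fracture dropped")
      next
    }
    kept <- kept + 1L
    frac[m] <- kept
    records[[kept]] <- data.frame(
      index = kept, kind = kinds[i],
      px = p0[1], py = p0[2], pz = p0[3],
      nx = normals[[i]][1], ny = normals[[i]][2], nz = normals[[i]][3],
      gt_voxel_count = cnt
    )
  }
  records <- if (kept > 0) do.call(rbind, records) else
    data.frame(index = integer(0), kind = character(0), px = numeric(0),
               py = numeric(0), pz = numeric(0), nx = numeric(0),
               ny = numeric(0), nz = numeric(0), gt_voxel_count = integer(0))

  if (spec$noise_sd > 0) {
    vol <- vol + array(rnorm(nvox, sd = spec$noise_sd), sh)
  }
  vol <- pmin(pmax(vol, 0), 1)

  spc <- rep(sp, 3)
  list(volume = mf_volume(array(vol, sh), spc),
       mandible = mf_mask(array(as.integer(bone), sh), spc),
       fracture = mf_mask(frac, spc),
       records = records)
}

# Per-scan fracture count for fractured scans, mirroring a cohort where one
# fracture is most common and three or more are rare.
.draw_fracture_count <- function() sample(1:3, 1, prob = c(0.63, 0.29, 0.08))

#' Generate an in-memory phantom dataset
#'
#' Scan-level seeds are `spec$seed + scan index`, so any single scan can be
#' regenerated in isolation. Exactly `round(n_scans * fractured_fraction)`
#' scans carry at least one fracture.
#'
#' @param n_scans number of phantoms.
#' @param spec base [phantom_spec()]; per-scan seed and fracture count
#'   override its `seed`/`n_fractures`.
#' @param fractured_fraction fraction of scans with fractures in `[0, 1]`.
#' @return list of scans, each as returned by [generate_phantom()] plus
#'   `scan_id` and `seed`.
#' @export
phantom_dataset <- function(n_scans, spec = phantom_spec(),
                            fractured_fraction = 0.5) {
  stopifnot(n_scans >= 1)
  n_fractured <- round(n_scans * fractured_fraction)
  set.seed(spec$seed)
  fractured <- sort(sample.int(n_scans, n_fractured))
  scans <- vector("list", n_scans)
  for (i in seq_len(n_scans)) {
    si <- spec
    si$seed <- spec$seed + i
    set.seed(si$seed)
    si$n_fractures <- if (i %in% fractured) .draw_fracture_count() else 0L
    sc <- generate_phantom(si)
    sc$scan_id <- sprintf("scan_%03d", i)
    sc$seed <- si$seed
    scans[[i]] <- sc
  }
  scans
}

.scan_manifest_rows <- function(sc) {
  if (nrow(sc$records) == 0) {
    data.frame(scan_id = sc$scan_id, split = NA_character_,
               fracture_id = NA_integer_, kind = "none",
               voxel_count = 0L, seed = sc$seed)
  } else {
    data.frame(scan_id = sc$scan_id, split = NA_character_,
               fracture_id = sc$records$index, kind = sc$records$kind,
               voxel_count = sc$records$gt_voxel_count, seed = sc$seed)
  }
}

#' Write a phantom dataset to disk
#'
#' Writes one NIfTI triple (volume, mandible mask, labeled fracture mask)
#' per scan plus a CSV manifest with one row per fracture (scans without
#' fractures get a single row with kind `"none"`).
#'
#' @inheritParams phantom_dataset
#' @param out_dir output directory (created if missing).
#' @return the manifest data frame, invisibly; also written as
#'   `manifest.csv` in `out_dir`.
#' @export
make_dataset <- function(n_scans, spec = phantom_spec(), out_dir,
                         fractured_fraction = 0.5) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  scans <- phantom_dataset(n_scans, spec, fractured_fraction)
  rows <- list()
  for (sc in scans) {
    write_volume(sc$volume, file.path(out_dir, paste0(sc$scan_id, "_vol.nii.gz")))
    write_volume(sc$mandible, file.path(out_dir, paste0(sc$scan_id, "_mandible.nii.gz")))
    write_volume(sc$fracture, file.path(out_dir, paste0(sc$scan_id, "_fracture.nii.gz")))
    rows[[length(rows) + 1]] <- .scan_manifest_rows(sc)
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

# Scan-level stratum: the set of fracture kinds present.
.scan_stratum <- function(kinds) {
  k <- unique(kinds[kinds != "none"])
  if (length(k) == 0) "none" else if (length(k) == 1) k else "mixed"
}

#' Stratified scan-level train/validation/test split
#'
#' Partitions scans (never fractures) into three splits. Within each stratum
#' — fracture kind, plus the no-fracture stratum — split sizes follow the
#' target fractions by largest-remainder allocation, so each deviates from
#' `fraction * stratum size` by at most one scan. Strata with fewer scans
#' than splits are pooled and assigned by a global shuffle with a warning.
#'
#' @param manifest manifest data frame from [make_dataset()] /
#'   [phantom_dataset()] rows.
#' @param fractions three split fractions summing to 1.
#' @param seed integer seed for the within-stratum shuffles.
#' @return the manifest with its `split` column filled
#'   (`"train"`/`"val"`/`"test"`).
#' @export
split_dataset <- function(manifest, fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  stopifnot(abs(sum(fractions) - 1) < 1e-9, length(fractions) == 3)
  set.seed(seed)
  labels <- c("train", "val", "test")
  scans <- unique(manifest$scan_id)
  strata <- vapply(scans, function(s) {
    .scan_stratum(manifest$kind[manifest$scan_id == s])
  }, character(1))
  assign_split <- setNames(rep(NA_character_, length(scans)), scans)
  .alloc <- function(m) {
    base <- floor(fractions * m)
    rem <- m - sum(base)
    if (rem > 0) {
      extra <- order(fractions * m - base, decreasing = TRUE)[seq_len(rem)]
      base[extra] <- base[extra] + 1
    }
    base
  }
  pooled <- character(0)
  for (st in unique(strata)) {
    ids <- scans[strata == st]
    if (length(ids) < length(labels)) {
      warning("stratum '", st, "' has fewer scans than splits; ",
              "assigning by global shuffle")
      pooled <- c(pooled, ids)
      next
    }
    sizes <- .alloc(length(ids))
    ids <- sample(ids)
    assign_split[ids] <- rep(labels, times = sizes)
  }
  if (length(pooled) > 0) {
    # fill splits that are furthest below their global target
    for (id in sample(pooled)) {
      done <- table(factor(assign_split, levels = labels))
      deficit <- fractions * length(scans) - as.numeric(done)
      assign_split[id] <- labels[which.max(deficit)]
    }
  }
  manifest$split <- assign_split[manifest$scan_id]
  manifest
}
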