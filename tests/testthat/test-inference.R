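test_that("overlap-averaged tiling of a constant stage yields a constant map", {
  v <- mf_volume(array(runif(48^3), c(48, 48, 48)))
  full <- mf_mask(array(1L, c(48, 48, 48)))
  s1 <- oracle_stage1(full)
  for (stride in c(8L, 16L)) {
    cfg <- pipeline_config(patch_size = 16L, stride = stride, batch_size = 8L)
    m <- segment_mandible(v, s1, cfg)
    expect_equal(max(m$data) - min(m$data), 0)
    expect_true(all(m$data > 0.99))
  }
})

test_that("crop_to_mandible computes margins, offsets and degenerate crops", {
  v <- mf_volume(array(runif(32^3), c(32, 32, 32)))
  # whole-grid mask: identity crop
  all1 <- mf_prob(array(1, c(32, 32, 32)))
  cr <- crop_to_mandible(v, all1, 0.5, 5L)
  expect_equal(cr$offset, c(0L, 0L, 0L))
  expect_equal(dim(cr$volume), dim(v))
  # single foreground voxel at (10, 10, 10) with margin 5 -> box [5, 16)
  one <- array(0, c(32, 32, 32)); one[11, 11, 11] <- 1
  cr1 <- crop_to_mandible(v, mf_prob(one), 0.5, 5L)
  expect_equal(cr1$offset, c(5L, 5L, 5L))
  expect_equal(dim(cr1$volume), c(11L, 11L, 11L))
  expect_equal(cr1$volume$index_origin, c(5L, 5L, 5L))
  # empty map: full volume plus warning
  expect_warning(cr0 <- crop_to_mandible(v, mf_prob(array(0, c(32, 32, 32)))),
                 "empty")
  expect_equal(dim(cr0$volume), dim(v))
})

test_that("patch-centre lattice interpolation is exact for simple layouts", {
  # single centre -> constant map
  out1 <- mf_ns$.lattice_interp(list(7.5, 7.5, 7.5),
                                array(0.4, c(1, 1, 1)), c(16L, 16L, 16L))
  expect_true(all(abs(out1 - 0.4) < 1e-12))
  # two centres along x with values 0 and 1 -> 0.5 at the midpoint voxel
  out2 <- mf_ns$.lattice_interp(list(c(3.5, 11.5), 3.5, 3.5),
                                array(c(0, 1), c(2, 1, 1)), c(16L, 8L, 8L))
  mid <- (out2[8, 4, 4] + out2[9, 4, 4]) / 2
  expect_equal(mid, 0.5, tolerance = 1e-9)
  # clamped beyond the hull
  expect_equal(out2[1, 4, 4], 0)
  expect_equal(out2[16, 4, 4], 1)
  expect_true(all(out2 >= 0 & out2 <= 1))
})

test_that("extract_proposals labels, filters and scores components", {
  m <- array(0, c(20, 10, 10))
  m[2:6, 2, 2] <- 0.9          # blob of 5
  m[12:16, 5, 5] <- 0.7        # blob of 5, separated
  props <- extract_proposals(mf_prob(m), threshold = 0.5, min_size_vox = 5)
  expect_length(props, 2)
  expect_equal(vapply(props, `[[`, numeric(1), "size"), c(5, 5))
  expect_equal(props[[1]]$confidence, 0.9)   # sorted by descending confidence
  # labeling agrees with the brute-force flood fill
  lab <- naive_label3d(m >= 0.5)
  expect_equal(sort(unique(lab[lab > 0])), 1:2)
  # min_size boundary: size min_size - 1 is dropped
  props6 <- extract_proposals(mf_prob(m), 0.5, min_size_vox = 6)
  expect_length(props6, 0)
  expect_length(extract_proposals(mf_prob(array(0, c(4, 4, 4)))), 0)
})

test_that("connected components agree with the flood-fill oracle", {
  set.seed(41)
  for (conn in c(6L, 18L, 26L)) {
    m <- array(rbinom(12^3, 1, 0.2), c(12, 12, 12))
    lab <- mf_ns$label3d_cpp(array(as.numeric(m), dim(m)), conn)
    ref <- naive_label3d(m, conn)
    expect_equal(max(lab), max(ref))
    # same partition up to label permutation
    expect_equal(length(unique(paste(lab[m > 0], ref[m > 0]))), max(ref))
  }
})

test_that("unite_proposals merges transitively and preserves the rest", {
  mk <- function(vox, conf, src = "stage2") {
    list(voxels = sort(vox), shape = c(50L, 4L, 4L), source = src,
         confidence = conf, size = length(vox))
  }
  # disjoint lists pass through
  u0 <- unite_proposals(list(mk(1:3, .9)), list(mk(10:12, .8, "stage3")))
  expect_length(u0, 2)
  expect_setequal(vapply(u0, `[[`, character(1), "source"),
                  c("stage2", "stage3"))
  # identical singletons merge idempotently
  u1 <- unite_proposals(list(mk(5:8, .9)), list(mk(5:8, .4, "stage3")))
  expect_length(u1, 1)
  expect_equal(u1[[1]]$voxels, 5:8)
  expect_equal(u1[[1]]$confidence, 0.9)
  expect_equal(u1[[1]]$source, "merged")
  # chain A-B-C with A and C disjoint collapses to one proposal
  u2 <- unite_proposals(list(mk(1:5, .9), mk(9:13, .7)),
                        list(mk(4:10, .5, "stage3")))
  expect_length(u2, 1)
  expect_equal(u2[[1]]$voxels, 1:13)
  expect_equal(u2[[1]]$size, 13)
})

test_that("filter_by_confidence keeps order and is monotone in tau", {
  mk <- function(conf) list(voxels = 1:2, shape = c(10L, 1L, 1L),
                            source = "stage2", confidence = conf, size = 2)
  props <- lapply(c(0.9, 0.6, 0.2), mk)
  expect_length(filter_by_confidence(props, 0), 3)
  expect_length(filter_by_confidence(props, 0.5), 2)
  expect_length(filter_by_confidence(props, 1), 0)
  counts <- vapply(seq(0, 1, by = 0.1), function(tau) {
    length(filter_by_confidence(props, tau))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("the oracle-driven pipeline recovers planted fractures end to end", {
  cfg <- pipeline_config(patch_size = 16L, stride = 16L, batch_size = 8L)
  # no fractures -> no proposals
  ph0 <- generate_phantom(small_spec(n_fractures = 0L, seed = 71))
  st0 <- list(s1 = oracle_stage1(ph0$mandible), s2 = oracle_stage2(ph0$fracture),
              s3 = oracle_stage3(ph0$fracture))
  r0 <- run_pipeline(ph0$volume, st0, cfg)
  expect_length(r0$proposals, 0)
  # one phantom per fracture kind
  for (kind in c("nondisplaced", "displaced")) {
    ph <- generate_phantom(small_spec(n_fractures = 1L, kinds = kind,
                                      seed = 72))
    st <- list(s1 = oracle_stage1(ph$mandible), s2 = oracle_stage2(ph$fracture),
               s3 = oracle_stage3(ph$fracture))
    r <- run_pipeline(ph$volume, st, cfg)
    expect_equal(length(r$proposals), 1L)
    m <- match_detections(r$proposals, ph$fracture)
    expect_equal(m$fp, 0L)
    expect_equal(m$fn, 0L)
    # proposals stay inside the original grid and map back onto the seg map
    shape <- dim(ph$volume$data)
    for (p in r$proposals) {
      expect_true(all(p$voxels >= 1 & p$voxels <= prod(shape)))
    }
    s2p <- Filter(function(p) p$source %in% c("stage2", "merged"),
                  r$all_proposals)
    for (p in s2p) {
      expect_gte(max(r$seg_map$data[p$voxels]), cfg$seg_threshold)
    }
    # raising tau never increases the proposal count
    counts <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(tau) {
      length(filter_by_confidence(r$all_proposals, tau))
    }, numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})
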