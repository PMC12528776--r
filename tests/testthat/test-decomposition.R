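test_that("carina is found at the constructed bifurcation slice", {
  m <- bifurcating_tube_mask(split_at = 21L)
  tr <- locate_trachea(m)
  expect_equal(tr$carina_slice, 21L)
  # trachea = the 20 superior slices of the component
  expect_identical(which(apply(tr$trachea, 1, any)), 1:20)
  expect_equal(tr$carina_mm[1], 19)  # centroid slice = carina_slice - 1
})

test_that("an unbranched tube has no carina; empty masks error", {
  grid <- voxel_grid(c(40L, 24L, 24L))
  ph <- airtree:::single_tube_phantom(grid = grid, length_mm = 30, radius = 3)
  tube <- rasterize_tree(ph)$airway
  expect_error(locate_trachea(tube), class = "airtree_no_carina")
  expect_error(locate_trachea(binary_mask(array(FALSE, dim = grid$shape), grid)),
               class = "airtree_empty_mask")
})

test_that("single-slice split artifacts are skipped by the persistence rule", {
  m <- bifurcating_tube_mask(split_at = 25L)
  vox <- m$voxels
  # carve a one-slice split at slice 12: remove the middle of the tube
  cy <- (dim(vox)[2] - 1) / 2
  vox[12, , ] <- vox[12, , ]
  vox[12, round(cy) + 1L + (-1:1), ] <- FALSE
  m2 <- binary_mask(vox, m$grid)
  tr <- locate_trachea(m2, decomposition_config(carina_persistence = 3L))
  expect_equal(tr$carina_slice, 25L)
  # with persistence 1 the artifact wins
  tr1 <- locate_trachea(m2, decomposition_config(carina_persistence = 1L))
  expect_equal(tr1$carina_slice, 12L)
})

test_that("projections follow the single-voxel and pigeonhole rules", {
  grid <- voxel_grid(c(8L, 9L, 10L))
  vox <- array(FALSE, dim = grid$shape)
  vox[3, 4, 5] <- TRUE
  pz <- project_mask(binary_mask(vox, grid), "z")
  expect_equal(which(pz, arr.ind = TRUE)[1, ], c(row = 4L, col = 5L))
  py <- project_mask(binary_mask(vox, grid), "y")
  expect_equal(which(py, arr.ind = TRUE)[1, ], c(row = 3L, col = 5L))
  f <- fix_small()
  expect_lte(sum(project_mask(f$airway, "z")), sum(f$airway$voxels))
})

test_that("split_lungs uses components when present, plane otherwise, and mirrors", {
  f <- fix_small()
  carina <- locate_trachea(f$airway)$carina_mm
  sp <- split_lungs(f$lung, carina)
  expect_equal(sum(sp$left$voxels) + sum(sp$right$voxels), sum(f$lung$voxels))
  # right lung must sit at smaller x than left
  xr <- mean(which(sp$right$voxels, arr.ind = TRUE)[, 3])
  xl <- mean(which(sp$left$voxels, arr.ind = TRUE)[, 3])
  expect_lt(xr, xl)
  # fused single-component lung -> sagittal plane split through the carina
  grid <- voxel_grid(c(10L, 10L, 11L))
  ball <- array(TRUE, dim = grid$shape)
  spl <- split_lungs(binary_mask(ball, grid), c(5, 5, 5))
  idx_r <- which(spl$right$voxels, arr.ind = TRUE)
  expect_true(all((idx_r[, 3] - 1) < 5))
  # mirrored input swaps the outputs exactly
  spm <- split_lungs(flip_x(f$lung), c(carina[1], carina[2],
                                       (f$lung$grid$shape[3] - 1) - carina[3]))
  expect_identical(spm$left$voxels, flip_x(sp$right)$voxels)
  expect_identical(spm$right$voxels, flip_x(sp$left)$voxels)
})

test_that("distance fields are normalised per lung and match the brute-force oracle", {
  f <- fix_small()
  cfg <- decomposition_config()
  tr <- locate_trachea(f$airway, cfg)
  lungs <- split_lungs(f$lung, tr$carina_mm)
  fields <- compute_distance_fields(f$airway, lungs, tr, cfg)
  for (s in c(-1L, 1L)) {
    D <- fields$D[!is.na(fields$side) & fields$side == s]
    expect_true(all(D >= 0 & D <= 1))
    expect_equal(max(D), 1, tolerance = 1e-12)
  }
  orc <- oracle_decompose(f$airway, f$lung, cfg)
  expect_equal(fields$D, orc$D, tolerance = 1e-9)
  expect_equal(fields$height_mm, orc$height, tolerance = 1e-9)
  labels <- decompose(f$airway, f$lung, cfg)
  expect_identical(labels$labels, orc$labels)
})

test_that("threshold semantics at the boundaries", {
  cfg <- decomposition_config()
  v <- c(0.0, 0.25, 0.55, 1.0, 0.6, 0.2499999, 0.5499999)
  cls <- airtree:::threshold_classes(v, cfg)
  expect_equal(unname(cls), c(2L, 3L, 4L, 4L, 4L, 2L, 3L))
})

test_that("back-projection applies one class per column and conserves counts", {
  f <- fix_small()
  cfg <- decomposition_config(revision = "off")
  tr <- locate_trachea(f$airway, cfg)
  lungs <- split_lungs(f$lung, tr$carina_mm)
  fields <- compute_distance_fields(f$airway, lungs, tr, cfg)
  cls <- classify_preliminary(fields, cfg)
  prelim <- back_project(cls, f$airway, tr$trachea)
  # conservation: class counts sum to airway voxel count
  expect_equal(sum(label_counts(prelim)), sum(f$airway$voxels))
  # column rule: within any column all non-trachea labels agree
  nt <- f$airway$voxels & !tr$trachea
  idx <- which(project_mask(nt, "z"), arr.ind = TRUE)
  for (k in sample(nrow(idx), min(25, nrow(idx)))) {
    col <- prelim$labels[, idx[k, 1], idx[k, 2]]
    col <- col[nt[, idx[k, 1], idx[k, 2]]]
    expect_equal(length(unique(col)), 1L)
  }
  # with revision off, decompose equals the back-projection
  expect_identical(decompose(f$airway, f$lung, cfg)$labels, prelim$labels)
})

test_that("vertical-max revision promotes but never demotes", {
  f <- fix_small()
  cfg_off <- decomposition_config(revision = "off")
  cfg_on <- decomposition_config(revision = "vertical-max")
  lab_off <- decompose(f$airway, f$lung, cfg_off)
  lab_on <- decompose(f$airway, f$lung, cfg_on)
  sel <- lab_off$labels >= 2L
  expect_true(all(lab_on$labels[sel] >= lab_off$labels[sel]))
  # hand application of the stated rule: D = 0.10, H = 0.90 -> terminal
  expect_equal(unname(airtree:::threshold_classes(max(0.10, 0.90),
                                                  decomposition_config())), 4L)
})

test_that("rank-percentile mode classifies by within-lung quantile rank", {
  f <- fix_small()
  cfg <- decomposition_config(threshold_mode = "rank", revision = "off")
  lab <- decompose(f$airway, f$lung, cfg)
  expect_equal(sum(label_counts(lab)), sum(f$airway$voxels))
  counts <- label_counts(lab)
  expect_true(all(counts[c("medium", "small", "terminal")] > 0))
})

test_that("decomposition is mirror-symmetric in per-class counts", {
  f <- fix_small()
  lab <- decompose(f$airway, f$lung)
  lab_m <- decompose(flip_x(f$airway), flip_x(f$lung))
  expect_identical(label_counts(lab), label_counts(lab_m))
})

test_that("isotropic spacing rescale leaves classes unchanged", {
  f <- fix_small()
  lab <- decompose(f$airway, f$lung)
  g2 <- voxel_grid(f$airway$grid$shape, f$airway$grid$spacing * 2)
  lab2 <- decompose(binary_mask(f$airway$voxels, g2),
                    binary_mask(f$lung$voxels, g2))
  expect_identical(lab$labels, lab2$labels)
})
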