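test_that("tree combinatorics: full binary tree edge counts", {
  y <- generate_tree(tree_spec(n_generations = 1L))
  expect_equal(nrow(y$edges), 3L)           # trachea + 2 main bronchi
  g4 <- generate_tree(tree_spec(n_generations = 4L))
  expect_equal(nrow(g4$edges), 2^5 - 1L)    # 31 edges
  expect_equal(sum(g4$edges$gen == 4L), 16L)
  # child generation = parent generation + 1, single root
  e <- g4$edges
  expect_equal(sum(is.na(e$parent)), 1L)
  for (k in which(!is.na(e$parent)))
    expect_equal(e$gen[k], e$gen[match(e$parent[k], e$id)] + 1L)
})

test_that("generation is deterministic given the seed", {
  s <- tree_spec(n_generations = 3L, jitter = 0.2, seed = 11L)
  expect_identical(generate_tree(s), generate_tree(s))
  s2 <- tree_spec(n_generations = 3L, jitter = 0.2, seed = 12L)
  expect_false(identical(generate_tree(s)$edges, generate_tree(s2)$edges))
})

test_that("geometry leaving the grid is rejected with the offending branch named", {
  expect_error(
    generate_tree(tree_spec(n_generations = 2L, trachea_length = 80),
                  grid = voxel_grid(c(64L, 64L, 64L))),
    "generation", class = "airtree_tree_exits_grid")
})

test_that("capsule rasterisation matches the analytic volume, improving with resolution", {
  analytic <- function(r, L) pi * r^2 * L + 4 / 3 * pi * r^3
  err <- numeric(2)
  for (i in 1:2) {
    sp <- c(1, 0.5)[i]
    n <- c(65L, 129L)[i]   # odd extent puts the tube axis on voxel centres
    grid <- voxel_grid(rep(n, 3L), rep(sp, 3L))
    ph <- airtree:::single_tube_phantom(grid = grid, length_mm = 30, radius = 3)
    ras <- rasterize_tree(ph)
    vol <- sum(ras$airway$voxels) * sp^3
    err[i] <- abs(vol - analytic(3, 30)) / analytic(3, 30)
  }
  expect_lt(err[1], 0.10)
  expect_lte(err[2], err[1] / 2 + 1e-12)   # error halves or better at 0.5 mm
})

test_that("ground-truth labels partition the airway and separate disjoint branches", {
  f <- fix_small()
  expect_identical(f$truth > 0L, f$airway$voxels)
  # two disjoint manual branches -> exactly two distinct nonzero labels
  grid <- voxel_grid(c(40L, 40L, 40L))
  edges <- data.frame(id = 1:2, parent = NA_integer_, gen = c(0L, 3L),
                      z0 = c(5, 25), y0 = c(10, 30), x0 = c(10, 30),
                      z1 = c(15, 35), y1 = c(10, 30), x1 = c(10, 30),
                      radius = 2)
  ras <- rasterize_tree(manual_phantom(edges, grid))
  expect_setequal(unique(as.vector(ras$truth[ras$truth > 0L])), c(1L, 4L))
})

test_that("sub-voxel radii are clamped with a warning", {
  expect_warning(
    generate_tree(tree_spec(n_generations = 1L, trachea_radius = 0.4)),
    "clamped")
  ph <- suppressWarnings(generate_tree(tree_spec(n_generations = 1L,
                                                 trachea_radius = 0.4)))
  expect_true(all(ph$edges$radius[ph$edges$gen > 0L] >= 1))
})

test_that("lung mask covers the bronchial tree and behaves monotonically", {
  f <- fix_g5()
  bronchial <- f$truth >= 2L   # generation >= 1
  expect_true(all(f$lung$voxels[bronchial]))
  # mirror-symmetric jitter-free spec -> left/right counts equal
  nx <- f$lung$grid$shape[3]
  expect_identical(sum(f$lung$voxels[, , 1:(nx / 2)]),
                   sum(f$lung$voxels[, , (nx / 2 + 1):nx]))
  m0 <- generate_lung_mask(f$phantom$grid, f$phantom, margin = 0)
  m10 <- generate_lung_mask(f$phantom$grid, f$phantom, margin = 10)
  expect_gt(sum(m10$voxels), sum(m0$voxels))
  expect_true(all(m10$voxels[m0$voxels]))
})

test_that("honeycomb clutter is reproducible, peripheral and airway-disjoint", {
  f <- fix_small()
  none <- add_honeycomb_clutter(f$lung, f$airway, n_cysts = 0)
  expect_equal(sum(none$voxels), 0L)
  c1 <- add_honeycomb_clutter(f$lung, f$airway, n_cysts = 10, seed = 5L)
  c2 <- add_honeycomb_clutter(f$lung, f$airway, n_cysts = 10, seed = 5L)
  expect_identical(c1$voxels, c2$voxels)
  expect_gt(sum(c1$voxels), 0L)
  expect_false(any(c1$voxels & f$airway$voxels))
  expect_true(all(f$lung$voxels[c1$voxels]))
})
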