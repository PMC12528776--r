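# Shared phantom fixtures, memoised so each is built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]]))
    .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

# small tree that fits in a 64^3 grid at 1 mm (for oracle-equivalence runs)
small_tree_spec <- function(n_generations = 4L, seed = 1L, jitter = 0) {
  tree_spec(n_generations = n_generations, trachea_length = 14,
            trachea_radius = 2.5, length_ratio = 0.75, radius_ratio = 0.8,
            half_angle_deg = 35, seed = seed, jitter = jitter)
}

small_grid <- function(n = 64L, spacing = 1) voxel_grid(rep(n, 3), rep(spacing, 3))

fix_small <- function() fixture("small", function() {
  ph <- suppressWarnings(generate_tree(small_tree_spec(), grid = small_grid()))
  ras <- rasterize_tree(ph)
  lung <- generate_lung_mask(ph$grid, ph, margin = 4)
  list(phantom = ph, airway = ras$airway, truth = ras$truth, lung = lung)
})

fix_g5 <- function() fixture("g5", function() {
  ph <- generate_tree(tree_spec(n_generations = 5L, seed = 1L))
  ras <- rasterize_tree(ph)
  lung <- generate_lung_mask(ph$grid, ph)
  list(phantom = ph, airway = ras$airway, truth = ras$truth, lung = lung)
})

fix_g6 <- function() fixture("g6", function() {
  ph <- suppressWarnings(generate_tree(tree_spec(n_generations = 6L, seed = 1L)))
  ras <- rasterize_tree(ph)
  lung <- generate_lung_mask(ph$grid, ph)
  list(phantom = ph, airway = ras$airway, truth = ras$truth, lung = lung)
})

# hand-built phantom from an explicit edge table (positions mm)
manual_phantom <- function(edges, grid) {
  structure(list(edges = edges, grid = grid, spec = list(manual = TRUE)),
            class = "airway_phantom")
}

# mask of a vertical tube that bifurcates into two parallel vertical tubes
# at slice `split_at` (1-based); useful for exact carina tests
bifurcating_tube_mask <- function(nz = 48L, ny = 48L, nx = 48L, split_at = 21L,
                                  r = 4, sep = 12) {
  vox <- array(FALSE, dim = c(nz, ny, nx))
  cy <- (ny - 1) / 2; cx <- (nx - 1) / 2
  for (z in seq_len(nz)) {
    for (y in seq_len(ny)) for (x in seq_len(nx)) {
      if (z < split_at) {
        if ((y - 1 - cy)^2 + (x - 1 - cx)^2 <= r^2) vox[z, y, x] <- TRUE
      } else {
        if ((y - 1 - cy)^2 + (x - 1 - cx - sep / 2)^2 <= r^2) vox[z, y, x] <- TRUE
        if ((y - 1 - cy)^2 + (x - 1 - cx + sep / 2)^2 <= r^2) vox[z, y, x] <- TRUE
      }
    }
  }
  binary_mask(vox, voxel_grid(c(nz, ny, nx)))
}

# quarter-circle tube mask (arc radius R, tube radius r) for tortuosity tests
quarter_circle_mask <- function(n = 80L, R = 30, r = 2.5) {
  grid <- voxel_grid(rep(n, 3))
  vox <- array(FALSE, dim = grid$shape)
  cz <- 10; cy <- (n - 1) / 2; cx <- 10
  for (t in seq(0, pi / 2, length.out = 4L * R)) {
    pz <- cz + R * sin(t); px <- cx + R * (1 - cos(t))
    iz <- round(pz) + 1L; ix <- round(px) + 1L
    rr <- ceiling(r) + 1L
    for (dz in -rr:rr) for (dy in -rr:rr) for (dx in -rr:rr) {
      z <- iz + dz; y <- round(cy) + 1L + dy; x <- ix + dx
      if (z >= 1 && z <= n && y >= 1 && y <= n && x >= 1 && x <= n &&
          (pz - (z - 1))^2 + (cy - (y - 1))^2 + (px - (x - 1))^2 <= r^2)
        vox[z, y, x] <- TRUE
    }
  }
  binary_mask(vox, grid)
}

# mirror both masks left-right (x axis)
flip_x <- function(mask) {
  nx <- mask$grid$shape[3]
  binary_mask(mask$voxels[, , nx:1], mask$grid)
}
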