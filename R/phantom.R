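# Synthetic airway-tree phantoms with ground-truth generation labels.
#
# The generator builds a dichotomous tree of tapering tubes (Weibel-like
# generations: trachea = 0, main bronchi = 1, ...) embedded in a two-lobe
# lung mask, plus optional peripheral cyst clutter mimicking honeycombing.
# Positions are mm in the package (z, y, x) convention.

with_seed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Specification of a synthetic airway tree
#'
#' Defaults describe a desk-scale tree on a 128 mm isotropic grid: a 30 mm
#' trachea of radius 5 mm, branch lengths shrinking by 0.78 and radii by
#' 0.75 per generation (Weibel-like tapering), 35 degree branching
#' half-angle.
#'
#' @param n_generations generations beyond the trachea (>= 1).
#' @param trachea_length,trachea_radius mm.
#' @param length_ratio,radius_ratio per-generation tapering in (0, 1].
#' @param half_angle_deg branching half-angle in (0, 90).
#' @param azimuth `"alternating"` (branching plane flips 90 degrees each
#'   generation) or `"rotating"` (advances 60 degrees each generation).
#' @param jitter fraction in `[0, 1)`; lengths and angles are perturbed
#'   uniformly by at most this fraction.
#' @param seed RNG seed for jitter.
#' @return A `tree_spec` list.
#' @export
tree_spec <- function(n_generations = 5L, trachea_length = 30, trachea_radius = 5,
                      length_ratio = 0.78, radius_ratio = 0.75,
                      half_angle_deg = 35, azimuth = c("alternating", "rotating"),
                      jitter = 0, seed = 1L) {
  azimuth <- match.arg(azimuth)
  if (n_generations < 1L)
    airtree_error("n_generations must be >= 1", "airtree_bad_spec")
  if (length_ratio <= 0 || length_ratio > 1 || radius_ratio <= 0 || radius_ratio > 1)
    airtree_error("tapering ratios must lie in (0, 1]", "airtree_bad_spec")
  if (half_angle_deg <= 0 || half_angle_deg >= 90)
    airtree_error("half angle must lie in (0, 90) degrees", "airtree_bad_spec")
  if (jitter < 0 || jitter >= 1)
    airtree_error("jitter must lie in [0, 1)", "airtree_bad_spec")
  structure(list(n_generations = as.integer(n_generations),
                 trachea_length = trachea_length, trachea_radius = trachea_radius,
                 length_ratio = length_ratio, radius_ratio = radius_ratio,
                 half_angle_deg = half_angle_deg, azimuth = azimuth,
                 jitter = jitter, seed = as.integer(seed)),
            class = "tree_spec")
}

# orthonormal vectors spanning the plane perpendicular to unit vector d
perp_frame <- function(d) {
  ref <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)  # prefer the x axis
  u <- ref - sum(ref * d) * d
  u <- u / sqrt(sum(u^2))
  v <- c(d[2] * u[3] - d[3] * u[2],
         d[3] * u[1] - d[1] * u[3],
         d[1] * u[2] - d[2] * u[1])
  list(u = u, v = v)
}

#' Generate a synthetic dichotomous airway tree
#'
#' Builds the centerline graph: one trachea edge plus a full binary tree,
#' `2^(g+1) - 1` edges for `g` generations when jitter-free. Radii that
#' taper below one voxel spacing are clamped (with a warning). Deterministic
#' given `spec$seed`.
#'
#' @param spec a [tree_spec()].
#' @param grid target [voxel_grid()] the tree must fit into.
#' @param root_mm optional root position (z, y, x) mm; defaults to 5 mm below
#'   the superior face, centred in-plane.
#' @return An `airway_phantom`: `edges` data frame (id, parent, gen,
#'   z0/y0/x0, z1/y1/x1, radius), `grid`, `spec`.
#' @export
generate_tree <- function(spec, grid = voxel_grid(c(128L, 128L, 128L)),
                          root_mm = NULL) {
  ext <- (grid$shape - 1L) * grid$spacing
  if (is.null(root_mm)) root_mm <- c(5, ext[2] / 2, ext[3] / 2)
  min_r <- min(grid$spacing)
  theta0 <- spec$half_angle_deg * pi / 180

  rows <- vector("list", 2^(spec$n_generations + 1L))
  nrows <- 0L
  clamped <- 0L
  add_row <- function(id, parent, gen, p0, p1, r) {
    nrows <<- nrows + 1L
    rows[[nrows]] <<- data.frame(id = id, parent = parent, gen = gen,
                                 z0 = p0[1], y0 = p0[2], x0 = p0[3],
                                 z1 = p1[1], y1 = p1[2], x1 = p1[3],
                                 radius = r)
  }

  with_seed(spec$seed, function() {
    down <- c(1, 0, 0)
    p1 <- root_mm + spec$trachea_length * down
    add_row(1L, NA_integer_, 0L, root_mm, p1, spec$trachea_radius)
    queue <- list(list(id = 1L, end = p1, dir = down, gen = 0L))
    next_id <- 2L
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      g <- cur$gen + 1L
      if (g > spec$n_generations) next
      len <- spec$trachea_length * spec$length_ratio^g
      rad <- spec$trachea_radius * spec$radius_ratio^g
      if (rad < min_r) { rad <- min_r; clamped <<- clamped + 1L }
      fr <- perp_frame(cur$dir)
      phi <- switch(spec$azimuth,
                    alternating = (g %% 2L) * pi / 2,
                    rotating = (g * pi / 3) %% pi)
      for (s in c(1, -1)) {
        th <- theta0
        ln <- len
        if (spec$jitter > 0) {
          th <- th * (1 + spec$jitter * runif(1, -1, 1))
          ln <- ln * (1 + spec$jitter * runif(1, -1, 1))
        }
        lat <- cos(phi) * fr$u + sin(phi) * fr$v
        d <- cos(th) * cur$dir + s * sin(th) * lat
        d <- d / sqrt(sum(d^2))
        p <- cur$end + ln * d
        add_row(next_id, cur$id, g, cur$end, p, rad)
        queue[[length(queue) + 1L]] <- list(id = next_id, end = p, dir = d, gen = g)
        next_id <- next_id + 1L
      }
    }
  })

  edges <- do.call(rbind, rows[seq_len(nrows)])
  if (clamped > 0L)
    warning(sprintf("%d branch radii clamped to the voxel spacing (%.3g mm)",
                    clamped, min_r))
  # reject geometry leaving the grid (capsule extent beyond voxel centres)
  for (k in seq_len(nrow(edges))) {
    lo <- pmin(unlist(edges[k, c("z0", "y0", "x0")]),
               unlist(edges[k, c("z1", "y1", "x1")])) - edges$radius[k]
    hi <- pmax(unlist(edges[k, c("z0", "y0", "x0")]),
               unlist(edges[k, c("z1", "y1", "x1")])) + edges$radius[k]
    if (any(lo < 0) || any(hi > ext))
      airtree_error(sprintf("branch %d (generation %d) exits the grid",
                            edges$id[k], edges$gen[k]),
                    "airtree_tree_exits_grid")
  }
  structure(list(edges = edges, grid = grid, spec = spec),
            class = "airway_phantom")
}

#' @export
print.airway_phantom <- function(x, ...) {
  cat(sprintf("<airway_phantom %d edges, %d generations>\n",
              nrow(x$edges), max(x$edges$gen)))
  invisible(x)
}

# linear indices (1-based) for an index-space bounding box
bbox_indices <- function(grid, lo_mm, hi_mm) {
  sp <- grid$spacing
  lo <- pmax(1L, floor(lo_mm / sp) + 1L)
  hi <- pmin(grid$shape, ceiling(hi_mm / sp) + 1L)
  if (any(lo > hi)) return(NULL)
  iz <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; ix <- lo[3]:hi[3]
  nz <- grid$shape[1]; ny <- grid$shape[2]
  g <- expand.grid(iz = iz, iy = iy, ix = ix)
  list(lin = g$iz + nz * ((g$iy - 1L) + ny * (g$ix - 1L)),
       z = (g$iz - 1) * sp[1], y = (g$iy - 1) * sp[2], x = (g$ix - 1) * sp[3])
}

#' Rasterize a phantom tree into masks
#'
#' Each centerline edge is painted as a capsule (cylinder with hemispherical
#' caps) of its radius. The ground-truth label of a voxel covered by several
#' capsules is the generation of the nearest one; exact ties go to the
#' higher (more distal) generation.
#'
#' @param phantom an `airway_phantom`.
#' @param grid target grid (defaults to the phantom's).
#' @return list with `airway` (a `binary_mask`) and `truth` (integer array,
#'   0 background, generation + 1 otherwise, so trachea voxels carry 1).
#' @export
rasterize_tree <- function(phantom, grid = phantom$grid) {
  n <- prod(grid$shape)
  dist_best <- rep(Inf, n)
  gen_best <- integer(n)           # stores generation + 1
  edges <- phantom$edges
  for (k in seq_len(nrow(edges))) {
    a <- c(edges$z0[k], edges$y0[k], edges$x0[k])
    b <- c(edges$z1[k], edges$y1[k], edges$x1[k])
    r <- edges$radius[k]
    bb <- bbox_indices(grid, pmin(a, b) - r, pmax(a, b) + r)
    if (is.null(bb)) next
    ab <- b - a
    len2 <- sum(ab^2)
    dz <- bb$z - a[1]; dy <- bb$y - a[2]; dx <- bb$x - a[3]
    t <- if (len2 > 0) pmin(1, pmax(0, (dz * ab[1] + dy * ab[2] + dx * ab[3]) / len2)) else 0
    d <- sqrt((dz - t * ab[1])^2 + (dy - t * ab[2])^2 + (dx - t * ab[3])^2)
    g1 <- edges$gen[k] + 1L
    inside <- d <= r
    lin <- bb$lin[inside]; dv <- d[inside]
    better <- dv < dist_best[lin] - 1e-9 |
      (abs(dv - dist_best[lin]) <= 1e-9 & g1 > gen_best[lin])
    lin <- lin[better]; dv <- dv[better]
    dist_best[lin] <- dv
    gen_best[lin] <- g1
  }
  truth <- array(gen_best, dim = grid$shape)
  airway <- binary_mask(array(gen_best > 0L, dim = grid$shape), grid)
  list(airway = airway, truth = truth)
}

# side of each generation >= 1 edge: sign of its generation-1 ancestor's
# lateral (x) displacement from the root
edge_sides <- function(edges) {
  root_x <- edges$x0[is.na(edges$parent)][1]
  anc1 <- integer(nrow(edges))
  for (k in seq_len(nrow(edges))) {
    j <- k
    while (!is.na(edges$parent[j]) && edges$gen[j] > 1L)
      j <- which(edges$id == edges$parent[j])
    anc1[k] <- j
  }
  ifelse(edges$gen == 0L, 0L,
         ifelse(edges$x1[anc1] < root_x, -1L, 1L))  # -1 = patient right (low x)
}

#' Generate a two-lobe lung mask around a phantom
#'
#' Two lateral ellipsoids sized so every bronchial (generation >= 1) airway
#' voxel lies inside with at least `margin` mm clearance; the trachea may
#' sit in the mediastinal gap between them.
#'
#' @param grid target grid.
#' @param phantom an `airway_phantom`.
#' @param margin clearance in mm (>= 0).
#' @return A `binary_mask`.
#' @export
generate_lung_mask <- function(grid, phantom, margin = 5) {
  edges <- phantom$edges
  side <- edge_sides(edges)
  vox <- array(FALSE, dim = grid$shape)
  sp <- grid$spacing
  for (s in c(-1L, 1L)) {
    e <- edges[side == s, , drop = FALSE]
    if (!nrow(e)) next
    rmax <- max(e$radius)
    p0 <- as.matrix(e[, c("z0", "y0", "x0")])
    p1 <- as.matrix(e[, c("z1", "y1", "x1")])
    lo <- pmin(apply(p0, 2, min), apply(p1, 2, min)) - rmax
    hi <- pmax(apply(p0, 2, max), apply(p1, 2, max)) + rmax
    centre <- (lo + hi) / 2
    half <- (hi - lo) / 2 + margin
    semi <- pmax(half, 1) * sqrt(3)   # box + margin fully inside the ellipsoid
    bb <- bbox_indices(grid, centre - semi, centre + semi)
    if (is.null(bb)) next
    q <- ((bb$z - centre[1]) / semi[1])^2 + ((bb$y - centre[2]) / semi[2])^2 +
      ((bb$x - centre[3]) / semi[3])^2
    vox[bb$lin[q <= 1]] <- TRUE
  }
  binary_mask(vox, grid)
}

#' Peripheral honeycomb-like cyst clutter
#'
#' Drops small spheres into the subpleural lung rind, guaranteed disjoint
#' (and 26-disconnected) from the airway mask, for stress-testing the
#' decomposition against the honeycombing/emphysema failure mode of airway
#' extraction. "Peripheral" follows the clinical distribution of
#' honeycombing: near the costal pleura, i.e. within `rind_mm` of the
#' lateral lung surface measured in the axial plane (cysts are not placed
#' centrally over the tracheal axis at the lung poles).
#'
#' @param lung,airway `binary_mask`s on a shared grid.
#' @param n_cysts number of spheres.
#' @param cyst_radius sphere radius mm.
#' @param seed RNG seed.
#' @param rind_mm rind thickness from the pleural boundary.
#' @return A `binary_mask` of clutter voxels.
#' @export
add_honeycomb_clutter <- function(lung, airway, n_cysts = 20, cyst_radius = 2,
                                  seed = 1L, rind_mm = 12) {
  if (!grid_equal(lung$grid, airway$grid))
    airtree_error("lung and airway masks must share a grid", "airtree_bad_grid")
  grid <- lung$grid
  empty <- binary_mask(array(FALSE, dim = grid$shape), grid)
  if (n_cysts <= 0) return(empty)
  dims <- grid$shape
  # in-plane distance to the projected (costal) lung boundary
  proj <- apply(lung$voxels, c(2, 3), any)
  d_lat2d <- .edt3d(!as.logical(proj), c(1L, dims[2], dims[3]),
                    c(1, grid$spacing[2], grid$spacing[3]))
  d_lat <- aperm(array(d_lat2d, dim = c(dims[2], dims[3], dims[1])), c(3, 1, 2))
  d_aw <- .edt3d(airway$voxels, dims, grid$spacing)    # distance to airway
  clearance <- cyst_radius + 2 * max(grid$spacing) + 1
  elig <- which(lung$voxels & d_lat <= rind_mm & d_aw >= clearance)
  if (!length(elig)) {
    warning("no eligible rind voxels for clutter; returning empty mask")
    return(empty)
  }
  centres <- with_seed(seed, function()
    elig[sample.int(length(elig), min(n_cysts, length(elig)))])
  vox <- array(FALSE, dim = dims)
  nz <- dims[1]; ny <- dims[2]
  for (lin in centres) {
    iz <- (lin - 1L) %% nz + 1L
    iy <- ((lin - 1L) %/% nz) %% ny + 1L
    ix <- (lin - 1L) %/% (nz * ny) + 1L
    c_mm <- (c(iz, iy, ix) - 1) * grid$spacing
    bb <- bbox_indices(grid, c_mm - cyst_radius, c_mm + cyst_radius)
    d <- sqrt((bb$z - c_mm[1])^2 + (bb$y - c_mm[2])^2 + (bb$x - c_mm[3])^2)
    vox[bb$lin[d <= cyst_radius]] <- TRUE
  }
  vox <- vox & lung$voxels & !airway$voxels
  binary_mask(vox, grid)
}

#' Ground-truth per-generation voxel counts
#' @param truth integer array from [rasterize_tree()].
#' @return named integer vector, one entry per generation (0 = trachea).
#' @export
generation_counts <- function(truth) {
  tab <- table(truth[truth > 0L])
  stats::setNames(as.integer(tab), as.integer(names(tab)) - 1L)
}
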