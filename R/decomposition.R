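# Distance-map airway-branch decomposition.
#
# Pipeline: locate the trachea and carina by slice scanning; split the lungs;
# project the non-trachea airway onto the transverse plane (P_Z); measure
# each airway pixel's in-plane Euclidean distance to its lung's adjusted
# central point; normalise per lung to [0, 1]; threshold at fixed percentile
# cuts (terminal >= 0.55, small >= 0.25, else medium); project the classes
# back to 3D; optionally promote voxels by the vertical depth constraint
# derived from the frontal projection (P_Y).

#' Decomposition configuration
#'
#' @param t_terminal,t_small normalised-distance cuts, `0 < t_small <
#'   t_terminal < 1`. Terminal = `[t_terminal, 1]`, small = `[t_small,
#'   t_terminal)`, medium = `[0, t_small)` (boundaries closed on the left,
#'   assigned to the more distal class).
#' @param carina_persistence slices a cross-section split must persist to
#'   count as the carina (skips single-slice loop artifacts).
#' @param threshold_mode `"normalised"` thresholds the max-normalised
#'   distance itself; `"rank"` thresholds its empirical quantile rank within
#'   the lung.
#' @param revision `"vertical-max"` (promotion-only revision by the vertical
#'   depth constraint) or `"off"`.
#' @param min_trachea_area_mm2 minimum cross-section area of the topmost
#'   airway slice.
#' @return A `decomposition_config`.
#' @export
decomposition_config <- function(t_terminal = 0.55, t_small = 0.25,
                                 carina_persistence = 3L,
                                 threshold_mode = c("normalised", "rank"),
                                 revision = c("vertical-max", "off"),
                                 min_trachea_area_mm2 = 4) {
  threshold_mode <- match.arg(threshold_mode)
  revision <- match.arg(revision)
  if (!(t_small > 0 && t_small < t_terminal && t_terminal < 1))
    airtree_error("need 0 < t_small < t_terminal < 1", "airtree_bad_config")
  structure(list(t_terminal = t_terminal, t_small = t_small,
                 carina_persistence = as.integer(carina_persistence),
                 threshold_mode = threshold_mode, revision = revision,
                 min_trachea_area_mm2 = min_trachea_area_mm2),
            class = "decomposition_config")
}

# largest 26-connected foreground component
largest_component <- function(voxels, grid) {
  lab <- .cc_label3d(voxels, grid$shape, 26L)
  if (max(lab) == 0L)
    airtree_error("mask is empty", "airtree_empty_mask")
  sizes <- tabulate(lab[lab > 0L])
  keep <- which.max(sizes)
  list(voxels = array(lab == keep, dim = grid$shape),
       discarded = sum(voxels) - sizes[keep])
}

slice_component_count <- function(slice2d) {
  d <- dim(slice2d)
  max(.cc_label3d(as.logical(slice2d), c(1L, d[1], d[2]), 26L))
}

#' Locate the trachea and the carina
#'
#' Scans the largest 26-connected component of the airway from the most
#' superior slice downward. The carina slice is the first slice whose
#' in-plane cross-section splits into >= 2 components and stays split for
#' `carina_persistence` consecutive slices. Trachea voxels are those
#' strictly superior to the carina slice; the carina point is the centroid
#' of the last single-component cross-section.
#'
#' @param airway a `binary_mask`.
#' @param config a [decomposition_config()].
#' @return list with `trachea` (logical array), `carina_mm` (z, y, x),
#'   `carina_slice` (1-based index), `component` (largest-component array),
#'   `discarded` (voxel count outside the largest component).
#' @export
locate_trachea <- function(airway, config = decomposition_config()) {
  grid <- airway$grid
  comp <- largest_component(airway$voxels, grid)
  vox <- comp$voxels
  nz <- grid$shape[1]
  nvox_slice <- vapply(seq_len(nz), function(z) sum(vox[z, , ]), integer(1))
  top <- which(nvox_slice > 0L)[1]
  area_mm2 <- nvox_slice[top] * grid$spacing[2] * grid$spacing[3]
  if (area_mm2 < config$min_trachea_area_mm2)
    airtree_error(sprintf(
      "topmost cross-section (%.1f mm2) below the minimum trachea area",
      area_mm2), "airtree_no_trachea")
  ncomp <- integer(nz)
  for (z in top:nz) {
    if (nvox_slice[z] > 0L) ncomp[z] <- slice_component_count(vox[z, , ])
  }
  carina_slice <- NA_integer_
  pers <- config$carina_persistence
  for (z in top:nz) {
    if (ncomp[z] < 2L) next
    run_end <- min(nz, z + pers - 1L)
    run <- ncomp[z:run_end]
    # persistence window truncated by the end of the mask counts as stable
    nonempty <- nvox_slice[z:run_end] > 0L
    if (all(run[nonempty] >= 2L) && any(nonempty)) {
      carina_slice <- z
      break
    }
  }
  if (is.na(carina_slice))
    airtree_error("no carina: the airway never splits", "airtree_no_carina")
  if (carina_slice == top)
    airtree_error("airway already split at the topmost slice", "airtree_no_trachea")
  trachea <- array(FALSE, dim = grid$shape)
  trachea[seq_len(carina_slice - 1L), , ] <- vox[seq_len(carina_slice - 1L), , ]
  ref_slice <- carina_slice - 1L
  idx <- which(vox[ref_slice, , ], arr.ind = TRUE)
  carina_mm <- c((ref_slice - 1) * grid$spacing[1],
                 mean((idx[, 1] - 1) * grid$spacing[2]),
                 mean((idx[, 2] - 1) * grid$spacing[3]))
  list(trachea = trachea, carina_mm = carina_mm, carina_slice = carina_slice,
       component = vox, discarded = comp$discarded)
}

#' Split a lung mask into left and right lungs
#'
#' If the mask has exactly two large (>= 5% of lung volume) 26-connected
#' components they are assigned left/right by centroid x; otherwise the mask
#' is split by the sagittal plane through the carina x coordinate. (Internal
#' x runs patient-right to patient-left, so the right lung has the smaller
#' centroid x.)
#'
#' @param lung a `binary_mask`.
#' @param carina_mm carina point (z, y, x) mm.
#' @return list with `left` and `right` `binary_mask`s.
#' @export
split_lungs <- function(lung, carina_mm) {
  grid <- lung$grid
  if (sum(lung$voxels) == 0L)
    airtree_error("lung mask is empty", "airtree_empty_mask")
  lab <- .cc_label3d(lung$voxels, grid$shape, 26L)
  sizes <- tabulate(lab[lab > 0L])
  big <- which(sizes >= 0.05 * sum(sizes))
  x_mm <- function(sel) ((which(sel, arr.ind = TRUE)[, 3]) - 1) * grid$spacing[3]
  if (length(big) == 2L) {
    m1 <- array(lab == big[1], dim = grid$shape)
    m2 <- array(lab == big[2], dim = grid$shape)
    if (mean(x_mm(m1)) < mean(x_mm(m2))) {
      right <- m1; left <- m2
    } else {
      right <- m2; left <- m1
    }
  } else {
    xs <- (slice.index(lung$voxels, 3) - 1) * grid$spacing[3]
    right <- lung$voxels & xs < carina_mm[3]
    left <- lung$voxels & !(xs < carina_mm[3])
  }
  list(left = binary_mask(left, grid), right = binary_mask(right, grid))
}

#' Binary maximum-intensity projection of a mask
#'
#' `axis = "z"` collapses the superior-inferior axis, giving the
#' transverse-plane image P_Z (y rows, x columns); `axis = "y"` collapses
#' the anterior-posterior axis, giving the frontal-plane image P_Y (z rows,
#' x columns).
#'
#' @param mask a `binary_mask` (or logical array).
#' @param axis `"z"` or `"y"`.
#' @return logical matrix.
#' @export
project_mask <- function(mask, axis = c("z", "y")) {
  axis <- match.arg(axis)
  vox <- if (inherits(mask, "binary_mask")) mask$voxels else mask
  if (axis == "z") apply(vox, c(2, 3), any) else apply(vox, c(1, 3), any)
}

#' Compute projection distance fields
#'
#' Builds P_Z from the airway minus the trachea, partitions its pixels into
#' left/right by the lung split, places per-lung adjusted central points at
#' the centroids of each lung's airway pixels, and normalises each pixel's
#' in-plane Euclidean distance by the maximum within its lung. Also
#' estimates the tree height (maximum depth of any non-trachea airway voxel
#' below the carina) used for the vertical depth fraction H.
#'
#' Geometry (centres, maxima, height) is estimated from the largest
#' connected component; pixels contributed only by disconnected debris are
#' still assigned (clamped) distances so every voxel can be classified.
#'
#' @param airway a `binary_mask`.
#' @param lungs list with `left`/`right` masks from [split_lungs()].
#' @param trachea_info result of [locate_trachea()].
#' @param config a [decomposition_config()].
#' @return A `distance_fields` object.
#' @export
compute_distance_fields <- function(airway, lungs, trachea_info,
                                    config = decomposition_config()) {
  grid <- airway$grid
  sp <- grid$spacing
  nt_all <- airway$voxels & !trachea_info$trachea
  nt_comp <- trachea_info$component & !trachea_info$trachea
  if (!any(nt_comp))
    airtree_error("no airway voxels below the carina", "airtree_empty_mask")

  pz <- project_mask(nt_all, "z")
  py <- project_mask(nt_all, "y")
  pix <- which(pz, arr.ind = TRUE)      # (iy, ix)
  pz_comp <- project_mask(nt_comp, "z")

  # voxel side: lung membership, falling back to the carina sagittal plane
  side_vox <- array(0L, dim = grid$shape)
  side_vox[lungs$right$voxels] <- -1L
  side_vox[lungs$left$voxels] <- 1L
  xs_mm <- (slice.index(side_vox, 3) - 1) * sp[3]
  fallback <- ifelse(xs_mm < trachea_info$carina_mm[3], -1L, 1L)
  side_vox[side_vox == 0L] <- fallback[side_vox == 0L]

  # pixel side: majority over the column's airway voxels; exact ties fall
  # back to the pixel's own x position
  n_pix <- nrow(pix)
  side_pix <- integer(n_pix)
  for (k in seq_len(n_pix)) {
    col_sides <- side_vox[, pix[k, 1], pix[k, 2]][nt_all[, pix[k, 1], pix[k, 2]]]
    s <- sum(col_sides)
    side_pix[k] <- if (s != 0) sign(s) else
      (if ((pix[k, 2] - 1) * sp[3] < trachea_info$carina_mm[3]) -1L else 1L)
  }

  y_mm <- (pix[, 1] - 1) * sp[2]
  x_mm <- (pix[, 2] - 1) * sp[3]
  in_comp <- pz_comp[cbind(pix[, 1], pix[, 2])]

  centres <- list(left = c(NA_real_, NA_real_), right = c(NA_real_, NA_real_))
  D_pix <- rep(NA_real_, n_pix)
  for (s in c(-1L, 1L)) {
    name <- if (s == 1L) "left" else "right"
    sel <- side_pix == s
    sel_ref <- sel & in_comp
    if (!any(sel_ref)) {
      if (any(sel)) {
        warning(sprintf("%s lung has only disconnected airway pixels", name))
        sel_ref <- sel
      } else {
        warning(sprintf("%s lung contains no airway pixels", name))
        next
      }
    }
    cy <- mean(y_mm[sel_ref]); cx <- mean(x_mm[sel_ref])
    centres[[name]] <- c(cy, cx)
    d <- sqrt((y_mm[sel] - cy)^2 + (x_mm[sel] - cx)^2)
    dmax <- max(sqrt((y_mm[sel_ref] - cy)^2 + (x_mm[sel_ref] - cx)^2))
    D_pix[sel] <- if (dmax > 0) pmin(d / dmax, 1) else 0
  }

  D <- matrix(NA_real_, nrow = nrow(pz), ncol = ncol(pz))
  D[cbind(pix[, 1], pix[, 2])] <- D_pix
  side_mat <- matrix(NA_integer_, nrow = nrow(pz), ncol = ncol(pz))
  side_mat[cbind(pix[, 1], pix[, 2])] <- side_pix

  z_carina <- trachea_info$carina_mm[1]
  z_nt <- (which(nt_comp, arr.ind = TRUE)[, 1] - 1) * sp[1]
  height <- max(z_nt - z_carina)
  if (height <= 0) {
    warning("degenerate tree height; vertical depth set to zero")
    height <- NA_real_
  }

  structure(list(pz = pz, py = py, D = D, side = side_mat,
                 centres = centres, carina_mm = trachea_info$carina_mm,
                 height_mm = height, grid = grid),
            class = "distance_fields")
}

# H(v): vertical depth fraction below the carina, clamped to [0, 1]
vertical_fraction <- function(fields, z_index) {
  if (is.na(fields$height_mm)) return(rep(0, length(z_index)))
  z_mm <- (z_index - 1) * fields$grid$spacing[1]
  pmin(pmax((z_mm - fields$carina_mm[1]) / fields$height_mm, 0), 1)
}

threshold_classes <- function(v, config) {
  ifelse(v >= config$t_terminal, AIRWAY_LABELS[["terminal"]],
         ifelse(v >= config$t_small, AIRWAY_LABELS[["small"]],
                AIRWAY_LABELS[["medium"]]))
}

# distance value actually thresholded: the normalised distance itself, or
# its empirical quantile rank within the lung
effective_distance <- function(fields, config) {
  if (config$threshold_mode == "normalised") return(fields$D)
  V <- fields$D
  for (s in c(-1L, 1L)) {
    sel <- !is.na(fields$side) & fields$side == s
    if (!any(sel)) next
    V[sel] <- ecdf(fields$D[sel])(fields$D[sel])
  }
  V
}

#' Preliminary pixel classification in P_Z
#'
#' Applies the percentile cuts to the (possibly rank-transformed) normalised
#' distance of every airway pixel: `>= t_terminal` terminal, `>= t_small`
#' small, else medium.
#'
#' @param fields a `distance_fields`.
#' @param config a [decomposition_config()].
#' @return integer matrix of class codes (NA off the airway projection).
#' @export
classify_preliminary <- function(fields, config = decomposition_config()) {
  V <- effective_distance(fields, config)
  cls <- matrix(NA_integer_, nrow = nrow(V), ncol = ncol(V))
  sel <- !is.na(V)
  cls[sel] <- as.integer(threshold_classes(V[sel], config))
  cls
}

#' Back-project pixel classes to a 3D label volume
#'
#' Every non-trachea airway voxel takes the class of its axial column's
#' pixel in P_Z; trachea voxels are labelled trachea.
#'
#' @param classes_pz integer class matrix from [classify_preliminary()].
#' @param airway a `binary_mask`.
#' @param trachea logical trachea array.
#' @return A `segment_labels` (preliminary).
#' @export
back_project <- function(classes_pz, airway, trachea) {
  grid <- airway$grid
  labels <- array(AIRWAY_LABELS[["background"]], dim = grid$shape)
  nt <- airway$voxels & !trachea
  idx <- which(nt, arr.ind = TRUE)
  labels[idx] <- classes_pz[cbind(idx[, 2], idx[, 3])]
  labels[trachea] <- AIRWAY_LABELS[["trachea"]]
  segment_labels(labels, grid)
}

#' Revise preliminary labels by the vertical depth constraint
#'
#' In `vertical-max` mode each voxel's combined score is `S = max(D, H)`
#' where `D` is its column's (effective) normalised distance and `H` its
#' vertical depth fraction below the carina; the same cuts are applied to
#' `S` and only promotions toward more distal classes can occur. In `off`
#' mode the labels pass through unchanged.
#'
#' @param preliminary a `segment_labels` from [back_project()].
#' @param fields a `distance_fields`.
#' @param config a [decomposition_config()].
#' @return A `segment_labels` (final).
#' @export
revise_labels <- function(preliminary, fields, config = decomposition_config()) {
  if (config$revision == "off") return(preliminary)
  labels <- preliminary$labels
  V <- effective_distance(fields, config)
  sel <- labels >= AIRWAY_LABELS[["medium"]]
  idx <- which(sel, arr.ind = TRUE)
  if (nrow(idx)) {
    d <- V[cbind(idx[, 2], idx[, 3])]
    h <- vertical_fraction(fields, idx[, 1])
    s <- pmax(d, h, na.rm = TRUE)
    revised <- as.integer(threshold_classes(s, config))
    labels[idx] <- pmax(labels[idx], revised)   # promotion-only
  }
  segment_labels(labels, preliminary$grid)
}

#' Decompose an airway mask into branch classes
#'
#' Full pipeline: [locate_trachea()] -> [split_lungs()] ->
#' [compute_distance_fields()] -> [classify_preliminary()] ->
#' [back_project()] -> [revise_labels()]. Deterministic. The returned
#' labels carry a `report` attribute with the carina slice/point, adjusted
#' central points, tree height, discarded-voxel count and per-class counts
#' and volumes.
#'
#' @param airway,lung `binary_mask`s on a shared grid.
#' @param config a [decomposition_config()].
#' @return A `segment_labels` with attribute `report`.
#' @export
decompose <- function(airway, lung, config = decomposition_config()) {
  if (!grid_equal(airway$grid, lung$grid))
    airtree_error("airway and lung masks must share a grid", "airtree_bad_grid")
  tr <- locate_trachea(airway, config)
  lungs <- split_lungs(lung, tr$carina_mm)
  fields <- compute_distance_fields(airway, lungs, tr, config)
  cls <- classify_preliminary(fields, config)
  prelim <- back_project(cls, airway, tr$trachea)
  final <- revise_labels(prelim, fields, config)
  counts <- label_counts(final)
  vox_ml <- voxel_volume_mm3(airway$grid) / 1000
  report <- list(
    carina_slice = tr$carina_slice,
    carina_mm = tr$carina_mm,
    centres_mm = fields$centres,
    tree_height_mm = fields$height_mm,
    discarded_voxels = tr$discarded,
    class_counts = as.list(counts),
    class_volumes_ml = as.list(counts * vox_ml),
    config = unclass(config))
  attr(final, "report") <- report
  final
}
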