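# Volume biomarkers: branch-class volumes normalised to total lung volume.

#' Segment volume biomarkers
#'
#' Converts a decomposition into the airway volume biomarkers, each
#' expressed as a percentage of total lung volume: STermAV (terminal),
#' SSmallAV (small), SMedAV (medium), STotalAV (their sum; the trachea is
#' excluded by construction) and SPAV (primary airway volume, small +
#' terminal).
#'
#' @param labels a `segment_labels`.
#' @param lung a `binary_mask` on the same grid.
#' @return A `biomarker_set`: percentages, raw volumes (mL) and lung volume.
#' @export
segment_volumes <- function(labels, lung) {
  if (!grid_equal(labels$grid, lung$grid))
    airtree_error("labels and lung mask must share a grid", "airtree_bad_grid")
  lung_ml <- mask_volume_ml(lung)
  if (lung_ml <= 0)
    airtree_error("lung mask is empty", "airtree_empty_mask")
  vox_ml <- voxel_volume_mm3(labels$grid) / 1000
  counts <- label_counts(labels)
  vols <- counts * vox_ml
  pct <- function(v) 100 * v / lung_ml
  structure(list(
    STermAV = pct(vols[["terminal"]]),
    SSmallAV = pct(vols[["small"]]),
    SMedAV = pct(vols[["medium"]]),
    STotalAV = pct(vols[["terminal"]] + vols[["small"]] + vols[["medium"]]),
    SPAV = pct(vols[["terminal"]] + vols[["small"]]),
    volumes_ml = list(terminal = vols[["terminal"]], small = vols[["small"]],
                      medium = vols[["medium"]], trachea = vols[["trachea"]]),
    lung_volume_ml = lung_ml), class = "biomarker_set")
}

#' @export
print.biomarker_set <- function(x, ...) {
  cat("<biomarker_set> (% of lung volume)\n")
  for (k in c("STermAV", "SSmallAV", "SMedAV", "STotalAV", "SPAV"))
    cat(sprintf("  %-9s %.4f\n", k, x[[k]]))
  cat(sprintf("  lung volume %.1f mL\n", x$lung_volume_ml))
  invisible(x)
}

#' Convert biomarkers to survival-model covariate units
#'
#' One covariate unit corresponds to a 0.1 percentage-point increment of
#' airway volume normalised by lung volume, the scale on which hazard
#' ratios for these biomarkers are reported.
#'
#' @param b a `biomarker_set`, or a numeric vector of percentages.
#' @return named numeric vector of covariate values (percent / 0.1).
#' @export
to_model_units <- function(b) {
  if (inherits(b, "biomarker_set")) {
    v <- unlist(b[c("STermAV", "SSmallAV", "SMedAV", "STotalAV", "SPAV")])
  } else {
    v <- b
  }
  v / 0.1
}

#' Tertile risk groups
#'
#' Cuts a biomarker vector at its empirical 1/3 and 2/3 quantiles into
#' low/medium/high groups; values tied with a boundary all go to the lower
#' group.
#'
#' @param values numeric vector with at least 3 distinct values.
#' @return factor with levels `low`, `medium`, `high`; attribute `cuts`
#'   holds the two quantiles and `sizes` the group sizes.
#' @export
tertile_groups <- function(values) {
  if (anyNA(values))
    airtree_error("tertile grouping requires complete values", "airtree_bad_values")
  if (length(unique(values)) < 3L)
    airtree_error("need at least 3 distinct values for tertiles", "airtree_bad_values")
  cuts <- unname(quantile(values, c(1 / 3, 2 / 3), type = 7))
  g <- ifelse(values <= cuts[1], "low", ifelse(values <= cuts[2], "medium", "high"))
  g <- factor(g, levels = c("low", "medium", "high"))
  attr(g, "cuts") <- cuts
  attr(g, "sizes") <- table(g)
  g
}

#' Serialise biomarkers to JSON
#' @param b a `biomarker_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_biomarkers <- function(b, path) {
  out <- list(STermAV = b$STermAV, SSmallAV = b$SSmallAV, SMedAV = b$SMedAV,
              STotalAV = b$STotalAV, SPAV = b$SPAV,
              volumes_ml = b$volumes_ml, lung_volume_ml = b$lung_volume_ml)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
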