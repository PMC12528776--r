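# Voxel grids, binary masks, NIfTI-1 I/O and cohort tables.
#
# Package-wide axis convention: array index 1 = z (superior -> inferior,
# slice 1 the most superior), index 2 = y (anterior -> posterior),
# index 3 = x (patient-right -> patient-left). A voxel is a point sample at
# its centre; physical position (mm) = (index - 1) * spacing.

airtree_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "airtree_error")))
}

#' Voxel grid descriptor
#'
#' @param shape integer triple `(nz, ny, nx)`.
#' @param spacing numeric triple `(sz, sy, sx)` in mm, all positive.
#' @return A `voxel_grid` object.
#' @export
voxel_grid <- function(shape, spacing = c(1, 1, 1)) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  if (length(shape) != 3L || any(shape < 1L))
    airtree_error("shape must be three integers >= 1", "airtree_bad_grid")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    airtree_error("spacing must be three positive mm values", "airtree_bad_grid")
  structure(list(shape = shape, spacing = spacing, axes = "zyx:sup-ant-right"),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid %dx%dx%d (z,y,x), spacing %.3gx%.3gx%.3g mm>\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

grid_equal <- function(a, b) {
  identical(a$shape, b$shape) && all(abs(a$spacing - b$spacing) < 1e-9)
}

voxel_volume_mm3 <- function(grid) prod(grid$spacing)

#' Binary mask on a voxel grid
#'
#' @param voxels logical 3D array with `dim == grid$shape`.
#' @param grid a [voxel_grid()].
#' @return A `binary_mask` object.
#' @export
binary_mask <- function(voxels, grid) {
  if (!is.logical(voxels)) {
    storage.mode(voxels) <- "logical"
  }
  if (!identical(as.integer(dim(voxels)), grid$shape))
    airtree_error("voxel array does not match grid shape", "airtree_bad_grid")
  voxels[is.na(voxels)] <- FALSE
  structure(list(grid = grid, voxels = voxels), class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask %d foreground voxels, %.2f mL>\n",
              sum(x$voxels), mask_volume_ml(x)))
  invisible(x)
}

#' Physical volume of a mask in millilitres
#' @param mask a `binary_mask`.
#' @return volume in mL (count x voxel volume / 1000).
#' @export
mask_volume_ml <- function(mask) {
  sum(mask$voxels) * voxel_volume_mm3(mask$grid) / 1000
}

#' Segment label volume
#'
#' Per-voxel decomposition result with codes 0 background, 1 trachea,
#' 2 medium, 3 small, 4 terminal.
#'
#' @param labels integer 3D array of codes in 0..4.
#' @param grid a [voxel_grid()].
#' @return A `segment_labels` object.
#' @export
segment_labels <- function(labels, grid) {
  storage.mode(labels) <- "integer"
  if (!identical(as.integer(dim(labels)), grid$shape))
    airtree_error("label array does not match grid shape", "airtree_bad_grid")
  if (anyNA(labels) || min(labels) < 0L || max(labels) > 4L)
    airtree_error("label codes must lie in 0..4", "airtree_bad_labels")
  structure(list(grid = grid, labels = labels), class = "segment_labels")
}

#' @export
print.segment_labels <- function(x, ...) {
  counts <- label_counts(x)
  cat("<segment_labels>\n")
  print(counts)
  invisible(x)
}

#' Per-class voxel counts of a label volume
#' @param labels a `segment_labels`.
#' @return named integer vector over trachea/medium/small/terminal.
#' @export
label_counts <- function(labels) {
  tab <- tabulate(labels$labels + 1L, nbins = 5L)
  stats::setNames(tab[2:5], names(AIRWAY_LABELS)[2:5])
}

# ---------------------------------------------------------------------------
# Minimal NIfTI-1 codec. No NIfTI reader ships with the supported R stack,
# so the subset needed here (single-file .nii/.nii.gz, 3D, common dtypes,
# sform/qform nearest-axis reorientation) is implemented directly.

NIFTI_DTYPES <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE),
  `4`   = list(what = "integer", size = 2L, signed = TRUE),
  `8`   = list(what = "integer", size = 4L, signed = TRUE),
  `16`  = list(what = "double",  size = 4L, signed = TRUE),
  `64`  = list(what = "double",  size = 8L, signed = TRUE),
  `256` = list(what = "integer", size = 1L, signed = TRUE),
  `512` = list(what = "integer", size = 2L, signed = FALSE)
)

nifti_open <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

read_nifti_raw <- function(path) {
  if (!file.exists(path))
    airtree_error(paste0("file not found: ", path), "airtree_missing_file")
  con <- nifti_open(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L)
    airtree_error("truncated NIfTI header", "airtree_bad_nifti")
  endian <- "little"
  sizeof <- readBin(hdr[1:4], "integer", size = 4L, endian = endian)
  if (sizeof != 348L) {
    endian <- "big"
    sizeof <- readBin(hdr[1:4], "integer", size = 4L, endian = endian)
  }
  magic <- rawToChar(hdr[345:347])
  if (sizeof != 348L || !(magic %in% c("n+1", "ni1")))
    airtree_error("not a NIfTI-1 file", "airtree_bad_nifti")
  if (magic == "ni1")
    airtree_error("two-file NIfTI (.hdr/.img) is not supported", "airtree_bad_nifti")
  i16 <- function(off, n) readBin(hdr[(off + 1):(off + 2L * n)], "integer",
                                  n = n, size = 2L, endian = endian)
  f32 <- function(off, n) readBin(hdr[(off + 1):(off + 4L * n)], "double",
                                  n = n, size = 4L, endian = endian)
  dims <- i16(40L, 8L)
  ndim <- dims[1]
  datatype <- i16(70L, 1L)
  pixdim <- f32(76L, 8L)
  vox_offset <- f32(108L, 1L)
  scl_slope <- f32(112L, 1L)
  scl_inter <- f32(116L, 1L)
  qform_code <- i16(252L, 1L)
  sform_code <- i16(254L, 1L)
  quatern <- f32(256L, 3L)
  qoffset <- f32(268L, 3L)
  srow <- matrix(f32(280L, 12L), nrow = 3, byrow = TRUE)
  dt <- NIFTI_DTYPES[[as.character(datatype)]]
  if (is.null(dt))
    airtree_error(sprintf("unsupported NIfTI datatype %d", datatype),
                  "airtree_bad_nifti")
  if (ndim < 1L || ndim > 7L)
    airtree_error("corrupt NIfTI dim field", "airtree_bad_nifti")
  shape <- pmax(dims[2:(ndim + 1L)], 1L)
  pad <- as.integer(round(vox_offset)) - 348L
  if (pad > 0) readBin(con, "raw", n = pad)
  n <- prod(shape)
  vals <- readBin(con, dt$what, n = n, size = dt$size, signed = dt$signed,
                  endian = endian)
  if (length(vals) < n)
    airtree_error("truncated NIfTI data", "airtree_bad_nifti")
  if (!is.na(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && (is.na(scl_inter) || scl_inter == 0)))
    vals <- vals * scl_slope + ifelse(is.na(scl_inter), 0, scl_inter)
  arr <- array(vals, dim = shape)
  affine <- nifti_affine(sform_code, srow, qform_code, quatern, qoffset, pixdim)
  list(array = arr, ndim = ndim, pixdim = pixdim, affine = affine,
       datatype = datatype)
}

nifti_affine <- function(sform_code, srow, qform_code, quatern, qoffset, pixdim) {
  if (sform_code > 0L) return(srow[, 1:3, drop = FALSE])
  if (qform_code > 0L) {
    b <- quatern[1]; c <- quatern[2]; d <- quatern[3]
    a2 <- max(0, 1 - b * b - c * c - d * d)
    a <- sqrt(a2)
    rot <- matrix(c(
      a * a + b * b - c * c - d * d, 2 * (b * c - a * d), 2 * (b * d + a * c),
      2 * (b * c + a * d), a * a + c * c - b * b - d * d, 2 * (c * d - a * b),
      2 * (b * d - a * c), 2 * (c * d + a * b), a * a + d * d - b * b - c * c
    ), nrow = 3, byrow = TRUE)
    qfac <- if (pixdim[1] < 0) -1 else 1
    sc <- c(pixdim[2], pixdim[3], pixdim[4] * qfac)
    return(rot %*% diag(sc))
  }
  # no orientation info: assume file axes already follow RAS directions
  diag(abs(pixdim[2:4]))
}

# Map file axes (fastest-varying first) onto the package (z, y, x) convention.
# Each file axis is assigned its dominant RAS world axis; the internal index
# must increase toward Inferior / Posterior / Left respectively, so an axis
# whose world direction is positive gets flipped.
reorient_to_canonical <- function(arr, affine) {
  dominant <- integer(3)
  flip <- logical(3)
  spacing_file <- numeric(3)
  for (f in 1:3) {
    v <- affine[, f]
    dominant[f] <- which.max(abs(v))
    flip[f] <- v[dominant[f]] > 0
    spacing_file[f] <- sqrt(sum(v^2))
  }
  if (length(unique(dominant)) != 3L)
    airtree_error("oblique NIfTI orientation not supported", "airtree_bad_nifti")
  # internal target axis per world axis: S/I -> 1, A/P -> 2, R/L -> 3
  target <- c(3L, 2L, 1L)[dominant]   # world 1 (R) -> internal 3, etc.
  perm <- order(target)               # perm[i] = file axis feeding internal i
  out <- aperm(arr, perm)
  fl <- flip[perm]
  idx <- lapply(1:3, function(i) if (fl[i]) rev(seq_len(dim(out)[i])) else seq_len(dim(out)[i]))
  out <- out[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  spacing <- spacing_file[perm]
  # record increasing-index direction per original file axis
  orient_codes <- ifelse(flip, c("R", "A", "S")[dominant],
                         c("L", "P", "I")[dominant])
  list(array = out, spacing = spacing,
       original_orientation = paste(orient_codes, collapse = ""))
}

#' Read a binary mask from a NIfTI-1 volume
#'
#' The volume is reoriented to the package axis convention (z superior-first,
#' y anterior-first, x patient-right-first) using its sform/qform.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param binarize `"strict"` (error if voxel values are not 0/1 within
#'   `tol`) or `"threshold"` (foreground = value > 0.5).
#' @param tol tolerance for strict binarisation.
#' @return A `binary_mask`; attribute `orientation` records the original
#'   increasing-index directions of the file axes.
#' @export
read_mask <- function(path, binarize = c("strict", "threshold"), tol = 1e-3) {
  binarize <- match.arg(binarize)
  nf <- read_nifti_raw(path)
  if (nf$ndim != 3L)
    airtree_error("not a 3D mask", "airtree_not_3d")
  re <- reorient_to_canonical(nf$array, nf$affine)
  vals <- re$array
  if (binarize == "strict") {
    bad <- abs(vals) > tol & abs(vals - 1) > tol
    if (any(bad))
      airtree_error(sprintf("non-binary mask content: %d voxels outside {0,1}",
                            sum(bad)), "airtree_not_binary")
  }
  grid <- voxel_grid(dim(vals), re$spacing)
  m <- binary_mask(vals > 0.5, grid)
  attr(m, "orientation") <- re$original_orientation
  m
}

nifti_header_raw <- function(shape_file, spacing_file, datatype, bitpix) {
  hdr <- raw(348L)
  put <- function(off, b) hdr[(off + 1):(off + length(b))] <<- b
  put_i32 <- function(off, v) put(off, writeBin(as.integer(v), raw(), size = 4L))
  put_i16 <- function(off, v) put(off, writeBin(as.integer(v), raw(), size = 2L))
  put_f32 <- function(off, v) put(off, writeBin(as.numeric(v), raw(), size = 4L))
  put_i32(0L, 348L)
  put_i16(40L, c(3L, shape_file, 1L, 1L, 1L, 1L))
  put_i16(70L, datatype)
  put_i16(72L, bitpix)
  put_f32(76L, c(1, spacing_file, 1, 1, 1, 1))
  put_f32(108L, 352)            # vox_offset
  put_f32(112L, 1); put_f32(116L, 0)   # scl_slope / scl_inter
  put_i16(252L, 0L)             # qform_code
  put_i16(254L, 1L)             # sform_code
  # canonical writer orientation: file axes run toward Left/Posterior/Inferior
  put_f32(280L, c(-spacing_file[1], 0, 0, (shape_file[1] - 1) * spacing_file[1]))
  put_f32(296L, c(0, -spacing_file[2], 0, (shape_file[2] - 1) * spacing_file[2]))
  put_f32(312L, c(0, 0, -spacing_file[3], (shape_file[3] - 1) * spacing_file[3]))
  hdr[345:348] <- c(charToRaw("n+1"), as.raw(0L))
  hdr
}

write_nifti_array <- function(arr, spacing, path, datatype) {
  # arr in internal (z, y, x) order; file order is (x, y, z)
  arr_file <- aperm(arr, c(3L, 2L, 1L))
  spacing_file <- spacing[c(3L, 2L, 1L)]
  dt <- NIFTI_DTYPES[[as.character(datatype)]]
  hdr <- nifti_header_raw(dim(arr_file), spacing_file, datatype, dt$size * 8L)
  con <- tryCatch(nifti_open(path, "wb"),
                  error = function(e) airtree_error(
                    paste0("cannot open for writing: ", path),
                    "airtree_unwritable"))
  on.exit(close(con))
  writeBin(hdr, con)
  writeBin(raw(4L), con)  # extension flag
  if (dt$what == "integer") {
    writeBin(as.integer(arr_file), con, size = dt$size)
  } else {
    writeBin(as.numeric(arr_file), con, size = dt$size)
  }
  invisible(path)
}

#' Write a binary mask as NIfTI-1 (uint8)
#' @param mask a `binary_mask`.
#' @param path output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  write_nifti_array(array(as.integer(mask$voxels), dim = mask$grid$shape),
                    mask$grid$spacing, path, datatype = 2L)
}

#' Write a segment label volume as NIfTI-1 (uint8)
#'
#' Codes: 0 background, 1 trachea, 2 medium, 3 small, 4 terminal.
#' Read-back with [read_labels()] reproduces the array exactly.
#'
#' @param labels a `segment_labels`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  write_nifti_array(labels$labels, labels$grid$spacing, path, datatype = 2L)
}

#' Read a segment label volume from NIfTI-1
#' @param path path to a label volume written by [write_labels()].
#' @return A `segment_labels`.
#' @export
read_labels <- function(path) {
  nf <- read_nifti_raw(path)
  if (nf$ndim != 3L)
    airtree_error("not a 3D mask", "airtree_not_3d")
  re <- reorient_to_canonical(nf$array, nf$affine)
  vals <- round(re$array)
  if (any(vals < 0 | vals > 4))
    airtree_error("label codes must lie in 0..4", "airtree_bad_labels")
  segment_labels(array(as.integer(vals), dim = dim(vals)),
                 voxel_grid(dim(vals), re$spacing))
}

# ---------------------------------------------------------------------------
# Cohort tables

#' Read a survival cohort from CSV
#'
#' Requires columns `id`, `time` (years) and `event` (0/1); all other
#' columns are kept as covariates. Rows with missing or invalid required
#' fields (`time <= 0`, `event` not 0/1) are dropped and counted.
#'
#' @param path CSV path.
#' @return A data frame of class `cohort`; attribute `dropped` reports the
#'   number of rejected rows and the reasons.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path))
    airtree_error(paste0("file not found: ", path), "airtree_missing_file")
  df <- read.csv(path, stringsAsFactors = FALSE)
  as_cohort(df)
}

#' Coerce a data frame to a cohort
#' @param df data frame with `id`, `time`, `event` columns.
#' @return A `cohort` data frame (invalid rows dropped and counted).
#' @export
as_cohort <- function(df) {
  required <- c("id", "time", "event")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    airtree_error(paste0("cohort is missing required column(s): ",
                         paste(missing_cols, collapse = ", ")),
                  "airtree_missing_column")
  df$time <- as.numeric(df$time)
  df$event <- as.numeric(df$event)
  bad_na <- is.na(df$time) | is.na(df$event) | is.na(df$id)
  bad_time <- !bad_na & df$time <= 0
  bad_event <- !bad_na & !(df$event %in% c(0, 1))
  keep <- !(bad_na | bad_time | bad_event)
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cohort", "data.frame")
  attr(out, "dropped") <- list(
    n = sum(!keep),
    missing = sum(bad_na), nonpositive_time = sum(bad_time),
    bad_event = sum(bad_event))
  out
}
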