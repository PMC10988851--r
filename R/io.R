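# File-format plumbing: DWI volumes with FSL-dialect gradient tables, label
# maps, parameter-map serialization, and the tidy ROI metric table.

ROI_LEGEND <- c(`0` = "background", `1` = "CO", `2` = "OS", `3` = "IS")

ROI_TABLE_COLS <- c("subject", "group", "timepoint", "region", "metric", "value")

#' Construct a DWI volume
#'
#' @param data 4D nonnegative signal array (x, y, z, volume).
#' @param scheme a `gradient_scheme`; its length must match the 4th dimension.
#' @param voxel_size voxel dimensions in mm.
#' @param affine optional 4x4 voxel-to-world matrix.
#' @return An object of class `dwi_volume`.
#' @export
dwi_volume <- function(data, scheme, voxel_size = c(1, 1, 1), affine = NULL) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  if (length(dim(data)) != 4L)
    stop("data must be a 4D array (x, y, z, volume)")
  if (dim(data)[4] != scheme$n_volumes)
    stop("format error: image has ", dim(data)[4], " volumes but the scheme ",
         "describes ", scheme$n_volumes)
  if (any(data < 0)) stop("signal values must be nonnegative")
  if (is.null(affine)) affine <- diag(c(voxel_size, 1))
  structure(list(data = data, scheme = scheme,
                 voxel_size = as.numeric(voxel_size), affine = affine),
            class = "dwi_volume")
}

#' Construct an ROI label map
#'
#' @param labels 3D integer array; 0 = background, codes per `legend`.
#' @param legend named character vector mapping codes to region names.
#' @return An object of class `label_map`.
#' @export
label_map <- function(labels, legend = ROI_LEGEND) {
  if (length(dim(labels)) != 3L) stop("labels must be a 3D array")
  codes <- unique(as.integer(labels))
  known <- as.integer(names(legend))
  if (!all(codes %in% known))
    stop("label codes outside legend: ", paste(setdiff(codes, known), collapse = ", "))
  structure(list(labels = labels, legend = legend), class = "label_map")
}

# FSL-dialect gradient tables -------------------------------------------

#' Read and write FSL bval/bvec gradient tables
#'
#' bval: one whitespace-delimited row of b-values. bvec: 3 rows x N columns
#' of direction components. Columns with nonzero b are renormalized to unit
#' length when their norm deviates from 1 by less than 1e-3, and rejected
#' otherwise.
#'
#' @param bval_path,bvec_path text file paths.
#' @return `read_bval_bvec()`: a `gradient_scheme`.
#' @export
read_bval_bvec <- function(bval_path, bvec_path) {
  bvals <- scan(bval_path, quiet = TRUE)
  bvec_rows <- utils::read.table(bvec_path)
  if (nrow(bvec_rows) != 3L)
    stop("format error: bvec must have 3 rows (FSL dialect), got ",
         nrow(bvec_rows))
  bvecs <- t(as.matrix(bvec_rows))
  if (nrow(bvecs) != length(bvals))
    stop("format error: ", length(bvals), " b-values vs ", nrow(bvecs),
         " bvec columns")
  nb <- bvals > 0
  norms <- sqrt(rowSums(bvecs^2))
  bad <- nb & abs(norms - 1) >= 1e-3
  if (any(bad))
    stop("format error: non-unit, non-renormalizable directions at volumes ",
         paste(which(bad), collapse = ", "))
  fix <- nb & norms > 0
  bvecs[fix, ] <- bvecs[fix, , drop = FALSE] / norms[fix]
  # determinability for kurtosis fitting is enforced by the fitting layer,
  # not the format reader
  gradient_scheme(bvals, bvecs, require_kurtosis = FALSE)
}

#' @rdname read_bval_bvec
#' @param scheme a `gradient_scheme` to serialize.
#' @export
write_bval_bvec <- function(scheme, bval_path, bvec_path) {
  writeLines(paste(format(scheme$bvals, trim = TRUE, scientific = FALSE),
                   collapse = " "), bval_path)
  rows <- apply(t(scheme$bvecs), 1, function(r)
    paste(formatC(r, format = "g", digits = 17), collapse = " "))
  writeLines(rows, bvec_path)
  invisible(c(bval_path, bvec_path))
}

#' Read a DWI volume with its gradient tables
#'
#' @param nifti_path 4D NIfTI image.
#' @param bval_path,bvec_path FSL-dialect gradient tables.
#' @return A `dwi_volume`.
#' @export
read_dwi <- function(nifti_path, bval_path, bvec_path) {
  img <- read_nifti(nifti_path)
  scheme <- read_bval_bvec(bval_path, bvec_path)
  if (length(dim(img$data)) == 3L) dim(img$data) <- c(dim(img$data), 1L)
  dwi_volume(img$data, scheme, voxel_size = img$voxel_size, affine = img$affine)
}

#' @rdname read_dwi
#' @param dwi a `dwi_volume`.
#' @param prefix output path prefix; writes `<prefix>.nii.gz`, `<prefix>.bval`,
#'   `<prefix>.bvec`.
#' @export
write_dwi <- function(dwi, prefix) {
  write_nifti(dwi$data, paste0(prefix, ".nii.gz"),
              voxel_size = dwi$voxel_size, affine = dwi$affine,
              datatype = "float64")
  write_bval_bvec(dwi$scheme, paste0(prefix, ".bval"), paste0(prefix, ".bvec"))
  invisible(prefix)
}

#' Write parameter maps as NIfTI files
#'
#' One float32 NIfTI per metric (`mk.nii.gz`, `fa.nii.gz`, `md.nii.gz`,
#' `s0.nii.gz`) with the source affine.
#'
#' @param maps a `parameter_maps` object (see [maps_from_fit()]).
#' @param directory output directory, created on demand.
#' @return Named vector of written paths, invisibly.
#' @export
write_maps <- function(maps, directory) {
  stopifnot(inherits(maps, "parameter_maps"))
  shapes <- lapply(maps[c("mk", "fa", "md", "s0")], dim)
  if (length(unique(vapply(shapes, paste, "", collapse = "x"))) != 1L)
    stop("parameter maps must share one grid")
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  out <- c(mk = "mk.nii.gz", fa = "fa.nii.gz", md = "md.nii.gz", s0 = "s0.nii.gz")
  paths <- file.path(directory, out)
  names(paths) <- names(out)
  for (m in names(out)) {
    write_nifti(maps[[m]], paths[[m]], voxel_size = maps$voxel_size,
                affine = maps$affine, datatype = "float32")
  }
  invisible(paths)
}

#' @rdname write_maps
#' @export
write_label_map <- function(labels, path, voxel_size = c(1, 1, 1), affine = NULL) {
  stopifnot(inherits(labels, "label_map"))
  write_nifti(labels$labels, path, voxel_size = voxel_size, affine = affine,
              datatype = "int32")
}

#' @rdname write_maps
#' @param path NIfTI path of an integer label image.
#' @export
read_label_map <- function(path, legend = ROI_LEGEND) {
  img <- read_nifti(path)
  label_map(array(as.integer(round(img$data)), dim = dim(img$data)[1:3]), legend)
}

# ROI metric tables -------------------------------------------------------

validate_roi_table <- function(df) {
  missing <- setdiff(ROI_TABLE_COLS, names(df))
  if (length(missing))
    stop("format error: ROI table lacks required column(s): ",
         paste(missing, collapse = ", "))
  key_cols <- intersect(c("subject", "group", "timepoint", "region", "metric",
                          "rater"), names(df))
  key <- do.call(paste, c(df[key_cols], sep = "\r"))
  if (anyDuplicated(key))
    stop("duplicate-key error: repeated (subject, region, metric, timepoint",
         if ("rater" %in% names(df)) ", rater", ") rows")
  if (!is.numeric(df$value)) stop("format error: value column must be numeric")
  df
}

#' Read and write tidy ROI metric tables
#'
#' Long-format CSV with columns subject, group, timepoint, region, metric,
#' value and optionally rater; one row per measurement. Numeric values round
#' trip at 15 significant digits.
#'
#' @param path CSV path.
#' @return A validated data frame.
#' @export
read_roi_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_roi_table(df)
}

#' @rdname read_roi_table
#' @param table an ROI table data frame.
#' @export
write_roi_table <- function(table, path) {
  validate_roi_table(table)
  out <- table
  out$value <- formatC(out$value, format = "g", digits = 15)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
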