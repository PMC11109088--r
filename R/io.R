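# NIfTI + JSON-sidecar I/O for series and maps, CSV for tables.
# Volumes are written RAS+ with the voxel spacing in the header; masks are
# integer-labeled NIfTI aligned voxelwise to their series.

#' Write an image series as NIfTI + JSON sidecar
#'
#' `<prefix>.nii.gz` holds the 4D stack; `<prefix>.json` holds the
#' acquisition metadata (b-values, flip angles in degrees, TR in ms, frame
#' times in s, injection frame, relaxivity, replicate id).
#'
#' @param series an [image_series()]
#' @param prefix output path prefix
#' @return the prefix, invisibly
#' @export
write_image_series <- function(series, prefix) {
  stopifnot(inherits(series, "image_series"))
  img <- RNifti::asNifti(series$data, pixdim = series$meta$spacing_mm)
  RNifti::writeNifti(img, paste0(prefix, ".nii.gz"))
  meta <- series$meta
  meta$kind <- series$kind
  jsonlite::write_json(meta[!vapply(meta, is.null, TRUE)],
                       paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Read an image series written by [write_image_series()]
#' @param prefix path prefix (without extension)
#' @return an [image_series()]
#' @export
read_image_series <- function(prefix) {
  nii <- paste0(prefix, ".nii.gz")
  if (!file.exists(nii)) nii <- paste0(prefix, ".nii")
  assert_that(file.exists(nii), "no NIfTI at ", prefix)
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  dat <- array(as.numeric(RNifti::readNifti(nii)), dim(RNifti::readNifti(nii)))
  image_series(dat, kind = meta$kind,
               b_values = meta$b_values,
               flip_angles_deg = meta$flip_angles_deg,
               tr_ms = meta$tr_ms, frame_times_s = meta$frame_times_s,
               injection_frame = meta$injection_frame,
               relaxivity = meta$relaxivity,
               spacing_mm = meta$spacing_mm %||% c(1, 1, 1),
               replicate = meta$replicate %||% 1L)
}

#' Write a parameter map as NIfTI + JSON sidecar
#'
#' Invalid voxels are stored as NaN; units are recorded in the sidecar
#' (raw SI-consistent units, e.g. ADC in mm^2/s, never premultiplied).
#'
#' @param map a [parameter_map()]
#' @param prefix output path prefix
#' @param spacing_mm voxel spacing for the header
#' @return the prefix, invisibly
#' @export
write_parameter_map <- function(map, prefix, spacing_mm = c(1, 1, 1)) {
  stopifnot(inherits(map, "parameter_map"))
  v <- map$values
  v[!map$mask] <- NaN
  RNifti::writeNifti(RNifti::asNifti(v, pixdim = spacing_mm),
                     paste0(prefix, ".nii.gz"))
  jsonlite::write_json(list(name = map$name, units = map$units),
                       paste0(prefix, ".json"), auto_unbox = TRUE)
  invisible(prefix)
}

#' Read a parameter map written by [write_parameter_map()]
#' @param prefix path prefix
#' @return a [parameter_map()] (mask = finite voxels)
#' @export
read_parameter_map <- function(prefix) {
  nii <- RNifti::readNifti(paste0(prefix, ".nii.gz"))
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  v <- array(as.numeric(nii), dim(nii))
  parameter_map(v, is.finite(v), units = meta$units, name = meta$name)
}

#' Write an AIF as CSV (columns time_s, cp_mM)
#' @param x an [aif()]
#' @param path output path
#' @return the path, invisibly
#' @export
write_aif <- function(x, path) {
  stopifnot(inherits(x, "aif"))
  utils::write.csv(data.frame(time_s = x$time_s, cp_mM = x$cp_mM),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read an AIF CSV
#' @param path CSV with columns time_s, cp_mM
#' @param source recorded source
#' @return an [aif()]
#' @export
read_aif <- function(path, source = "measured") {
  d <- utils::read.csv(path)
  aif(d$time_s, d$cp_mM, source = source)
}

# CSV writers with fixed column order and deterministic formatting
write_table_csv <- function(d, path, digits = 10) {
  num <- vapply(d, is.numeric, TRUE)
  d[num] <- lapply(d[num], function(x) signif(x, digits))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Write the cohort table CSV
#'
#' Fixed schema: patient_id, tumor_id, visit, parameter, median, baseline,
#' delta, flag, label.
#' @param table labeled cohort table
#' @param path output path
#' @return the path, invisibly
#' @export
write_cohort_table <- function(table, path) {
  cols <- c("patient_id", "tumor_id", "visit", "parameter", "median",
            "baseline", "delta", "flag", "label")
  for (cl in setdiff(cols, names(table))) table[[cl]] <- NA
  write_table_csv(table[, cols], path)
}
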