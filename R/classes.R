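#' Image series container
#'
#' A stack of volumes (4D array, last dimension indexes volumes) plus the
#' acquisition metadata a downstream fitter needs: b-values (s/mm^2) for
#' diffusion series, flip angles (degrees) and TR (ms) for variable-flip-angle
#' series, frame times (s), injection frame and relaxivity for dynamic series.
#'
#' @param data numeric 4D array `[x, y, z, volume]` (3D input is promoted to a
#'   single-slice 4D array)
#' @param kind one of `"dwi"`, `"vfa"`, `"dce"`
#' @param b_values numeric, s/mm^2, one per volume (DWI)
#' @param flip_angles_deg numeric, degrees; one per volume (VFA) or scalar (DCE)
#' @param tr_ms repetition time in milliseconds (VFA/DCE)
#' @param frame_times_s numeric, seconds, one per frame (DCE)
#' @param injection_frame index of the first post-bolus frame (DCE)
#' @param relaxivity r1 of the contrast agent in mM^-1 s^-1 (DCE)
#' @param spacing_mm voxel spacing, length 3
#' @param replicate replicate index (DWI)
#' @return an object of class `image_series`
#' @export
image_series <- function(data, kind = c("dwi", "vfa", "dce"),
                         b_values = NULL, flip_angles_deg = NULL, tr_ms = NULL,
                         frame_times_s = NULL, injection_frame = NULL,
                         relaxivity = NULL, spacing_mm = c(1, 1, 1),
                         replicate = 1L) {
  kind <- match.arg(kind)
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  assert_that(length(dim(data)) == 4L, "image data must be a 3D or 4D array")
  nv <- dim(data)[4L]
  if (kind == "dwi") {
    assert_that(!is.null(b_values) && length(b_values) == nv,
                "a DWI series needs one b-value per volume")
    assert_that(all(b_values >= 0), "b-values must be >= 0")
  }
  if (kind == "vfa") {
    assert_that(!is.null(flip_angles_deg) && length(flip_angles_deg) == nv,
                "a VFA series needs one flip angle per volume")
    assert_that(!is.null(tr_ms) && tr_ms > 0, "TR must be positive")
  }
  if (kind == "dce") {
    assert_that(!is.null(frame_times_s) && length(frame_times_s) == nv,
                "a DCE series needs one frame time per volume")
    assert_that(all(diff(frame_times_s) > 0), "frame times must be increasing")
    assert_that(!is.null(tr_ms) && tr_ms > 0, "TR must be positive")
    assert_that(length(flip_angles_deg) == 1L, "DCE uses a single dynamic flip angle")
  }
  structure(list(data = data, kind = kind,
                 meta = list(b_values = b_values,
                             flip_angles_deg = flip_angles_deg,
                             tr_ms = tr_ms, frame_times_s = frame_times_s,
                             injection_frame = injection_frame,
                             relaxivity = relaxivity,
                             spacing_mm = spacing_mm,
                             replicate = replicate)),
            class = "image_series")
}

#' @export
print.image_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_series: %s, %dx%dx%d voxels, %d volumes>\n",
              x$kind, d[1], d[2], d[3], d[4]))
  invisible(x)
}

#' Parameter map container
#'
#' Per-voxel values of one quantitative parameter with a units string and a
#' validity mask; voxels that failed to fit are flagged, never silently zero.
#'
#' @param values numeric 3D array
#' @param mask logical 3D array of valid voxels (default: all finite values)
#' @param units unit string (e.g. `"mm^2/s"`, `"s"`, `"mM.s"`, `"1/min"`)
#' @param name short parameter name (e.g. `"adc"`)
#' @return object of class `parameter_map`
#' @export
parameter_map <- function(values, mask = NULL, units = "", name = "") {
  if (is.null(dim(values))) dim(values) <- c(length(values), 1L, 1L)
  if (is.null(mask)) mask <- is.finite(values)
  assert_that(identical(dim(values), dim(mask)), "mask must match map dimensions")
  structure(list(values = values, mask = mask, units = units, name = name),
            class = "parameter_map")
}

#' @export
print.parameter_map <- function(x, ...) {
  cat(sprintf("<parameter_map %s [%s]: %s voxels, %d valid>\n",
              x$name, x$units, paste(dim(x$values), collapse = "x"),
              sum(x$mask)))
  invisible(x)
}

#' Arterial input function
#'
#' Plasma gadolinium concentration versus time, used as the input to the
#' extended Tofts model. Concentration is zero before the injection.
#'
#' @param time_s time grid in seconds (strictly increasing)
#' @param cp_mM plasma concentration in mM, same length as `time_s`
#' @param source `"measured"` or `"analytic"`
#' @param hematocrit optional hematocrit used for blood-to-plasma conversion
#' @return object of class `aif`
#' @export
aif <- function(time_s, cp_mM, source = c("analytic", "measured"),
                hematocrit = NULL) {
  source <- match.arg(source)
  assert_that(length(time_s) == length(cp_mM), "time and concentration differ in length")
  assert_that(all(diff(time_s) > 0), "AIF time grid must be strictly increasing")
  assert_that(all(cp_mM >= -1e-12), "AIF concentration must be non-negative")
  structure(list(time_s = time_s, cp_mM = pmax(cp_mM, 0), source = source,
                 hematocrit = hematocrit), class = "aif")
}

#' @export
print.aif <- function(x, ...) {
  cat(sprintf("<aif (%s): %d samples, peak %.2f mM at %.0f s>\n",
              x$source, length(x$time_s), max(x$cp_mM),
              x$time_s[which.max(x$cp_mM)]))
  invisible(x)
}
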