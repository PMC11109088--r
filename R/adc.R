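#' Fit an ADC map from a diffusion-weighted series
#'
#' Mono-exponential model `S(b) = S0 * exp(-b * ADC)`. With exactly two
#' b-values the solution is the closed form
#' `ADC = log(S(b1)/S(b2)) / (b2 - b1)`; with more, a per-voxel log-linear
#' least squares fit. Voxels with a non-positive signal at any b-value are
#' flagged invalid rather than clamped (the log is undefined there and
#' clamping biases ADC).
#'
#' The acquisition protocol is validated against `expected_b`: a missing
#' low-b (b = 0) volume is always a hard error identifying the series, and a
#' deviating b-value set is an error under `strict = TRUE`, a warning
#' otherwise — deviating series are meant to be excluded, not adapted to.
#'
#' @param series an [image_series()] of kind `"dwi"` with >= 2 distinct b-values
#' @param expected_b protocol b-values (default `c(0, 450)` s/mm^2); NULL
#'   skips the protocol check (the low-b requirement still applies)
#' @param strict if TRUE, protocol deviation is an error; if FALSE, a warning
#' @param adc_lower lower physical bound; fitted values below it are clipped
#'   to the bound (default 0)
#' @param series_id identifier used in error messages
#' @return object of class `dwi_fit` with elements `adc` and `s0`
#'   ([parameter_map()]s) and `replicate`
#' @export
fit_adc <- function(series, expected_b = c(0, 450), strict = FALSE,
                    adc_lower = 0, series_id = "DWI series") {
  stopifnot(inherits(series, "image_series"))
  b <- series$meta$b_values
  assert_that(length(unique(b)) >= 2, series_id,
              ": need >= 2 distinct b-values to fit ADC")
  low_b <- if (is.null(expected_b)) 0 else min(expected_b)
  if (!any(b == low_b))
    stop_qmri(series_id, ": ADC cannot be computed, b = ", low_b,
              " s/mm^2 images were not acquired")
  if (!is.null(expected_b) && !setequal(b, expected_b)) {
    msg <- paste0(series_id, ": b-values {", paste(sort(unique(b)), collapse = ", "),
                  "} deviate from the protocol {",
                  paste(sort(expected_b), collapse = ", "), "}")
    if (strict) stop_qmri(msg) else warning(msg, call. = FALSE)
  }
  dm <- dim(series$data)[1:3]
  nb <- length(b)
  sig <- matrix(series$data, prod(dm), nb)
  valid <- rowSums(sig > 0) == nb
  adc <- rep(NA_real_, nrow(sig))
  s0 <- rep(NA_real_, nrow(sig))
  if (any(valid)) {
    ls <- log(sig[valid, , drop = FALSE])
    if (nb == 2L) {
      o <- order(b)
      slope <- (ls[, o[2]] - ls[, o[1]]) / (b[o[2]] - b[o[1]])
      adc[valid] <- -slope
      s0[valid] <- exp(ls[, o[1]] + slope * b[o[1]])
    } else {
      bc <- b - mean(b)
      slope <- (ls %*% bc) / sum(bc^2)
      adc[valid] <- -slope
      s0[valid] <- exp(rowMeans(ls) + slope * mean(b))
    }
    adc[valid] <- pmax(adc[valid], adc_lower)
  }
  mask <- array(valid, dm)
  structure(list(adc = parameter_map(array(adc, dm), mask, "mm^2/s", "adc"),
                 s0 = parameter_map(array(s0, dm), mask, "a.u.", "s0"),
                 replicate = series$meta$replicate),
            class = "dwi_fit")
}

#' Combine replicate ADC fits into a session mean map
#'
#' Voxelwise mean over the replicates that are valid at each voxel; the
#' output validity mask keeps voxels where at least `min_count` replicates
#' were valid.
#'
#' @param fits list of `dwi_fit` objects on identical grids
#' @param min_count minimum number of valid replicates per voxel (default 1)
#' @return a [parameter_map()] of the mean ADC in mm^2/s
#' @export
combine_replicates <- function(fits, min_count = 1L) {
  assert_that(length(fits) >= 1, "need at least one replicate fit")
  dims <- lapply(fits, function(f) dim(f$adc$values))
  assert_that(all(vapply(dims, identical, TRUE, dims[[1]])),
              "replicate maps are on mismatched grids")
  dm <- dims[[1]]
  acc <- array(0, dm)
  cnt <- array(0L, dm)
  for (f in fits) {
    m <- f$adc$mask
    acc[m] <- acc[m] + f$adc$values[m]
    cnt <- cnt + m
  }
  mask <- cnt >= min_count
  out <- array(NA_real_, dm)
  out[mask] <- acc[mask] / cnt[mask]
  parameter_map(out, mask, "mm^2/s", "adc")
}
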