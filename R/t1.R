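# Variable-flip-angle T1 mapping from spoiled gradient-echo series.

# separable Gaussian smoothing of each volume of a 4D stack (in-plane only;
# slices are thick relative to in-plane resolution)
gauss_smooth_xy <- function(vol4, sigma) {
  if (sigma <= 0) return(vol4)
  r <- max(1L, ceiling(3 * sigma))
  k <- dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  sm1 <- function(x) as.numeric(stats::filter(c(rep(x[1], r), x, rep(x[length(x)], r)),
                                              k, sides = 2)[(r + 1):(r + length(x))])
  d <- dim(vol4)
  for (v in seq_len(d[4])) for (z in seq_len(d[3])) {
    sl <- vol4[, , z, v]
    sl <- apply(sl, 2, sm1)
    sl <- t(apply(sl, 1, sm1))
    vol4[, , z, v] <- sl
  }
  vol4
}

# per-voxel linearized VFA fit: regress S/sin(a) on S/tan(a); slope = E1,
# intercept = M0 (1 - E1). sig: [nvox, nfa]; a: [nvox, nfa] radians.
vfa_linearized <- function(sig, a) {
  y <- sig / sin(a)
  x <- sig / tan(a)
  n <- ncol(sig)
  xm <- rowMeans(x); ym <- rowMeans(y)
  sxx <- rowSums((x - xm)^2)
  sxy <- rowSums((x - xm) * (y - ym))
  e1 <- sxy / sxx
  m0 <- (ym - e1 * xm) / (1 - e1)
  list(e1 = e1, m0 = m0)
}

#' Fit T1 and M0 maps from a variable-flip-angle series
#'
#' Per-voxel fit of the SPGR signal equation
#' `S(a) = M0 sin(a) (1 - E1) / (1 - cos(a) E1)`, `E1 = exp(-TR/T1)`.
#' Initialization uses the standard linearization (S/sin a regressed on
#' S/tan a, whose slope is E1); voxels whose linearized solution leaves a
#' non-negligible residual are refined by bounded nonlinear least squares,
#' and the refined solution is kept only when it does not increase the
#' residual. Out-of-bounds T1 solutions are clipped to `bounds` and flagged.
#'
#' Spatial regularization is available only as optional Gaussian
#' pre-smoothing of the flip-angle images (`smooth_sigma`, voxels, default
#' off) — a deliberate simplification of full regularized estimation, which
#' homogeneous phantoms do not need. A per-voxel flip-angle scale map
#' (`fa_scale`) can be supplied when an external B1 correction is available.
#'
#' @param series an [image_series()] of kind `"vfa"`
#' @param scales optional per-image intensity scale factors (from
#'   [estimate_intensity_scales()]); data are divided by them before fitting
#' @param smooth_sigma Gaussian pre-smoothing s.d. in voxels (0 = off)
#' @param bounds admissible T1 range in seconds (default `c(0.05, 10)`,
#'   physiological at 1.5 T plus numerical safety)
#' @param fa_scale optional 3D array multiplying the nominal flip angles
#' @param refine refine voxels by bounded nonlinear least squares when the
#'   linearized residual is non-negligible (default TRUE)
#' @param series_id identifier used in error messages
#' @return object of class `t1_fit`: `t1`, `m0` ([parameter_map()]s),
#'   `clipped` (logical array), `scales`, `smooth_sigma`
#' @export
fit_t1_vfa <- function(series, scales = NULL, smooth_sigma = 0,
                       bounds = c(0.05, 10), fa_scale = NULL, refine = TRUE,
                       series_id = "VFA series") {
  stopifnot(inherits(series, "image_series"))
  fa <- series$meta$flip_angles_deg
  tr_ms <- series$meta$tr_ms
  if (length(unique(fa)) < 2)
    stop_qmri(series_id, ": T1 map cannot be obtained, images were acquired ",
              "using one flip angle only")
  dat <- series$data
  if (!is.null(scales)) {
    assert_that(length(scales) == dim(dat)[4] && all(scales > 0),
                "scales must be positive, one per image")
    for (i in seq_along(scales)) dat[, , , i] <- dat[, , , i] / scales[i]
  }
  if (smooth_sigma > 0) dat <- gauss_smooth_xy(dat, smooth_sigma)
  dm <- dim(dat)[1:3]
  nfa <- length(fa)
  sig <- matrix(dat, prod(dm), nfa)
  a <- matrix(deg2rad(fa), prod(dm), nfa, byrow = TRUE)
  if (!is.null(fa_scale)) a <- a * as.vector(fa_scale)
  valid <- rowSums(sig > 0) == nfa
  t1 <- rep(NA_real_, nrow(sig))
  m0 <- rep(NA_real_, nrow(sig))
  clipped <- rep(FALSE, nrow(sig))
  if (any(valid)) {
    sv <- sig[valid, , drop = FALSE]
    av <- a[valid, , drop = FALSE]
    lin <- vfa_linearized(sv, av)
    e1 <- lin$e1
    m0v <- lin$m0
    nv <- length(e1)
    t1v <- rep(NA_real_, nv)
    in_range <- is.finite(e1) & e1 > 0 & e1 < 1 & is.finite(m0v) & m0v > 0
    t1v[in_range] <- -(tr_ms / 1000) / log(e1[in_range])
    # apparent E1 outside (0,1): the noise tails of the linearized slope.
    # Dropping them would bias VOI medians low, so clip to the T1 bounds
    # and flag, re-estimating M0 by linear LS at the clipped T1.
    cl <- !in_range
    t1v[cl & is.finite(e1) & e1 >= 1] <- bounds[2]
    t1v[cl & (!is.finite(e1) | e1 <= 0)] <- bounds[1]
    lo <- in_range & t1v < bounds[1]; hi <- in_range & t1v > bounds[2]
    t1v[lo] <- bounds[1]; t1v[hi] <- bounds[2]
    cl <- cl | lo | hi
    if (any(cl)) {
      e1c <- exp(-(tr_ms / 1000) / t1v[cl])
      f <- sin(av[cl, , drop = FALSE]) * (1 - e1c) /
        (1 - cos(av[cl, , drop = FALSE]) * e1c)
      m0v[cl] <- pmax(rowSums(sv[cl, , drop = FALSE] * f) / rowSums(f^2),
                      .Machine$double.eps)
    }
    if (refine) {
      ref <- vfa_refine(sv, av, tr_ms, t1v, m0v, bounds)
      t1v <- ref$t1
      m0v <- ref$m0
    }
    vi <- which(valid)
    bad <- !is.finite(t1v) | !is.finite(m0v) | m0v <= 0
    valid[vi[bad]] <- FALSE
    t1[vi] <- t1v
    m0[vi] <- m0v
    clipped[vi] <- cl & !bad
  }
  mask <- array(valid & is.finite(t1), dm)
  structure(list(t1 = parameter_map(array(t1, dm), mask, "s", "t1"),
                 m0 = parameter_map(array(m0, dm), mask, "a.u.", "m0"),
                 clipped = array(clipped, dm),
                 scales = scales %||% rep(1, nfa),
                 smooth_sigma = smooth_sigma),
            class = "t1_fit")
}

# bounded per-voxel refinement; keeps the better of (initial, refined)
vfa_refine <- function(sig, a, tr_ms, t1_init, m0_init, bounds,
                       rel_tol = 1e-6) {
  tr_s <- tr_ms / 1000
  resid_of <- function(t1, m0, i) {
    pred <- m0 * sin(a[i, ]) * (1 - exp(-tr_s / t1)) /
      (1 - cos(a[i, ]) * exp(-tr_s / t1))
    sum((sig[i, ] - pred)^2)
  }
  t1 <- t1_init; m0 <- m0_init
  scale2 <- rowSums(sig^2)
  for (i in seq_len(nrow(sig))) {
    r0 <- resid_of(t1[i], m0[i], i)
    if (!is.finite(r0) || r0 <= rel_tol * scale2[i]) next
    fn <- function(p) {
      r <- resid_of(exp(p[1]), exp(p[2]), i)
      if (is.finite(r)) r else 1e300
    }
    opt <- try(stats::optim(c(log(t1[i]), log(m0[i])), fn, method = "L-BFGS-B",
                            lower = c(log(bounds[1]), log(m0[i]) - 5),
                            upper = c(log(bounds[2]), log(m0[i]) + 5)),
               silent = TRUE)
    if (!inherits(opt, "try-error") && opt$value <= r0) {
      t1[i] <- exp(opt$par[1]); m0[i] <- exp(opt$par[2])
    }
  }
  list(t1 = t1, m0 = m0)
}

#' Estimate inter-image intensity scale factors of a VFA series
#'
#' When the images of a multi-flip-angle series were exported with
#' different intensity scalings, no single (T1, M0) pair per voxel fits the
#' series. In the linearized SPGR coordinates (`S/sin a` against `S/tan a`)
#' the images of a correctly scaled voxel are collinear, and per-image
#' scaling moves each point radially, breaking collinearity (a factor
#' common to all images preserves it, which is why the first image is
#' fixed at 1). The factors are estimated by minimizing the summed
#' normalized per-voxel linearized-fit residual over the reference region;
#' with more than two flip angles and a spread of reference T1 values the
#' minimum is the planted scaling. Dividing the series by the returned
#' factors makes it consistent with a single M0.
#'
#' @param series an [image_series()] of kind `"vfa"` with >= 2 images
#' @param reference_mask logical 3D array of reference voxels (nonempty)
#' @param n_iter maximum optimizer iterations
#' @return numeric vector of per-image scale factors, first element 1
#' @export
estimate_intensity_scales <- function(series, reference_mask, n_iter = 200) {
  stopifnot(inherits(series, "image_series"))
  nimg <- dim(series$data)[4]
  assert_that(nimg >= 2, "need at least two images")
  assert_that(any(reference_mask), "reference mask is empty")
  fa <- series$meta$flip_angles_deg
  idx <- which(reference_mask)
  sig <- matrix(series$data, ncol = nimg)[idx, , drop = FALSE]
  keep <- rowSums(sig > 0) == nimg
  assert_that(any(keep), "reference mask has no voxels with positive signal")
  sig <- sig[keep, , drop = FALSE]
  a <- matrix(deg2rad(fa), nrow(sig), nimg, byrow = TRUE)
  obj <- function(ls) {
    scales <- c(1, exp(ls))
    cur <- sweep(sig, 2, scales, `/`)
    y <- cur / sin(a)
    x <- cur / tan(a)
    xm <- rowMeans(x); ym <- rowMeans(y)
    sxx <- rowSums((x - xm)^2)
    sxy <- rowSums((x - xm) * (y - ym))
    syy <- rowSums((y - ym)^2)
    sse <- pmax(syy - sxy^2 / pmax(sxx, 1e-300), 0)
    sum(sse / pmax(rowSums(y^2), 1e-300))
  }
  opt <- stats::optim(rep(0, nimg - 1L), obj, method = "BFGS",
                      control = list(maxit = n_iter, reltol = 1e-14))
  # simplex polish: BFGS stalls on the nearly flat valley near the optimum
  opt <- stats::optim(opt$par, obj, method = "Nelder-Mead",
                      control = list(maxit = 10 * n_iter, reltol = 1e-15))
  c(1, exp(opt$par))
}

#' Reference T1 values by tissue label
#'
#' A fallback piecewise-constant T1 assignment for series where a T1 fit is
#' unavailable. The shipped default values are implementation defaults at
#' 1.5 T (soft tissue 0.6 s, blood 1.4 s), not measured values.
#'
#' @param labels integer labels present in label maps
#' @param t1_s T1 values in seconds, one per label
#' @param field_t field strength in tesla (recorded)
#' @return a `reference_t1_table` data.frame
#' @export
reference_t1_table <- function(labels = c(1L, 2L), t1_s = c(0.6, 1.4),
                               field_t = 1.5) {
  assert_that(length(labels) == length(t1_s), "labels and t1_s differ in length")
  assert_that(all(t1_s > 0), "reference T1 values must be positive")
  structure(data.frame(label = as.integer(labels), t1_s = t1_s),
            field_t = field_t, class = c("reference_t1_table", "data.frame"))
}

#' Assign literature T1 values by tissue label
#'
#' @param label_map integer 3D array (0 = background, ignored)
#' @param table a [reference_t1_table()]
#' @param overrides optional named numeric vector (names = label ids) that
#'   shadows table entries
#' @return a [parameter_map()] of T1 in seconds, valid on labeled voxels
#' @export
assign_reference_t1 <- function(label_map, table, overrides = NULL) {
  stopifnot(inherits(table, "reference_t1_table"))
  lut <- stats::setNames(table$t1_s, as.character(table$label))
  if (!is.null(overrides)) lut[names(overrides)] <- overrides
  present <- setdiff(unique(as.vector(label_map)), 0L)
  missing <- setdiff(as.character(present), names(lut))
  if (length(missing))
    stop_qmri("no reference T1 for label(s): ", paste(missing, collapse = ", "))
  out <- array(NA_real_, dim(label_map))
  for (lb in present) out[label_map == lb] <- lut[[as.character(lb)]]
  parameter_map(out, label_map != 0L, "s", "t1")
}
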