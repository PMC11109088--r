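# Dynamic contrast-enhanced MRI: concentration conversion, AIF extraction,
# iAUC, and extended Tofts pharmacokinetic fitting.
#
# Unit conventions: time grids in seconds, k-trans and kep in min^-1 (the
# field's unit), with explicit conversion at the convolution boundary.

# exact exponential-kernel convolution for piecewise-linear Cp:
# y(t) = int_0^t Cp(tau) exp(-k (t - tau)) dtau, k in s^-1, scalar k.
exp_conv <- function(cp, times, k_s) {
  n <- length(times)
  y <- numeric(n)
  for (i in seq_len(n - 1)) {
    dt <- times[i + 1] - times[i]
    if (k_s * dt < 1e-10) {
      y[i + 1] <- y[i] + (cp[i] + cp[i + 1]) * dt / 2
    } else {
      e <- exp(-k_s * dt)
      slope <- (cp[i + 1] - cp[i]) / dt
      y[i + 1] <- y[i] * e + cp[i] * (1 - e) / k_s +
        slope * (dt / k_s - (1 - e) / k_s^2)
    }
  }
  y
}

# vectorized over voxels: ktrans/ve/vp vectors, cp/times shared.
# Returns [nvox, ntime] tissue concentration. ve may be 0 only where
# ktrans is 0.
tofts_forward_matrix <- function(ktrans, ve, vp, cp, times) {
  nvox <- length(ktrans)
  nt <- length(times)
  bad <- ktrans > 0 & ve <= 0
  if (any(bad)) stop_qmri("ve = 0 with ktrans > 0: transfer rate undefined")
  k_s <- ifelse(ktrans > 0, (ktrans / ve) / 60, 0)
  y <- matrix(0, nvox, nt)
  for (i in seq_len(nt - 1)) {
    dt <- times[i + 1] - times[i]
    e <- exp(-k_s * dt)
    slope <- (cp[i + 1] - cp[i]) / dt
    small <- k_s * dt < 1e-10
    term <- numeric(nvox)
    term[small] <- (cp[i] + cp[i + 1]) * dt / 2
    if (any(!small)) {
      kk <- k_s[!small]
      term[!small] <- cp[i] * (1 - e[!small]) / kk +
        slope * (dt / kk - (1 - e[!small]) / kk^2)
    }
    y[, i + 1] <- y[, i] * e + term
  }
  outer(vp, cp) + (ktrans / 60) * y
}

#' Extended Tofts forward model
#'
#' Tissue concentration
#' `Ct(t) = vp Cp(t) + ktrans int_0^t Cp(tau) exp(-(ktrans/ve)(t - tau)) dtau`
#' evaluated by an exponential-kernel recursion that is exact for a
#' piecewise-linear plasma curve. `ktrans` is in min^-1, the time grid in
#' seconds; the unit conversion is internal.
#'
#' @param params numeric vector `c(ktrans, ve, vp)` (min^-1, fraction, fraction)
#' @param aif an [aif()] object (or a numeric vector of Cp on `times_s`)
#' @param times_s output time grid in seconds (default: the AIF grid)
#' @return tissue concentration in mM on `times_s`
#' @export
tofts_forward <- function(params, aif, times_s = NULL) {
  ktrans <- params[[1]]; ve <- params[[2]]; vp <- params[[3]]
  assert_that(ktrans >= 0 && ve >= 0 && ve <= 1 && vp >= 0 && vp <= 1,
              "parameters out of bounds: ktrans >= 0, ve and vp in [0, 1]")
  if (ktrans > 0 && ve == 0)
    stop_qmri("ve = 0 with ktrans > 0: transfer rate undefined")
  if (inherits(aif, "aif")) {
    times_s <- times_s %||% aif$time_s
    cp <- stats::approx(aif$time_s, aif$cp_mM, xout = times_s)$y
  } else {
    assert_that(!is.null(times_s), "give times_s when aif is a plain vector")
    cp <- aif
  }
  drop(tofts_forward_matrix(ktrans, ve, vp, cp, times_s))
}

#' Detect the injection frame of a dynamic series
#'
#' Finds the first post-bolus frame as the first frame whose mean signal
#' (over `mask`, or over all nonzero voxels) exceeds the pre-injection level
#' by a margin: `baseline mean + max(5 sd, 5% of baseline mean)`, baseline
#' statistics taken from the first `min_baseline` frames. An `override`
#' short-circuits detection.
#'
#' @param series an [image_series()] of kind `"dce"` with >= 3 frames
#' @param mask optional logical array restricting the detection curve
#' @param override known injection frame index (returned as-is)
#' @param min_baseline frames assumed pre-injection for the noise estimate
#' @return list with `injection_frame` and `baseline_frames`
#' @export
detect_injection <- function(series, mask = NULL, override = NULL,
                             min_baseline = 3L) {
  stopifnot(inherits(series, "image_series"))
  nf <- dim(series$data)[4]
  assert_that(nf >= 3, "need at least 3 frames")
  if (!is.null(override)) {
    assert_that(override >= 2 && override <= nf, "override out of range")
    return(list(injection_frame = as.integer(override),
                baseline_frames = seq_len(override - 1L)))
  }
  dat <- matrix(series$data, ncol = nf)
  if (is.null(mask)) {
    keep <- rowSums(dat) > 0
  } else {
    keep <- as.vector(mask)
  }
  assert_that(any(keep), "no voxels available for injection detection")
  curve <- colMeans(dat[keep, , drop = FALSE])
  bm <- mean(curve[seq_len(min_baseline)])
  bs <- stats::sd(curve[seq_len(min_baseline)])
  thr <- bm + max(5 * bs, 0.05 * abs(bm))
  hit <- which(curve > thr)
  hit <- hit[hit > min_baseline]
  if (!length(hit))
    stop_qmri("no detectable enhancement; supply an injection-frame override")
  list(injection_frame = hit[1],
       baseline_frames = seq_len(hit[1] - 1L))
}

#' Convert a dynamic signal series to gadolinium concentration
#'
#' Inverts the SPGR signal equation frame by frame: M0 is normalized per
#' voxel from the mean pre-injection signal and the pre-contrast T1, each
#' frame's signal gives T1(t), and
#' `C(t) = (1/T1(t) - 1/T1(0)) / r1`. Negative concentrations (noise below
#' baseline) are clipped to zero and counted; frames before the injection
#' carry C = 0 by construction.
#'
#' @param series an [image_series()] of kind `"dce"`
#' @param t1_pre pre-contrast T1 [parameter_map()] in seconds
#' @param relaxivity r1 in mM^-1 s^-1 (default: series metadata)
#' @param injection_frame first post-bolus frame (default: series metadata)
#' @param baseline_frames frames used for M0 normalization (default: all
#'   frames before the injection)
#' @param mask optional logical array of voxels to convert (default: the
#'   valid voxels of `t1_pre`)
#' @return object of class `concentration_series`: `conc` (4D array, mM),
#'   `mask`, `time_s`, `injection_frame`, `relaxivity`, `n_clipped`
#' @export
signal_to_concentration <- function(series, t1_pre, relaxivity = NULL,
                                    injection_frame = NULL,
                                    baseline_frames = NULL, mask = NULL) {
  stopifnot(inherits(series, "image_series"), inherits(t1_pre, "parameter_map"))
  r1 <- relaxivity %||% series$meta$relaxivity
  assert_that(!is.null(r1) && r1 > 0, "relaxivity must be positive")
  fa <- series$meta$flip_angles_deg
  assert_that(fa > 0 && fa <= 90, "dynamic flip angle must be in (0, 90] degrees")
  tr_s <- series$meta$tr_ms / 1000
  inj <- injection_frame %||% series$meta$injection_frame
  assert_that(!is.null(inj), "injection frame unknown: detect or supply it")
  baseline_frames <- baseline_frames %||% seq_len(inj - 1L)
  assert_that(length(baseline_frames) >= 1, "baseline frames must be nonempty")
  dm <- dim(series$data)[1:3]
  nf <- dim(series$data)[4]
  mask <- mask %||% t1_pre$mask
  idx <- which(mask & t1_pre$mask & is.finite(t1_pre$values))
  assert_that(length(idx) > 0, "no valid voxels to convert")
  sig <- matrix(series$data, ncol = nf)[idx, , drop = FALSE]
  t1_0 <- t1_pre$values[idx]
  s_pre <- rowMeans(sig[, baseline_frames, drop = FALSE])
  f_pre <- spgr_signal(1, t1_0, fa, tr_s * 1000)
  m0 <- s_pre / f_pre
  ok <- is.finite(m0) & m0 > 0
  conc <- matrix(NA_real_, length(idx), nf)
  n_clipped <- 0L
  for (f in seq_len(nf)) {
    e1 <- spgr_invert_e1(sig[, f], m0, fa)
    good <- ok & is.finite(e1) & e1 > 0 & e1 < 1
    t1t <- rep(NA_real_, length(idx))
    t1t[good] <- -tr_s / log(e1[good])
    cf <- (1 / t1t - 1 / t1_0) / r1
    neg <- !is.na(cf) & cf < 0
    n_clipped <- n_clipped + sum(neg & f >= inj)
    cf[neg] <- 0
    conc[, f] <- cf
  }
  conc[, seq_len(inj - 1L)] <- 0
  out <- array(NA_real_, c(dm, nf))
  flat <- matrix(out, ncol = nf)
  flat[idx, ] <- conc
  out <- array(flat, c(dm, nf))
  cmask <- array(FALSE, dm)
  cmask[idx] <- ok
  structure(list(conc = out, mask = cmask,
                 time_s = series$meta$frame_times_s,
                 injection_frame = inj, relaxivity = r1,
                 n_clipped = n_clipped),
            class = "concentration_series")
}

#' Build a concentration series directly from curves
#'
#' Convenience constructor used in tests and for analytic inputs.
#' @param conc matrix `[nvox, nframes]` or 4D array of concentration (mM)
#' @param time_s frame times, s
#' @param injection_frame first post-bolus frame index
#' @param relaxivity r1, mM^-1 s^-1
#' @return a `concentration_series`
#' @export
concentration_series <- function(conc, time_s, injection_frame = 1L,
                                 relaxivity = 4.5) {
  if (is.matrix(conc)) {
    conc <- array(conc, c(nrow(conc), 1L, 1L, ncol(conc)))
  } else if (is.null(dim(conc))) {
    conc <- array(conc, c(1L, 1L, 1L, length(conc)))
  }
  assert_that(dim(conc)[4] == length(time_s), "frames and time grid differ")
  assert_that(all(diff(time_s) > 0), "time grid must be strictly increasing")
  structure(list(conc = conc, mask = array(TRUE, dim(conc)[1:3]),
                 time_s = time_s, injection_frame = as.integer(injection_frame),
                 relaxivity = relaxivity, n_clipped = 0L),
            class = "concentration_series")
}

# internal: masked curves of a concentration series as [nvox, nframes]
conc_curves <- function(conc, mask = NULL) {
  nf <- dim(conc$conc)[4]
  m <- conc$mask
  if (!is.null(mask)) m <- m & mask
  idx <- which(m)
  list(curves = matrix(conc$conc, ncol = nf)[idx, , drop = FALSE], idx = idx)
}

#' Extract an arterial input function from arterial voxels
#'
#' The AIF is the pointwise mean of the selected voxel curves. Selection
#' default is the top-k voxels by peak concentration (partial-volume voxels
#' have damped peaks); `k = Inf` averages all artery voxels. Optionally
#' converts whole-blood to plasma concentration with a hematocrit factor
#' `1 / (1 - hct)`.
#'
#' @param conc a `concentration_series`
#' @param artery_mask logical 3D array (nonempty)
#' @param k number of top-peak voxels to average (default 10)
#' @param hematocrit optional hematocrit for blood-to-plasma conversion
#'   (default NULL: curves are used as-is)
#' @return an [aif()] with source `"measured"`
#' @export
extract_aif <- function(conc, artery_mask, k = 10, hematocrit = NULL) {
  stopifnot(inherits(conc, "concentration_series"))
  assert_that(any(artery_mask), "artery mask is empty")
  cc <- conc_curves(conc, artery_mask)
  assert_that(nrow(cc$curves) > 0, "no valid artery voxels in the series")
  peaks <- apply(cc$curves, 1, max)
  k <- min(k, length(peaks))
  sel <- order(peaks, decreasing = TRUE)[seq_len(k)]
  cp <- colMeans(cc$curves[sel, , drop = FALSE])
  if (!is.null(hematocrit)) cp <- cp / (1 - hematocrit)
  aif(conc$time_s, pmax(cp, 0), source = "measured", hematocrit = hematocrit)
}

# trapezoidal integral of each curve over [t_start, t_start + window_s],
# linear interpolation at the window edge. ct: [nvox, ntime].
iauc_from_curves <- function(ct, times, t_start, window_s) {
  t_end <- t_start + window_s
  assert_that(t_end <= max(times) + 1e-9,
              "iAUC window exceeds the acquisition (ends at ",
              max(times), " s)")
  interp_col <- function(tq) {
    i <- findInterval(tq, times)
    if (i >= length(times)) return(ct[, length(times)])
    w <- (tq - times[i]) / (times[i + 1] - times[i])
    ct[, i] * (1 - w) + ct[, i + 1] * w
  }
  inside <- which(times > t_start & times < t_end)
  grid <- c(t_start, times[inside], t_end)
  vals <- cbind(interp_col(t_start),
                ct[, inside, drop = FALSE],
                interp_col(t_end))
  dt <- diff(grid)
  as.numeric(((vals[, -ncol(vals), drop = FALSE] +
               vals[, -1, drop = FALSE]) / 2) %*% dt)
}

#' Initial area under the concentration curve (iAUC)
#'
#' Trapezoidal integral of C(t) over a window starting at the injection
#' time, with linear interpolation to the window edge. The window is
#' anchored at the injection frame, not at a per-voxel bolus arrival.
#'
#' @param conc a `concentration_series`
#' @param window_s integration window in seconds (default 90)
#' @param mask optional logical array restricting the computation
#' @return a [parameter_map()] in mM·s
#' @export
compute_iauc <- function(conc, window_s = 90, mask = NULL) {
  stopifnot(inherits(conc, "concentration_series"))
  t0 <- conc$time_s[conc$injection_frame]
  cc <- conc_curves(conc, mask)
  v <- iauc_from_curves(cc$curves, conc$time_s, t0, window_s)
  dm <- dim(conc$conc)[1:3]
  out <- array(NA_real_, dm)
  out[cc$idx] <- v
  m <- array(FALSE, dm)
  m[cc$idx] <- TRUE
  parameter_map(out, m, "mM.s", "iauc")
}

#' Fit the extended Tofts model to concentration curves
#'
#' Bounded least squares against [tofts_forward()] by variable projection:
#' for each candidate rate constant `kep = ktrans/ve` the model is linear in
#' `(ktrans, vp)` and solved in closed form; a coarse logarithmic kep grid is
#' scanned (the multi-start stage) and the per-voxel optimum is refined by a
#' bracketed 1-D minimization of the projected residual. The returned
#' solution therefore never has a larger residual than any scanned
#' initialization. Negative amplitudes are clamped to the boundary and
#' re-solved. Curves with (numerically) zero signal are flagged degenerate
#' with `ktrans = 0`, `vp = 0`.
#'
#' @param curves numeric matrix `[nvox, ntime]`, vector, or a
#'   `concentration_series`
#' @param aif an [aif()] on the same time grid (interpolated if needed)
#' @param times_s time grid, s (default from `curves`/`aif`)
#' @param mask optional mask when `curves` is a `concentration_series`
#' @param kep_grid `c(min, max, n)` for the coarse kep scan, min^-1
#' @param vp_max upper bound for vp (default 1)
#' @return object of class `pk_fit`: vectors `ktrans` (min^-1), `ve`, `vp`,
#'   `residual` (sum of squares), `converged`, `degenerate`; plus `idx` and
#'   `dim` when a `concentration_series` was supplied
#' @export
fit_extended_tofts <- function(curves, aif, times_s = NULL, mask = NULL,
                               kep_grid = c(0.01, 20, 40), vp_max = 1) {
  stopifnot(inherits(aif, "aif"))
  idx <- NULL; dm <- NULL
  if (inherits(curves, "concentration_series")) {
    times_s <- times_s %||% curves$time_s
    dm <- dim(curves$conc)[1:3]
    cc <- conc_curves(curves, mask)
    idx <- cc$idx
    curves <- cc$curves
  } else if (is.null(dim(curves))) {
    curves <- matrix(curves, nrow = 1)
  }
  times_s <- times_s %||% aif$time_s
  assert_that(ncol(curves) == length(times_s), "curves and time grid differ")
  cp <- stats::approx(aif$time_s, aif$cp_mM, xout = times_s)$y
  assert_that(!anyNA(cp), "AIF does not cover the time grid")
  nvox <- nrow(curves)
  nt <- length(times_s)
  cc_ss <- rowSums(curves^2)
  scale2 <- max(cc_ss)
  degenerate <- cc_ss <= 1e-12 * max(scale2, 1e-300)
  gcc <- sum(cp^2)
  b2_all <- as.numeric(curves %*% cp)

  # closed-form (ktrans, vp) at fixed basis g, with nonnegativity clamps
  solve_amp <- function(g, rows) {
    ggg <- sum(g^2); ggc <- sum(g * cp)
    b1 <- as.numeric(curves[rows, , drop = FALSE] %*% g)
    b2 <- b2_all[rows]
    det <- ggg * gcc - ggc^2
    if (det <= 1e-300) {
      th1 <- rep(0, length(rows))
      th2 <- pmin(pmax(b2 / gcc, 0), vp_max)
    } else {
      th1 <- (gcc * b1 - ggc * b2) / det
      th2 <- (ggg * b2 - ggc * b1) / det
      neg1 <- th1 < 0
      th1[neg1] <- 0
      th2[neg1] <- pmin(pmax(b2[neg1] / gcc, 0), vp_max)
      neg2 <- !neg1 & (th2 < 0)
      th2[neg2] <- 0
      th1[neg2] <- pmax(b1[neg2] / ggg, 0)
      hi <- th2 > vp_max
      if (any(hi)) {
        th2[hi] <- vp_max
        th1[hi] <- pmax((b1[hi] - vp_max * ggc) / ggg, 0)
      }
    }
    resid <- cc_ss[rows] - 2 * th1 * b1 - 2 * th2 * b2 +
      th1^2 * ggg + th2^2 * gcc + 2 * th1 * th2 * ggc
    list(ktrans = th1, vp = th2, resid = pmax(resid, 0))
  }
  basis <- function(kep) exp_conv(cp, times_s, kep / 60) / 60

  keps <- exp(seq(log(kep_grid[1]), log(kep_grid[2]), length.out = kep_grid[3]))
  live <- which(!degenerate)
  best_r <- rep(Inf, nvox); best_k <- rep(keps[1], nvox)
  best_t1 <- numeric(nvox); best_t2 <- numeric(nvox)
  if (length(live)) {
    for (kep in keps) {
      s <- solve_amp(basis(kep), live)
      upd <- s$resid < best_r[live]
      rows <- live[upd]
      best_r[rows] <- s$resid[upd]; best_k[rows] <- kep
      best_t1[rows] <- s$ktrans[upd]; best_t2[rows] <- s$vp[upd]
    }
    # per-voxel refinement within one coarse grid step of the best kep
    step <- keps[2] / keps[1]
    for (i in live) {
      f <- function(lk) solve_amp(basis(exp(lk)), i)$resid
      o <- stats::optimize(f, interval = log(best_k[i]) + c(-1, 1) * log(step),
                           tol = 1e-4)
      if (o$objective <= best_r[i]) {
        kref <- exp(o$minimum)
        s <- solve_amp(basis(kref), i)
        best_r[i] <- s$resid; best_k[i] <- kref
        best_t1[i] <- s$ktrans; best_t2[i] <- s$vp
      }
    }
  }
  ktrans <- best_t1
  vp <- best_t2
  ve <- ifelse(ktrans > 0, pmin(ktrans / best_k, 1), NA_real_)
  ktrans[degenerate] <- 0
  vp[degenerate] <- 0
  ve[degenerate] <- NA_real_
  best_r[degenerate] <- 0
  structure(list(ktrans = ktrans, ve = ve, vp = vp, residual = best_r,
                 converged = rep(TRUE, nvox), degenerate = degenerate,
                 idx = idx, dim = dm),
            class = "pk_fit")
}

#' Extended Tofts parameter maps from a concentration series
#'
#' Convenience wrapper around [fit_extended_tofts()] that returns spatial
#' [parameter_map()]s restricted to a mask.
#'
#' @param conc a `concentration_series`
#' @param aif an [aif()]
#' @param mask logical array of voxels to fit (default: the series mask)
#' @param ... passed to [fit_extended_tofts()]
#' @return list of parameter maps `ktrans` (min^-1), `ve`, `vp` and the
#'   underlying `pk_fit`
#' @export
fit_pk_maps <- function(conc, aif, mask = NULL, ...) {
  fit <- fit_extended_tofts(conc, aif, mask = mask, ...)
  dm <- fit$dim
  mk <- function(v, units, name, extra_ok = TRUE) {
    out <- array(NA_real_, dm)
    out[fit$idx] <- v
    m <- array(FALSE, dm)
    m[fit$idx] <- !fit$degenerate & is.finite(v)
    parameter_map(out, m, units, name)
  }
  list(ktrans = mk(fit$ktrans, "1/min", "ktrans"),
       ve = mk(fit$ve, "", "ve"),
       vp = mk(fit$vp, "", "vp"),
       fit = fit)
}
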