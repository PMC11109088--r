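#' Digital phantom cohort configuration
#'
#' Defines the geometry and ground-truth parameter ranges of a simulated
#' multi-visit, multi-patient cohort. Each patient volume contains a soft
#' tissue "body", a tubular artery, and one or more ellipsoidal tumors whose
#' quantitative parameters are drawn from the configured ranges with mild
#' voxel-level heterogeneity. Defaults emulate metastatic solid tumors imaged
#' at 1.5 T.
#'
#' @param n_patients number of patients
#' @param tumors_per_patient tumors per patient (recycled or scalar)
#' @param dim grid dimensions, length 3 (default `c(64, 64, 8)`)
#' @param spacing_mm voxel spacing in mm
#' @param visits character vector of visit names; first is baseline
#' @param tumor_radius_vox range of tumor semi-axis lengths in voxels
#' @param adc_range tumor ADC range, mm^2/s
#' @param t1_range tumor T1 range, s
#' @param ktrans_range tumor k-trans range, min^-1
#' @param ve_range tumor extravascular-extracellular fraction range
#' @param vp_range tumor plasma fraction range
#' @param heterogeneity relative s.d. of voxel-level variation about the
#'   tumor mean (0 disables)
#' @param m0 equilibrium signal (arbitrary units, also the SNR reference)
#' @param normal named list of normal-tissue parameter values
#' @param artery named list of arterial values (`vp = 1`, `ve = 0` enforced)
#' @return object of class `phantom_config`
#' @export
phantom_config <- function(n_patients = 6, tumors_per_patient = 1,
                           dim = c(64, 64, 8), spacing_mm = c(1.5, 1.5, 8),
                           visits = c("baseline", "day1"),
                           tumor_radius_vox = c(5, 9),
                           adc_range = c(0.9e-3, 2.0e-3),
                           t1_range = c(1.0, 1.8),
                           ktrans_range = c(0.05, 0.25),
                           ve_range = c(0.15, 0.55),
                           vp_range = c(0.01, 0.06),
                           heterogeneity = 0.08,
                           m0 = 1000,
                           normal = list(adc = 1.1e-3, t1 = 0.6,
                                         ktrans = 0.02, ve = 0.2, vp = 0.02),
                           artery = list(adc = 3.0e-3, t1 = 1.4)) {
  assert_that(n_patients >= 1, "need at least one patient")
  assert_that(length(dim) == 3 && all(dim >= 4), "grid must be 3D, >= 4 voxels per axis")
  assert_that(length(visits) >= 1, "need at least one visit")
  for (rg in list(adc_range, t1_range, ktrans_range, ve_range, vp_range))
    assert_that(length(rg) == 2 && rg[1] <= rg[2] && rg[1] >= 0,
                "parameter ranges must be non-negative and ordered")
  assert_that(max(ve_range) + max(vp_range) <= 1,
              "ve and vp ranges are inconsistent: ve + vp may exceed 1")
  assert_that(all(t1_range > 0), "T1 must be positive")
  tumors_per_patient <- rep_len(tumors_per_patient, n_patients)
  assert_that(all(tumors_per_patient >= 1), "need at least one tumor per patient")
  structure(list(n_patients = n_patients,
                 tumors_per_patient = tumors_per_patient,
                 dim = as.integer(dim), spacing_mm = spacing_mm,
                 visits = visits, tumor_radius_vox = tumor_radius_vox,
                 adc_range = adc_range, t1_range = t1_range,
                 ktrans_range = ktrans_range, ve_range = ve_range,
                 vp_range = vp_range, heterogeneity = heterogeneity,
                 m0 = m0, normal = normal, artery = artery),
            class = "phantom_config")
}

# label conventions for phantom scenes
LABEL_BACKGROUND <- 0L
LABEL_NORMAL <- 1L
LABEL_ARTERY <- 2L
LABEL_TUMOR_BASE <- 10L # tumor i has label 10 + i

#' Tumor label id
#' @param tumor_id integer tumor index within patient
#' @return the integer label used in phantom label maps
#' @export
tumor_label <- function(tumor_id) LABEL_TUMOR_BASE + as.integer(tumor_id)

#' Treatment effect model
#'
#' Maps ground-truth parameters to their programmed day-1 change in responder
#' tumors, with a recovery schedule for later visits. The default effects
#' encode the pharmacodynamic signature of stromal hyaluronic-acid depletion:
#' ADC and T1 decrease while k-trans, ve and vp increase on day 1, and
#' parameters drift back toward baseline at subsequent visits. Default
#' magnitudes are twice the corresponding repeatability bands used for
#' response classification, i.e. changes a repeatability analysis should call
#' significant.
#'
#' @param effects named list; each element is `list(mode, value)` with mode
#'   `"additive"` (value in parameter units) or `"multiplicative"`
#'   (value = factor). Omit a parameter (or use value 0 / factor 1) for no
#'   effect.
#' @param responder_rule `list(mode = "fraction", fraction = 0.5)` assigns a
#'   fixed fraction of tumors as responders at random;
#'   `list(mode = "threshold", parameter =, op = ">" or "<", cut =)` makes a
#'   tumor a responder exactly when its baseline tumor-mean parameter
#'   satisfies the inequality; `list(mode = "all")` / `list(mode = "none")`.
#' @param recovery fraction of the day-1 effect remaining at each later
#'   visit (geometrically: visit k past day 1 keeps `recovery^k`)
#' @return object of class `treatment_effect_model`
#' @export
treatment_effect_model <- function(effects = list(
                                     adc = list(mode = "additive", value = -0.30e-3),
                                     t1 = list(mode = "additive", value = -0.54),
                                     ktrans = list(mode = "multiplicative", value = 2.66),
                                     ve = list(mode = "additive", value = 0.152),
                                     vp = list(mode = "additive", value = 0.0124)),
                                   responder_rule = list(mode = "fraction", fraction = 0.5),
                                   recovery = 0.3) {
  known <- c("adc", "t1", "ktrans", "ve", "vp")
  assert_that(all(names(effects) %in% known),
              "effects must be named among: ", paste(known, collapse = ", "))
  for (e in effects)
    assert_that(is.list(e) && e$mode %in% c("additive", "multiplicative"),
                "each effect is list(mode = additive|multiplicative, value = )")
  assert_that(responder_rule$mode %in% c("fraction", "threshold", "all", "none"),
              "unknown responder rule mode")
  structure(list(effects = effects, responder_rule = responder_rule,
                 recovery = recovery), class = "treatment_effect_model")
}

#' A treatment effect model with no effects (all visits identical to baseline)
#' @return a [treatment_effect_model()] whose effects are empty
#' @export
null_effect_model <- function() {
  treatment_effect_model(effects = list(),
                         responder_rule = list(mode = "none"))
}

# ellipsoid mask on an integer grid
ellipsoid_mask <- function(dim, center, radii) {
  x <- (seq_len(dim[1]) - center[1]) / radii[1]
  y <- (seq_len(dim[2]) - center[2]) / radii[2]
  z <- (seq_len(dim[3]) - center[3]) / radii[3]
  d2 <- outer(outer(x^2, y^2, `+`), z^2, `+`)
  d2 <= 1
}

runif1 <- function(range) runif(1, range[1], range[2])

# apply one effect rule to a voxel vector; strength in [0, 1]
apply_effect <- function(values, effect, strength) {
  if (is.null(effect)) return(values)
  if (effect$mode == "additive") values + strength * effect$value
  else values * (1 + strength * (effect$value - 1))
}

#' Generate a ground-truth phantom cohort
#'
#' Builds per-visit ground-truth scenes for each patient: parameter maps
#' (ADC, T1, M0, k-trans, ve, vp and the implied noiseless 90-s iAUC), an
#' integer label map (0 background, 1 normal tissue, 2 artery, 10+i tumor i),
#' and a truth table recording, per tumor and parameter, the programmed
#' responder flag and the true baseline/day-1 VOI medians. Treatment effects
#' are applied to the ground-truth maps (not to signals), so downstream
#' responder labels have an unambiguous truth. The whole cohort is a pure
#' function of (config, effect model, seed).
#'
#' @param config a [phantom_config()]
#' @param effect_model a [treatment_effect_model()]
#' @param seed integer seed
#' @param aif_par named list of [analytic_aif()] parameters used for the
#'   truth iAUC map and later DCE simulation (defaults used when NULL)
#' @return object of class `gt_cohort`: list with `patients` (each holding
#'   `scenes`, one `gt_scene` per visit), `truth` (data.frame), `config`,
#'   `effect_model`, `aif_par`, `seed`
#' @export
generate_ground_truth <- function(config, effect_model = treatment_effect_model(),
                                  seed = 1L, aif_par = NULL) {
  stopifnot(inherits(config, "phantom_config"),
            inherits(effect_model, "treatment_effect_model"))
  aif_par <- aif_par %||% list(t0_s = 64, peak1_mM = 4, rise_s = 8,
                               peak2_mM = 1, decay1_s = 80, decay2_s = 600)
  with_seed(seed, generate_ground_truth_impl(config, effect_model, aif_par, seed))
}

generate_ground_truth_impl <- function(config, effect_model, aif_par, seed) {
  dm <- config$dim
  nv <- prod(dm)
  # shared geometry scaffold: body ellipsoid + artery tube along z
  body <- ellipsoid_mask(dm, center = dm / 2 + 0.5,
                         radii = dm * c(0.45, 0.45, 0.6))
  artery_center_xy <- c(round(dm[1] * 0.15), round(dm[2] * 0.5))
  ax <- (seq_len(dm[1]) - artery_center_xy[1])^2
  ay <- (seq_len(dm[2]) - artery_center_xy[2])^2
  artery <- array(outer(outer(ax, ay, `+`), rep(0, dm[3]), `+`) <= 2.5^2, dm)
  patients <- vector("list", config$n_patients)
  truth <- list()
  visit_names <- config$visits
  params <- c("adc", "t1", "ktrans", "ve", "vp")
  # cohort-wide responder pool (fraction mode): exact count over all tumors
  total_tumors <- sum(config$tumors_per_patient)
  resp_pool <- NULL
  pool_at <- 1L
  if (effect_model$responder_rule$mode == "fraction") {
    k <- round(effect_model$responder_rule$fraction * total_tumors)
    resp_pool <- rep(FALSE, total_tumors)
    if (k > 0) resp_pool[sample(seq_len(total_tumors), k)] <- TRUE
  }
  for (p in seq_len(config$n_patients)) {
    pid <- sprintf("P%02d", p)
    nt <- config$tumors_per_patient[p]
    labels <- array(LABEL_BACKGROUND, dm)
    labels[body] <- LABEL_NORMAL
    labels[artery & body] <- LABEL_ARTERY
    tumor_means <- matrix(NA_real_, nt, length(params),
                          dimnames = list(NULL, params))
    tumor_masks <- vector("list", nt)
    placed <- 0L
    attempt <- 0L
    while (placed < nt && attempt < 500L) {
      attempt <- attempt + 1L
      radii <- c(runif1(config$tumor_radius_vox), runif1(config$tumor_radius_vox),
                 max(1.5, runif1(config$tumor_radius_vox) * dm[3] / dm[1]))
      center <- c(runif(1, dm[1] * 0.3, dm[1] * 0.75),
                  runif(1, dm[2] * 0.25, dm[2] * 0.75),
                  runif(1, dm[3] * 0.3, dm[3] * 0.7))
      m <- ellipsoid_mask(dm, center, radii)
      ok <- all(labels[m] == LABEL_NORMAL) && sum(m) >= 30
      if (!ok) next
      placed <- placed + 1L
      labels[m] <- tumor_label(placed)
      tumor_masks[[placed]] <- m
      tumor_means[placed, ] <- c(runif1(config$adc_range), runif1(config$t1_range),
                                 runif1(config$ktrans_range), runif1(config$ve_range),
                                 runif1(config$vp_range))
    }
    assert_that(placed == nt, "could not place ", nt, " tumors for patient ", pid,
                "; reduce tumor count or radius")
    # baseline maps
    base_maps <- list()
    for (j in seq_along(params)) {
      par <- params[j]
      mp <- array(0, dm)
      mp[labels == LABEL_NORMAL] <- config$normal[[par]]
      if (par %in% names(config$artery)) mp[labels == LABEL_ARTERY] <- config$artery[[par]]
      for (ti in seq_len(nt)) {
        m <- tumor_masks[[ti]]
        vox <- rep(tumor_means[ti, par], sum(m))
        if (config$heterogeneity > 0)
          vox <- vox * pmax(0.2, 1 + rnorm(length(vox), 0, config$heterogeneity))
        mp[m] <- vox
      }
      base_maps[[par]] <- mp
    }
    # enforce invariants
    base_maps$vp[labels == LABEL_ARTERY] <- 1
    base_maps$ve[labels == LABEL_ARTERY] <- 0
    base_maps$ktrans[labels == LABEL_ARTERY] <- 0
    tot <- base_maps$ve + base_maps$vp
    over <- tot > 1
    if (any(over)) {
      base_maps$ve[over] <- base_maps$ve[over] / tot[over]
      base_maps$vp[over] <- base_maps$vp[over] / tot[over]
    }
    m0_map <- array(0, dm)
    m0_map[labels != LABEL_BACKGROUND] <- config$m0
    # responder assignment
    resp <- switch(effect_model$responder_rule$mode,
      all = rep(TRUE, nt),
      none = rep(FALSE, nt),
      fraction = resp_pool[seq(pool_at, length.out = nt)],
      threshold = {
        rr <- effect_model$responder_rule
        bl <- vapply(seq_len(nt), function(ti)
          stats::median(base_maps[[rr$parameter]][tumor_masks[[ti]]]), 0)
        if (rr$op == ">") bl > rr$cut else bl < rr$cut
      })
    # per-visit scenes
    scenes <- list()
    for (vi in seq_along(visit_names)) {
      maps <- base_maps
      if (vi > 1) {
        strength <- effect_model$recovery^(vi - 2) # vi = 2 is day 1
        for (par in names(effect_model$effects)) {
          eff <- effect_model$effects[[par]]
          for (ti in which(resp)) {
            m <- tumor_masks[[ti]]
            maps[[par]][m] <- apply_effect(maps[[par]][m], eff, strength)
          }
        }
        maps$adc <- pmax(maps$adc, 0)
        maps$t1[labels != LABEL_BACKGROUND] <-
          pmax(maps$t1[labels != LABEL_BACKGROUND], 0.05)
        maps$ktrans <- pmax(maps$ktrans, 0)
        maps$vp <- pmin(pmax(maps$vp, 0), 1)
        maps$ve <- pmin(pmax(maps$ve, 0), 1 - maps$vp)
      }
      scenes[[visit_names[vi]]] <- gt_scene(dm, config$spacing_mm, maps, m0_map,
                                            labels, visit_names[vi], pid,
                                            aif_par)
    }
    # truth table: per tumor x parameter, programmed flags and true medians
    eff_names <- names(effect_model$effects)
    any_pk <- any(c("ktrans", "ve", "vp") %in% eff_names)
    for (ti in seq_len(nt)) {
      m <- tumor_masks[[ti]]
      for (par in c(params, "iauc")) {
        programmed <- if (par == "iauc") resp[ti] && any_pk
                      else resp[ti] && par %in% eff_names
        bmed <- stats::median(scenes[[1]]$maps[[par]][m])
        dmed <- if (length(scenes) >= 2) stats::median(scenes[[2]]$maps[[par]][m]) else NA_real_
        truth[[length(truth) + 1L]] <- data.frame(
          patient_id = pid, tumor_id = ti, parameter = par,
          responder = programmed, true_baseline = bmed, true_day1 = dmed,
          stringsAsFactors = FALSE)
      }
    }
    patients[[p]] <- list(patient_id = pid, scenes = scenes, n_tumors = nt)
    pool_at <- pool_at + nt
  }
  structure(list(patients = patients, truth = do.call(rbind, truth),
                 config = config, effect_model = effect_model,
                 aif_par = aif_par, seed = seed),
            class = "gt_cohort")
}

# ground-truth scene constructor; adds the implied noiseless 90-s iAUC map
gt_scene <- function(dim, spacing_mm, maps, m0_map, labels, visit, patient_id,
                     aif_par) {
  maps$m0 <- m0_map
  frame_times <- seq(0, by = 8, length.out = 48)
  cp <- do.call(analytic_aif, c(list(time_s = frame_times), aif_par))
  idx <- which(labels != LABEL_BACKGROUND)
  ct <- tofts_forward_matrix(maps$ktrans[idx], maps$ve[idx], maps$vp[idx],
                             cp, frame_times)
  inj <- which(cp > 0)[1]
  iauc <- array(0, dim)
  iauc[idx] <- iauc_from_curves(ct, frame_times, t_start = frame_times[inj],
                                window_s = 90)
  maps$iauc <- iauc
  structure(list(dim = dim, spacing_mm = spacing_mm, maps = maps,
                 labels = labels, visit = visit, patient_id = patient_id,
                 aif_par = aif_par),
            class = "gt_scene")
}

#' @export
print.gt_cohort <- function(x, ...) {
  cat(sprintf("<gt_cohort: %d patients, visits: %s, grid %s>\n",
              length(x$patients),
              paste(x$config$visits, collapse = ", "),
              paste(x$config$dim, collapse = "x")))
  invisible(x)
}

#' Masks of a phantom scene
#' @param scene a ground-truth scene from [generate_ground_truth()]
#' @param what `"tumor"` (all tumors), a tumor id (integer), `"artery"`,
#'   `"normal"` or `"body"`
#' @return logical array
#' @export
scene_mask <- function(scene, what = "tumor") {
  l <- scene$labels
  if (is.numeric(what)) return(l == tumor_label(what))
  switch(what,
         tumor = l >= LABEL_TUMOR_BASE,
         artery = l == LABEL_ARTERY,
         normal = l == LABEL_NORMAL,
         body = l != LABEL_BACKGROUND,
         stop_qmri("unknown mask: ", what))
}

#' Simulate a diffusion-weighted series from a scene
#'
#' Noiseless signal follows the mono-exponential model
#' `S(b) = S0 * exp(-b * ADC)`; replicates differ only by their noise
#' realization (noise seed is offset by the replicate index).
#'
#' @param scene a ground-truth scene
#' @param b_values b-values in s/mm^2 (default protocol `c(0, 450)`)
#' @param n_replicates number of replicate acquisitions
#' @param noise a [noise_model()] or NULL for noiseless
#' @return list of [image_series()], one per replicate
#' @export
simulate_dwi <- function(scene, b_values = c(0, 450), n_replicates = 3,
                         noise = NULL) {
  assert_that(length(b_values) >= 1, "b_values must be non-empty")
  assert_that(all(b_values >= 0), "b-values must be >= 0")
  assert_that(n_replicates >= 1, "need at least one replicate")
  dm <- scene$dim
  sig <- array(0, c(dm, length(b_values)))
  for (i in seq_along(b_values))
    sig[, , , i] <- scene$maps$m0 * exp(-b_values[i] * scene$maps$adc)
  lapply(seq_len(n_replicates), function(r) {
    s <- image_series(sig, kind = "dwi", b_values = b_values,
                      spacing_mm = scene$spacing_mm, replicate = r)
    if (!is.null(noise)) {
      nr <- noise; nr$seed <- noise$seed + r - 1L
      s <- add_noise(s, nr)
    }
    s
  })
}

#' Simulate a variable-flip-angle series from a scene
#'
#' Noiseless signal follows the SPGR steady-state equation (see
#' [spgr_signal()]) at each protocol flip angle.
#'
#' @param scene a ground-truth scene
#' @param flip_angles_deg flip angles in degrees (protocol default 15/23/30/60)
#' @param tr_ms repetition time, ms
#' @param noise a [noise_model()] or NULL
#' @param scales optional per-image intensity scale factors (simulating
#'   inter-image scaling differences); length must match `flip_angles_deg`
#' @return an [image_series()]
#' @export
simulate_vfa <- function(scene, flip_angles_deg = c(15, 23, 30, 60), tr_ms = 3,
                         noise = NULL, scales = NULL) {
  assert_that(length(flip_angles_deg) >= 1, "need at least one flip angle")
  assert_that(tr_ms > 0, "TR must be positive")
  dm <- scene$dim
  body <- scene$labels != LABEL_BACKGROUND
  sig <- array(0, c(dm, length(flip_angles_deg)))
  for (i in seq_along(flip_angles_deg)) {
    v <- array(0, dm)
    v[body] <- spgr_signal(scene$maps$m0[body], scene$maps$t1[body],
                           flip_angles_deg[i], tr_ms)
    if (!is.null(scales)) v <- v * scales[i]
    sig[, , , i] <- v
  }
  s <- image_series(sig, kind = "vfa", flip_angles_deg = flip_angles_deg,
                    tr_ms = tr_ms, spacing_mm = scene$spacing_mm)
  if (!is.null(noise)) s <- add_noise(s, noise)
  s
}

#' Analytic arterial input function
#'
#' A bolus-rise times biexponential-decay form:
#' `Cp(t') = (1 - exp(-t'/rise)) * (A1 exp(-t'/d1) + A2 exp(-t'/d2))` for
#' `t' = t - t0 > 0`, zero before the bolus arrival `t0`. Peaks around
#' `peak1_mM + peak2_mM` shortly after `t0` with a fast and a slow washout
#' compartment, the usual shape of a first-pass gadolinium plasma curve.
#'
#' @param time_s time grid, s
#' @param t0_s bolus arrival time, s
#' @param peak1_mM,decay1_s fast compartment amplitude (mM) and decay (s)
#' @param peak2_mM,decay2_s slow compartment amplitude (mM) and decay (s)
#' @param rise_s bolus rise time constant, s
#' @return plasma concentration in mM on `time_s`
#' @export
analytic_aif <- function(time_s, t0_s = 64, peak1_mM = 4, rise_s = 8,
                         peak2_mM = 1, decay1_s = 80, decay2_s = 600) {
  tp <- pmax(time_s - t0_s, 0)
  on <- as.numeric(time_s > t0_s)
  on * (1 - exp(-tp / rise_s)) *
    (peak1_mM * exp(-tp / decay1_s) + peak2_mM * exp(-tp / decay2_s))
}

#' Simulate a dynamic contrast-enhanced series from a scene
#'
#' Per voxel, the tissue concentration follows the extended Tofts forward
#' model driven by the supplied AIF (artery voxels carry the AIF itself:
#' `vp = 1`, `ve = 0`). Concentration shortens T1 via
#' `1/T1(t) = 1/T1(0) + r1 C(t)`, and the SPGR equation at the dynamic flip
#' angle gives the signal. Frames before the injection carry no contrast.
#'
#' @param scene a ground-truth scene
#' @param aif an [aif()] defined on (at least) the frame time grid; NULL
#'   builds the scene's analytic AIF with bolus arrival at the first
#'   post-baseline frame
#' @param frame_interval_s frame spacing, s
#' @param n_frames number of dynamic frames
#' @param n_baseline_frames frames acquired before injection
#' @param fa_deg dynamic flip angle, degrees
#' @param tr_ms repetition time, ms
#' @param relaxivity contrast agent r1, mM^-1 s^-1
#' @param noise a [noise_model()] or NULL
#' @return an [image_series()] of kind `"dce"`
#' @export
simulate_dce <- function(scene, aif = NULL, frame_interval_s = 8, n_frames = 48,
                         n_baseline_frames = 8, fa_deg = 30, tr_ms = 3,
                         relaxivity = 4.5, noise = NULL) {
  assert_that(n_baseline_frames >= 1 && n_baseline_frames < n_frames,
              "n_baseline_frames must lie in [1, n_frames)")
  times <- seq(0, by = frame_interval_s, length.out = n_frames)
  if (is.null(aif)) {
    ap <- scene$aif_par
    ap$t0_s <- times[n_baseline_frames] # contrast visible from the next frame
    cp <- do.call(analytic_aif, c(list(time_s = times), ap))
    aif <- aif(times, cp, source = "analytic")
  }
  assert_that(inherits(aif, "aif"), "aif must be an aif object")
  assert_that(min(aif$time_s) <= min(times) && max(aif$time_s) >= max(times),
              "AIF does not cover the frame time grid")
  cp <- stats::approx(aif$time_s, aif$cp_mM, xout = times)$y
  dm <- scene$dim
  idx <- which(scene$labels != LABEL_BACKGROUND)
  ct <- tofts_forward_matrix(scene$maps$ktrans[idx], scene$maps$ve[idx],
                             scene$maps$vp[idx], cp, times)
  t1_0 <- scene$maps$t1[idx]
  m0 <- scene$maps$m0[idx]
  sig <- array(0, c(dm, n_frames))
  base <- array(0, dm)
  for (f in seq_len(n_frames)) {
    r1t <- 1 / t1_0 + relaxivity * ct[, f]
    v <- base
    v[idx] <- spgr_signal(m0, 1 / r1t, fa_deg, tr_ms)
    sig[, , , f] <- v
  }
  s <- image_series(sig, kind = "dce", flip_angles_deg = fa_deg, tr_ms = tr_ms,
                    frame_times_s = times,
                    injection_frame = n_baseline_frames + 1L,
                    relaxivity = relaxivity, spacing_mm = scene$spacing_mm)
  if (!is.null(noise)) s <- add_noise(s, noise)
  s
}
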