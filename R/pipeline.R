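# End-to-end pipeline driver: simulate -> fit ADC/T1 -> concentration/AIF/
# iAUC/Tofts -> VOI response -> pixel-wise model.

#' Study configuration
#'
#' Validates all pipeline settings up front (a malformed configuration
#' fails before any computation). Acquisition defaults follow the imaging
#' protocol this pipeline targets: DW-MRI at b = 0/450 s/mm^2 with 3
#' replicates, VFA at 15/23/30/60 degrees with TR 3 ms, and a dynamic
#' series of 48 frames every 8 s at FA 30 degrees.
#'
#' @param phantom a [phantom_config()]
#' @param effects a [treatment_effect_model()]
#' @param seed master seed; all stage seeds derive from it
#' @param dwi list: b_values, n_replicates, snr
#' @param vfa list: flip_angles_deg, tr_ms, snr, smooth_sigma (in-plane
#'   Gaussian pre-smoothing of the flip-angle images, voxels; the T1-map
#'   smoothness constraint)
#' @param dce list: frame_interval_s, n_frames, n_baseline_frames, fa_deg,
#'   tr_ms, relaxivity (mM^-1 s^-1), snr, blood_t1_s (reference blood T1
#'   used for the arterial concentration conversion)
#' @param noise_family `"rician"` (default) or `"gaussian"`
#' @param rc_literature literature RC bands (see [rc_literature_defaults()])
#' @param strict strict protocol validation for DWI b-values
#' @param pixelwise list: enabled, max_depth, n_repeats, lopo (logical),
#'   group_rc_fallback
#' @param aif_k top-k artery voxels averaged into the AIF (default Inf:
#'   average all; phantom arteries have no partial-volume voxels to reject)
#' @param iauc_window_s iAUC window in seconds
#' @return object of class `study_config`
#' @export
study_config <- function(phantom = phantom_config(),
                         effects = treatment_effect_model(),
                         seed = 1L,
                         dwi = list(b_values = c(0, 450), n_replicates = 3, snr = 50),
                         vfa = list(flip_angles_deg = c(15, 23, 30, 60),
                                    tr_ms = 3, snr = 150, smooth_sigma = 0),
                         dce = list(frame_interval_s = 8, n_frames = 48,
                                    n_baseline_frames = 8, fa_deg = 30,
                                    tr_ms = 3, relaxivity = 4.5, snr = 50,
                                    blood_t1_s = 1.4),
                         noise_family = "rician",
                         rc_literature = rc_literature_defaults(),
                         strict = FALSE,
                         pixelwise = list(enabled = TRUE, max_depth = 2,
                                          n_repeats = 10, lopo = FALSE,
                                          group_rc_fallback = 1.4e-3),
                         aif_k = Inf, iauc_window_s = 90) {
  stopifnot(inherits(phantom, "phantom_config"),
            inherits(effects, "treatment_effect_model"))
  assert_that(all(dwi$b_values >= 0) && length(dwi$b_values) >= 2,
              "dwi: need >= 2 non-negative b-values")
  assert_that(dwi$n_replicates >= 1, "dwi: n_replicates must be >= 1")
  assert_that(length(vfa$flip_angles_deg) >= 2 && vfa$tr_ms > 0,
              "vfa: need >= 2 flip angles and positive TR")
  assert_that(dce$relaxivity > 0, "dce: relaxivity must be positive")
  assert_that(dce$fa_deg > 0 && dce$fa_deg <= 90, "dce: FA must be in (0, 90]")
  assert_that(dce$n_baseline_frames >= 1 &&
                dce$n_baseline_frames < dce$n_frames,
              "dce: n_baseline_frames must be in [1, n_frames)")
  assert_that(is.null(dwi$snr) || dwi$snr > 0, "dwi: snr must be positive")
  assert_that(iauc_window_s > 0 &&
                iauc_window_s <= (dce$n_frames - dce$n_baseline_frames - 1) *
                  dce$frame_interval_s,
              "iauc window exceeds the post-injection acquisition")
  assert_that(noise_family %in% c("rician", "gaussian"), "unknown noise family")
  structure(list(phantom = phantom, effects = effects, seed = as.integer(seed),
                 dwi = dwi, vfa = vfa, dce = dce, noise_family = noise_family,
                 rc_literature = rc_literature, strict = strict,
                 pixelwise = pixelwise, aif_k = aif_k,
                 iauc_window_s = iauc_window_s),
            class = "study_config")
}

# deterministic stage seed derived from the master seed (kept < 2^31)
stage_seed <- function(seed, patient, visit, stage) {
  (seed * 97L + patient * 7919L + visit * 389L + stage * 31L) %% 2147483629L
}

mk_noise <- function(family, snr, seed) {
  if (is.null(snr)) return(NULL)
  noise_model(family, snr = snr, seed = seed)
}

#' Run the full analysis pipeline on a simulated cohort
#'
#' Executes simulate -> ADC fit -> T1 fit -> concentration/AIF/iAUC/Tofts ->
#' VOI response labeling and threshold models -> pixel-wise model, and (when
#' the cohort carries a ground truth) evaluates recovered responder labels
#' against the programmed ones. Every per-patient exclusion (missing b = 0,
#' single flip angle, protocol deviation) surfaces as a logged warning or a
#' stage-tagged error rather than a silent drop.
#'
#' @param config a [study_config()]
#' @param cohort optional pre-generated [generate_ground_truth()] cohort
#'   (defaults to generating one from the config)
#' @param out_dir optional output directory; when given, cohort/threshold/
#'   pixel-wise CSVs, the AIF and a JSON summary are written there
#' @param verbose print stage progress
#' @return list: `cohort_table` (labeled), `rc` (replicate RC analysis),
#'   `rc_spec`, `thresholds` (per-parameter [optimize_threshold()] models),
#'   `associations`, `truth_evaluation` (per-parameter + pooled BA against
#'   programmed labels), `pixel` (dataset, model, optional LOPO), `maps`
#'   (per patient/visit fitted maps), `aifs`
#' @export
run_pipeline <- function(config, cohort = NULL, out_dir = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(config, "study_config"))
  say <- function(...) if (verbose) message(...)
  say("[simulate] generating phantom cohort")
  cohort <- cohort %||% generate_ground_truth(config$phantom, config$effects,
                                              seed = config$seed)
  visits <- config$phantom$visits
  fam <- config$noise_family
  s0 <- config$phantom$m0
  rows <- list()
  adc_reps <- list() # replicate ADC medians at baseline, per tumor
  pix_reps <- list() # per-patient pixel replicate matrices (baseline, tumors)
  maps_all <- list()
  aifs <- list()
  for (pi in seq_along(cohort$patients)) {
    pat <- cohort$patients[[pi]]
    pid <- pat$patient_id
    for (vi in seq_along(visits)) {
      vname <- visits[vi]
      scene <- pat$scenes[[vname]]
      tumor_masks <- lapply(seq_len(pat$n_tumors), function(ti)
        scene_mask(scene, ti))
      ## --- stage: DWI -> ADC ---------------------------------------------
      n_rep <- if (vi == 1) config$dwi$n_replicates else 1L
      dwi <- simulate_dwi(scene, b_values = config$dwi$b_values,
                          n_replicates = n_rep,
                          noise = mk_noise(fam, config$dwi$snr,
                                           stage_seed(config$seed, pi, vi, 1L)))
      fits <- lapply(seq_along(dwi), function(r)
        fit_adc(dwi[[r]], expected_b = config$dwi$b_values,
                strict = config$strict,
                series_id = paste0(pid, "/", vname, "/DWI rep ", r)))
      adc_map <- combine_replicates(fits)
      if (vi == 1 && n_rep >= 2) {
        for (ti in seq_len(pat$n_tumors)) {
          med <- vapply(fits, function(f)
            voi_medians(f$adc, tumor_masks[[ti]],
                        id = paste0(pid, " tumor ", ti)), 0)
          adc_reps[[length(adc_reps) + 1L]] <-
            data.frame(tumor = paste0(pid, ":", ti), value = med)
        }
        tum_any <- scene_mask(scene, "tumor")
        pix_reps[[pid]] <- sapply(fits, function(f) f$adc$values[tum_any])
      }
      ## --- stage: VFA -> T1 ----------------------------------------------
      vfa <- simulate_vfa(scene, flip_angles_deg = config$vfa$flip_angles_deg,
                          tr_ms = config$vfa$tr_ms,
                          noise = mk_noise(fam, config$vfa$snr,
                                           stage_seed(config$seed, pi, vi, 2L)))
      t1fit <- fit_t1_vfa(vfa, smooth_sigma = config$vfa$smooth_sigma %||% 0,
                          series_id = paste0(pid, "/", vname, "/VFA"))
      ## --- stage: DCE -> concentration, AIF, iAUC, Tofts ------------------
      dce <- simulate_dce(scene, frame_interval_s = config$dce$frame_interval_s,
                          n_frames = config$dce$n_frames,
                          n_baseline_frames = config$dce$n_baseline_frames,
                          fa_deg = config$dce$fa_deg, tr_ms = config$dce$tr_ms,
                          relaxivity = config$dce$relaxivity,
                          noise = mk_noise(fam, config$dce$snr,
                                           stage_seed(config$seed, pi, vi, 3L)))
      artery <- scene_mask(scene, "artery")
      inj <- detect_injection(dce, mask = artery)
      conc <- signal_to_concentration(dce, t1fit$t1,
                                      injection_frame = inj$injection_frame,
                                      baseline_frames = inj$baseline_frames)
      # arterial conversion uses the literature blood T1 (a fitted blood T1
      # would propagate its error into every downstream PK parameter)
      blood_t1 <- parameter_map(array(config$dce$blood_t1_s %||% 1.4,
                                      dim(scene$labels)),
                                artery, "s", "t1_blood")
      conc_art <- signal_to_concentration(dce, blood_t1,
                                          injection_frame = inj$injection_frame,
                                          baseline_frames = inj$baseline_frames,
                                          mask = artery)
      aif_v <- extract_aif(conc_art, artery, k = config$aif_k)
      iauc_map <- compute_iauc(conc, window_s = config$iauc_window_s)
      tum_any <- scene_mask(scene, "tumor")
      pk <- fit_pk_maps(conc, aif_v, mask = tum_any)
      maps <- list(adc = adc_map, t1 = t1fit$t1, iauc = iauc_map,
                   ktrans = pk$ktrans, ve = pk$ve, vp = pk$vp)
      maps_all[[paste0(pid, ".", vname)]] <- maps
      aifs[[paste0(pid, ".", vname)]] <- aif_v
      ## --- stage: VOI medians --------------------------------------------
      for (ti in seq_len(pat$n_tumors)) {
        for (par in names(maps)) {
          rows[[length(rows) + 1L]] <- data.frame(
            patient_id = pid, tumor_id = ti, visit = vname, parameter = par,
            median = voi_medians(maps[[par]], tumor_masks[[ti]],
                                 id = paste0(pid, "/", vname, "/tumor ", ti,
                                             "/", par)),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  table <- do.call(rbind, rows)
  ## --- stage: repeatability + responder labeling --------------------------
  say("[respond] repeatability and responder labels")
  rc <- rc_from_replicates(do.call(rbind, adc_reps))
  spec <- build_rc_spec(rc$group_rc,
                        adc_rc_by_tumor = stats::setNames(rc$per_tumor$rc,
                                                          rc$per_tumor$tumor),
                        literature = config$rc_literature)
  labeled <- label_responders(table, spec, baseline_visit = visits[1],
                              label_visit = visits[2])
  ## --- stage: threshold models + associations -----------------------------
  dir_of <- function(par) if (par %in% c("adc", "t1")) ">" else "<"
  thresholds <- list()
  for (par in unique(labeled$parameter)) {
    d <- labeled[labeled$parameter == par & !is.na(labeled$label), ]
    if (length(unique(d$label)) == 2)
      thresholds[[par]] <- optimize_threshold(d$baseline, d$label,
                                              direction = dir_of(par),
                                              parameter = par)
  }
  n_tum <- length(unique(paste(labeled$patient_id, labeled$tumor_id)))
  associations <- if (n_tum >= 3) association_stats(labeled) else NULL
  ## --- stage: truth evaluation --------------------------------------------
  truth_evaluation <- NULL
  if (!is.null(cohort$truth)) {
    tr <- cohort$truth
    key <- function(d) paste(d$patient_id, d$tumor_id, d$parameter, sep = ":")
    lut <- stats::setNames(ifelse(tr$responder, "P", "N"), key(tr))
    truth_lab <- lut[key(labeled)]
    ok <- !is.na(truth_lab) & !is.na(labeled$label)
    pooled <- classification_metrics(labeled$label[ok], truth_lab[ok])
    per_par <- do.call(rbind, lapply(unique(labeled$parameter), function(par) {
      sel <- ok & labeled$parameter == par
      m <- classification_metrics(labeled$label[sel], truth_lab[sel])
      data.frame(parameter = par, ba = m$ba, sensitivity = m$sensitivity,
                 specificity = m$specificity, n = m$n,
                 stringsAsFactors = FALSE)
    }))
    truth_evaluation <- list(pooled = pooled, per_parameter = per_par)
  }
  ## --- stage: pixel-wise ---------------------------------------------------
  pixel <- NULL
  if (isTRUE(config$pixelwise$enabled)) {
    say("[pixelwise] pixel dataset and decision-rule model")
    grp_rc <- if (length(pix_reps)) {
      group_pixel_rc(pix_reps, seed = config$seed)
    } else config$pixelwise$group_rc_fallback
    ds <- list()
    for (pi in seq_along(cohort$patients)) {
      pat <- cohort$patients[[pi]]
      pid <- pat$patient_id
      mb <- maps_all[[paste0(pid, ".", visits[1])]]
      md <- maps_all[[paste0(pid, ".", visits[2])]]
      scene <- pat$scenes[[1]]
      for (ti in seq_len(pat$n_tumors)) {
        m <- scene_mask(scene, ti)
        ok <- m & Reduce(`&`, lapply(mb, function(x) x$mask)) &
          Reduce(`&`, lapply(md, function(x) x$mask))
        if (!any(ok)) next
        baselines <- lapply(mb, function(x) x$values[ok])
        deltas <- Map(function(b, d) d$values[ok] - b$values[ok], mb, md)
        adc_pix <- pix_reps[[pid]]
        rc_t <- if (!is.null(adc_pix))
          pixel_rc(adc_pix[scene$labels[scene_mask(scene, "tumor")] ==
                             tumor_label(ti), , drop = FALSE],
                   group_fallback = grp_rc)$rc
        else grp_rc
        lab <- label_pixels(baselines, deltas, spec, adc_rc = rc_t)
        ds[[length(ds) + 1L]] <- pixel_dataset(pid, ti, baselines, deltas,
                                               lab$any)
      }
    }
    dataset <- do.call(rbind, ds)
    model <- train_threshold_tree(dataset,
                                  max_depth = config$pixelwise$max_depth,
                                  n_repeats = config$pixelwise$n_repeats,
                                  seed = config$seed)
    lopo <- if (isTRUE(config$pixelwise$lopo))
      lopo_evaluate(dataset, max_depth = config$pixelwise$max_depth,
                    n_repeats = max(2L, config$pixelwise$n_repeats %/% 2L),
                    seed = config$seed)
    pixel <- list(dataset = dataset, model = model, lopo = lopo,
                  group_pixel_rc = grp_rc)
  }
  bundle <- list(cohort_table = labeled, rc = rc, rc_spec = spec,
                 thresholds = thresholds, associations = associations,
                 truth_evaluation = truth_evaluation, pixel = pixel,
                 maps = maps_all, aifs = aifs, config = config)
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

# write the CSV/JSON output bundle
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort_table(bundle$cohort_table, file.path(out_dir, "cohort_table.csv"))
  if (length(bundle$thresholds)) {
    th <- do.call(rbind, lapply(bundle$thresholds, function(t)
      data.frame(parameter = t$parameter, direction = t$direction,
                 cutpoint = t$cutpoint, sensitivity = t$sensitivity,
                 specificity = t$specificity, ba = t$ba,
                 mcnemar_p = t$mcnemar_p, stringsAsFactors = FALSE)))
    write_table_csv(th, file.path(out_dir, "thresholds.csv"))
    jsonlite::write_json(bundle$thresholds, file.path(out_dir, "thresholds.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  write_table_csv(bundle$rc$per_tumor, file.path(out_dir, "adc_rc.csv"))
  if (length(bundle$aifs)) write_aif(bundle$aifs[[1]], file.path(out_dir, "aif.csv"))
  if (!is.null(bundle$pixel)) {
    write_table_csv(bundle$pixel$dataset, file.path(out_dir, "pixel_dataset.csv"))
    jsonlite::write_json(list(rules = bundle$pixel$model$rules,
                              training_ba = bundle$pixel$model$training_ba,
                              mean_validation_ba = bundle$pixel$model$mean_validation_ba),
                         file.path(out_dir, "pixel_model.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    if (!is.null(bundle$pixel$lopo))
      write_table_csv(bundle$pixel$lopo$per_patient,
                      file.path(out_dir, "lopo.csv"))
  }
  if (!is.null(bundle$truth_evaluation)) {
    jsonlite::write_json(list(pooled = bundle$truth_evaluation$pooled,
                              per_parameter = bundle$truth_evaluation$per_parameter),
                         file.path(out_dir, "truth_evaluation.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  invisible(out_dir)
}
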