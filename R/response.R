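# VOI-level response statistics: medians, repeatability coefficients,
# responder labeling, threshold models, association and agreement statistics.

#' Repeatability coefficient from a within-subject variance
#'
#' QIBA convention: `RC = 2.77 sqrt(sigma^2)`, the band outside which a
#' change between two measurements is deemed a true change (95% of repeated
#' measurements fall inside -RC..+RC).
#'
#' @param sigma2 within-subject variance (parameter units squared)
#' @return RC in parameter units
#' @export
repeatability_coefficient <- function(sigma2) {
  assert_that(all(sigma2 >= 0), "variance must be non-negative")
  2.77 * sqrt(sigma2)
}

#' Median of a parameter map over a volume of interest
#'
#' Median over the valid, finite in-mask voxels. Invalid or NaN-flagged
#' voxels are excluded before the median; an even voxel count uses the mean
#' of the central pair (the default of [stats::median()]).
#'
#' @param map a [parameter_map()] (or plain numeric array)
#' @param mask logical array
#' @param id identifier (tumor/visit) used in error messages
#' @return the median value
#' @export
voi_medians <- function(map, mask, id = "VOI") {
  if (inherits(map, "parameter_map")) {
    v <- map$values[mask & map$mask]
  } else {
    v <- map[mask]
  }
  v <- v[is.finite(v)]
  if (!length(v)) stop_qmri(id, ": mask is empty or all voxels invalid")
  stats::median(v)
}

#' Repeatability coefficient from replicate VOI medians
#'
#' Per tumor, `sigma^2` is the variance of the replicate medians and
#' `RC = 2.77 sqrt(sigma^2)`; the group RC applies the same formula to the
#' pooled (degrees-of-freedom-weighted) within-tumor variance and is the
#' fallback for tumors without replicates. Pooling, rather than taking a
#' median of per-tumor RCs, keeps the estimator unbiased with 2-3
#' replicates, which is what makes the 95% coverage of the -RC..+RC band
#' hold. A Bland-Altman summary of the replicate differences (bias and
#' 1.96-sd limits of agreement) is also returned.
#'
#' @param replicates data.frame with columns `tumor` (any id) and `value`
#'   (replicate VOI medians, >= 2 rows per tumor for a per-tumor RC)
#' @return list: `per_tumor` (data.frame tumor, n, sigma2, rc), `group_rc`,
#'   `bland_altman` (bias, loa_lower, loa_upper, differences, means)
#' @export
rc_from_replicates <- function(replicates) {
  assert_that(is.data.frame(replicates) &&
                all(c("tumor", "value") %in% names(replicates)),
              "replicates must have columns tumor, value")
  sp <- split(replicates$value, replicates$tumor)
  n <- vapply(sp, length, 0L)
  if (!any(n >= 2)) stop_qmri("no tumor has >= 2 replicates; no RC derivable")
  sigma2 <- vapply(sp, function(v) if (length(v) >= 2) stats::var(v) else NA_real_, 0)
  per_tumor <- data.frame(tumor = names(sp), n = n,
                          sigma2 = sigma2,
                          rc = repeatability_coefficient(ifelse(is.na(sigma2), 0, sigma2)),
                          row.names = NULL, stringsAsFactors = FALSE)
  per_tumor$rc[is.na(sigma2)] <- NA_real_
  df <- pmax(n - 1L, 0L)
  pooled <- sum(sigma2 * df, na.rm = TRUE) / sum(df[!is.na(sigma2)])
  group_rc <- repeatability_coefficient(pooled)
  means <- unlist(lapply(sp[n >= 2], function(v)
    (outer(v, v, `+`) / 2)[upper.tri(diag(length(v)))]))
  diffs <- unlist(lapply(sp[n >= 2], function(v)
    outer(v, v, `-`)[upper.tri(diag(length(v)))]))
  bias <- mean(diffs)
  s <- stats::sd(diffs)
  list(per_tumor = per_tumor, group_rc = group_rc,
       bland_altman = list(bias = bias,
                           loa_lower = bias - 1.96 * s,
                           loa_upper = bias + 1.96 * s,
                           differences = diffs, means = means))
}

#' Literature repeatability bands
#'
#' The default repeatability bands for parameters without replicate scans,
#' taken from published repeatability studies of tumor DCE-MRI and T1
#' mapping: absolute 0.27 s for T1, relative 32% for iAUC, asymmetric
#' -45%/+83% for k-trans, absolute 0.076 for ve and 0.0062 for vp.
#'
#' @return data.frame with columns parameter, band_type, rc_abs, lower_pct,
#'   upper_pct, direction, provenance
#' @export
rc_literature_defaults <- function() {
  data.frame(
    parameter = c("t1", "iauc", "ktrans", "ve", "vp"),
    band_type = c("absolute", "relative", "asymmetric", "absolute", "absolute"),
    rc_abs = c(0.27, NA, NA, 0.076, 0.0062),
    lower_pct = c(NA, -32, -45, NA, NA),
    upper_pct = c(NA, 32, 83, NA, NA),
    direction = c("decrease", "increase", "increase", "increase", "increase"),
    provenance = "literature",
    stringsAsFactors = FALSE)
}

#' Build a repeatability specification for all analyzed parameters
#'
#' ADC uses the replicate-derived RC (per tumor where available, group
#' fallback otherwise); the other parameters use the configured literature
#' bands. The expected response direction is a decrease for ADC and T1 and
#' an increase for iAUC, k-trans, ve and vp.
#'
#' @param adc_group_rc group (fallback) ADC RC in mm^2/s
#' @param adc_rc_by_tumor optional named numeric vector of per-tumor ADC RCs
#'   (names = tumor keys as used in the cohort table, `"patient:tumor"`)
#' @param literature literature bands, default [rc_literature_defaults()]
#' @return object of class `rc_spec`
#' @export
build_rc_spec <- function(adc_group_rc, adc_rc_by_tumor = NULL,
                          literature = rc_literature_defaults()) {
  assert_that(is.numeric(adc_group_rc) && adc_group_rc >= 0,
              "adc_group_rc must be a non-negative number")
  needed <- c("t1", "iauc", "ktrans", "ve", "vp")
  missing <- setdiff(needed, literature$parameter)
  if (length(missing))
    stop_qmri("no repeatability source for: ", paste(missing, collapse = ", "))
  spec <- rbind(
    data.frame(parameter = "adc", band_type = "absolute", rc_abs = adc_group_rc,
               lower_pct = NA, upper_pct = NA, direction = "decrease",
               provenance = "replicates", stringsAsFactors = FALSE),
    literature)
  structure(list(table = spec, adc_rc_by_tumor = adc_rc_by_tumor),
            class = "rc_spec")
}

# significance band (delta_lower, delta_upper) for one parameter at a
# baseline value; tumor_key looks up per-tumor ADC RCs
rc_band <- function(spec, parameter, baseline, tumor_key = NULL) {
  stopifnot(inherits(spec, "rc_spec"))
  row <- spec$table[spec$table$parameter == parameter, ]
  if (!nrow(row)) stop_qmri("parameter missing from RC spec: ", parameter)
  if (parameter == "adc" && !is.null(tumor_key) &&
      !is.null(spec$adc_rc_by_tumor) && tumor_key %in% names(spec$adc_rc_by_tumor)) {
    rc <- spec$adc_rc_by_tumor[[tumor_key]]
    return(c(-rc, rc))
  }
  switch(row$band_type,
         absolute = c(-row$rc_abs, row$rc_abs),
         relative = c(row$lower_pct, row$upper_pct) / 100 * baseline,
         asymmetric = c(row$lower_pct, row$upper_pct) / 100 * baseline,
         stop_qmri("unknown band type: ", row$band_type))
}

#' Label tumors as pharmacodynamic responders
#'
#' For each (patient, tumor, parameter), the change from baseline at the
#' label visit is compared with the repeatability band: the significance
#' flag is `below` / `within` / `above`, and the responder label is `P`
#' exactly when the significant change is in the parameter's expected
#' direction (below -RC for ADC and T1; above +RC for iAUC, k-trans, ve,
#' vp), otherwise `N`. Labels are only defined where both baseline and
#' label-visit medians exist.
#'
#' @param table cohort table: data.frame with columns patient_id, tumor_id,
#'   visit, parameter, median
#' @param spec an [build_rc_spec()] object
#' @param baseline_visit,label_visit visit names (defaults "baseline", "day1")
#' @return the cohort table restricted to the label visit, with added
#'   columns baseline, delta, flag, label
#' @export
label_responders <- function(table, spec, baseline_visit = "baseline",
                             label_visit = "day1") {
  stopifnot(inherits(spec, "rc_spec"))
  need <- c("patient_id", "tumor_id", "visit", "parameter", "median")
  assert_that(all(need %in% names(table)), "cohort table misses columns: ",
              paste(setdiff(need, names(table)), collapse = ", "))
  missing <- setdiff(unique(table$parameter), spec$table$parameter)
  if (length(missing))
    stop_qmri("parameter missing from RC spec: ", paste(missing, collapse = ", "))
  base <- table[table$visit == baseline_visit, ]
  day1 <- table[table$visit == label_visit, ]
  key <- function(d) paste(d$patient_id, d$tumor_id, d$parameter, sep = ":")
  base_lut <- stats::setNames(base$median, key(base))
  day1$baseline <- base_lut[key(day1)]
  day1$delta <- day1$median - day1$baseline
  flags <- character(nrow(day1))
  labels <- character(nrow(day1))
  for (i in seq_len(nrow(day1))) {
    if (!is.finite(day1$delta[i])) { flags[i] <- NA; labels[i] <- NA; next }
    par <- day1$parameter[i]
    band <- rc_band(spec, par, day1$baseline[i],
                    tumor_key = paste(day1$patient_id[i], day1$tumor_id[i], sep = ":"))
    flags[i] <- if (day1$delta[i] < band[1]) "below"
                else if (day1$delta[i] > band[2]) "above" else "within"
    dirn <- spec$table$direction[spec$table$parameter == par]
    labels[i] <- if ((dirn == "decrease" && flags[i] == "below") ||
                     (dirn == "increase" && flags[i] == "above")) "P" else "N"
  }
  day1$flag <- flags
  day1$label <- labels
  day1
}

#' Sensitivity, specificity, balanced accuracy and McNemar test
#'
#' `sensitivity = (PP intersect P)/P`, `specificity = (PN intersect N)/N`,
#' `BA = (sensitivity + specificity)/2`. A zero denominator leaves the
#' component undefined (NA) and BA is the mean of the defined components,
#' with `single_class = TRUE`. The McNemar test is computed on the
#' discordant pairs of the paired (predicted vs. true) table:
#' continuity-corrected chi-square, or an exact binomial test when fewer
#' than 25 pairs are discordant.
#'
#' @param predicted predicted labels (`"P"`/`"N"`, `"PP"`/`"PN"` accepted)
#' @param truth true labels (`"P"`/`"N"`)
#' @return list: sensitivity, specificity, ba, mcnemar_p, n, single_class
#' @export
classification_metrics <- function(predicted, truth) {
  assert_that(length(predicted) == length(truth),
              "predicted and true labels differ in length")
  assert_that(length(truth) > 0, "empty label vectors")
  norm <- function(x) ifelse(x %in% c("P", "PP", "TRUE", "1"), "P", "N")
  p <- norm(as.character(predicted))
  t <- norm(as.character(truth))
  np <- sum(t == "P"); nn <- sum(t == "N")
  sens <- if (np > 0) sum(p == "P" & t == "P") / np else NA_real_
  spec <- if (nn > 0) sum(p == "N" & t == "N") / nn else NA_real_
  ba <- mean(c(sens, spec), na.rm = TRUE)
  b <- sum(p == "P" & t == "N")
  c_ <- sum(p == "N" & t == "P")
  mcnemar_p <- if (b + c_ == 0) 1
  else if (b + c_ < 25) stats::binom.test(b, b + c_, 0.5)$p.value
  else {
    x2 <- (abs(b - c_) - 1)^2 / (b + c_)
    stats::pchisq(x2, df = 1, lower.tail = FALSE)
  }
  list(sensitivity = sens, specificity = spec, ba = ba,
       mcnemar_p = mcnemar_p, n = length(t),
       single_class = np == 0 || nn == 0)
}

#' Baseline threshold maximizing balanced accuracy
#'
#' Exhaustive search over the midpoints of consecutive sorted distinct
#' baseline values (plus -Inf and +Inf): a tumor is predicted `P` when its
#' baseline satisfies `baseline > c` (direction `">"`) or `baseline < c`
#' (`"<"`). Ties in BA are broken toward the cutpoint with the larger
#' minimum distance to an observed value (class margin), then the smaller
#' cutpoint.
#'
#' @param baseline numeric baseline values
#' @param labels responder labels (`"P"`/`"N"`), both classes present
#' @param direction `">"` (high baseline predicts response) or `"<"`
#' @param parameter optional parameter name carried into the result
#' @return object of class `threshold_model`: parameter, direction,
#'   cutpoint, sensitivity, specificity, ba, mcnemar_p
#' @export
optimize_threshold <- function(baseline, labels, direction = c(">", "<"),
                               parameter = NA_character_) {
  direction <- match.arg(direction)
  keep <- is.finite(baseline) & !is.na(labels)
  baseline <- baseline[keep]; labels <- as.character(labels)[keep]
  assert_that(length(unique(labels)) == 2,
              "need both responder classes to optimize a threshold")
  sv <- sort(unique(baseline))
  cuts <- c(-Inf, if (length(sv) > 1) (sv[-1] + sv[-length(sv)]) / 2, Inf)
  best <- NULL
  for (cc in cuts) {
    pred <- if (direction == ">") ifelse(baseline > cc, "P", "N")
            else ifelse(baseline < cc, "P", "N")
    m <- classification_metrics(pred, labels)
    margin <- if (is.finite(cc)) min(abs(baseline - cc)) else Inf
    cand <- list(cut = cc, ba = m$ba, m = m, margin = margin)
    if (is.null(best) || cand$ba > best$ba + 1e-12 ||
        (abs(cand$ba - best$ba) <= 1e-12 &&
         (cand$margin > best$margin + 1e-12 ||
          (abs(cand$margin - best$margin) <= 1e-12 && cand$cut < best$cut))))
      best <- cand
  }
  structure(list(parameter = parameter, direction = direction,
                 cutpoint = best$cut,
                 sensitivity = best$m$sensitivity,
                 specificity = best$m$specificity,
                 ba = best$m$ba, mcnemar_p = best$m$mcnemar_p),
            class = "threshold_model")
}

#' @export
print.threshold_model <- function(x, ...) {
  cat(sprintf("<threshold_model %s: baseline %s %.4g -> P; BA = %.3f (sens %.3f, spec %.3f), McNemar p = %.3g>\n",
              x$parameter, x$direction, x$cutpoint, x$ba,
              x$sensitivity, x$specificity, x$mcnemar_p))
  invisible(x)
}

#' Association statistics of parameter changes
#'
#' Per parameter, an ordinary least-squares regression of the day-1 change
#' on the baseline value (slope, R-squared, F-test p-value), and pairwise
#' correlations among the parameter changes across tumors.
#'
#' @param labeled a labeled cohort table from [label_responders()] (one row
#'   per patient/tumor/parameter with `baseline` and `delta`)
#' @param method correlation method, `"pearson"` (default) or `"spearman"`
#' @return list: `regression` (data.frame parameter, slope, intercept, r2,
#'   p), `correlations` (data.frame param_a, param_b, estimate, p, n)
#' @export
association_stats <- function(labeled, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  pars <- unique(labeled$parameter)
  reg <- do.call(rbind, lapply(pars, function(par) {
    d <- labeled[labeled$parameter == par & is.finite(labeled$delta) &
                   is.finite(labeled$baseline), ]
    assert_that(nrow(d) >= 3, par, ": need >= 3 paired observations")
    fit <- stats::lm(delta ~ baseline, data = d)
    s <- summary(fit)
    pval <- stats::pf(s$fstatistic[1], s$fstatistic[2], s$fstatistic[3],
                      lower.tail = FALSE)
    data.frame(parameter = par, slope = stats::coef(fit)[2],
               intercept = stats::coef(fit)[1], r2 = s$r.squared,
               p = as.numeric(pval), n = nrow(d), row.names = NULL,
               stringsAsFactors = FALSE)
  }))
  wide <- stats::reshape(
    labeled[, c("patient_id", "tumor_id", "parameter", "delta")],
    idvar = c("patient_id", "tumor_id"), timevar = "parameter",
    direction = "wide")
  names(wide) <- sub("^delta\\.", "", names(wide))
  if (length(pars) < 2)
    return(list(regression = reg, correlations = NULL))
  combs <- utils::combn(as.character(pars), 2)
  cors <- do.call(rbind, lapply(seq_len(ncol(combs)), function(i) {
    a <- combs[1, i]; b <- combs[2, i]
    x <- wide[[a]]; y <- wide[[b]]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3) return(NULL)
    ct <- stats::cor.test(x[ok], y[ok], method = method, exact = FALSE)
    data.frame(param_a = a, param_b = b, estimate = unname(ct$estimate),
               p = ct$p.value, n = sum(ok), stringsAsFactors = FALSE)
  }))
  list(regression = reg, correlations = cors)
}

#' Intraclass correlation for inter-observer agreement
#'
#' Two-way random-effects model, absolute agreement, single measures
#' (ICC(2,1)), computed from the ANOVA mean squares of the subjects-by-
#' observers table. With a `visit` grouping, per-visit ICCs and the overall
#' ICC are returned.
#'
#' @param obs1,obs2 paired VOI medians from the two observers
#' @param visit optional visit factor for per-visit ICCs
#' @return with `visit` NULL, a single ICC value; otherwise a data.frame of
#'   per-visit ICCs plus an `"all"` row
#' @export
icc_interobserver <- function(obs1, obs2, visit = NULL) {
  assert_that(length(obs1) == length(obs2), "observer vectors differ in length")
  icc21 <- function(x, y) {
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    n <- length(x)
    assert_that(n >= 2, "need >= 2 pairs for an ICC")
    m <- cbind(x, y)
    k <- 2
    grand <- mean(m)
    msr <- k * stats::var(rowMeans(m))
    msc <- n * sum((colMeans(m) - grand)^2) / (k - 1)
    sse <- sum((m - outer(rowMeans(m), rep(1, k)) -
                  outer(rep(1, n), colMeans(m)) + grand)^2)
    mse <- sse / ((n - 1) * (k - 1))
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  }
  if (is.null(visit)) return(icc21(obs1, obs2))
  visits <- unique(visit)
  out <- data.frame(visit = c(as.character(visits), "all"),
                    icc = c(vapply(visits, function(v)
                      icc21(obs1[visit == v], obs2[visit == v]), 0),
                      icc21(obs1, obs2)),
                    stringsAsFactors = FALSE)
  out
}
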