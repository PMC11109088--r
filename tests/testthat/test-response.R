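# VOI response statistics: RC, labels, thresholds, associations, ICC

test_that("VOI median follows the even-count convention and skips NaN", {
  m <- parameter_map(array(c(1, 2, 3, NaN), c(4, 1, 1)))
  all4 <- array(TRUE, c(4, 1, 1))
  expect_equal(voi_medians(m, all4), 2)
  m2 <- parameter_map(array(c(1, 2, 3, 4), c(4, 1, 1)))
  expect_equal(voi_medians(m2, all4), 2.5)
  expect_error(voi_medians(m, array(FALSE, c(4, 1, 1))), "empty")
})

test_that("replicate RC follows 2.77 sqrt(sigma^2) with a pooled group RC", {
  expect_equal(repeatability_coefficient(1), 2.77)
  same <- data.frame(tumor = rep("a", 3), value = c(2, 2, 2))
  expect_equal(rc_from_replicates(same)$per_tumor$rc, 0)
  reps <- data.frame(tumor = rep(c("a", "b"), each = 2),
                     value = c(1, 3, 2, 2))
  rc <- rc_from_replicates(reps)
  expect_equal(rc$per_tumor$sigma2, c(var(c(1, 3)), 0))
  expect_equal(rc$per_tumor$rc[1], 2.77 * sqrt(2))
  # group RC pools the within-tumor variances (df-weighted)
  expect_equal(rc$group_rc, 2.77 * sqrt(mean(c(2, 0))))
  # Bland-Altman on the replicate pairs: diffs {-2, 0}
  expect_equal(rc$bland_altman$bias, -1)
  expect_equal(rc$bland_altman$loa_upper, -1 + 1.96 * sd(c(-2, 0)))
  expect_error(rc_from_replicates(data.frame(tumor = c("a", "b"),
                                             value = c(1, 2))),
               "no RC derivable")
})

test_that("the RC band covers ~95% of replicate differences", {
  set.seed(3)
  n <- 10000
  d <- rnorm(n, 0, 1) - rnorm(n, 0, 1)
  sigma2_hat <- mean(d^2) / 2
  rc <- repeatability_coefficient(sigma2_hat)
  expect_equal(mean(abs(d) <= rc), 0.95, tolerance = 0.011)
})

test_that("RC specification encodes absolute, relative and asymmetric bands", {
  spec <- build_rc_spec(adc_group_rc = 0.8e-3)
  expect_equal(qmripd:::rc_band(spec, "iauc", baseline = 10), c(-3.2, 3.2))
  expect_equal(qmripd:::rc_band(spec, "ktrans", baseline = 0.10),
               c(-0.045, 0.083))
  expect_equal(qmripd:::rc_band(spec, "t1", baseline = 5), c(-0.27, 0.27))
  expect_equal(qmripd:::rc_band(spec, "adc", baseline = 1e-3),
               c(-0.8e-3, 0.8e-3))
  # per-tumor ADC override
  spec2 <- build_rc_spec(0.8e-3, adc_rc_by_tumor = c("P01:1" = 2e-4))
  expect_equal(qmripd:::rc_band(spec2, "adc", 1e-3, tumor_key = "P01:1"),
               c(-2e-4, 2e-4))
  expect_error(build_rc_spec(0.8e-3, literature = rc_literature_defaults()[-1, ]),
               "no repeatability source")
})

mk_table <- function(parameter, baseline, day1) {
  rbind(data.frame(patient_id = "P01", tumor_id = 1, visit = "baseline",
                   parameter = parameter, median = baseline),
        data.frame(patient_id = "P01", tumor_id = 1, visit = "day1",
                   parameter = parameter, median = day1))
}

test_that("responder labels require significance in the expected direction", {
  spec <- build_rc_spec(adc_group_rc = 0.2e-3)
  # ADC decrease beyond -RC is a responder
  lab <- label_responders(mk_table("adc", 1.5e-3, 1.5e-3 - 1.1 * 0.2e-3), spec)
  expect_equal(lab$label, "P")
  expect_equal(lab$flag, "below")
  # significant in the wrong direction is a non-responder
  lab2 <- label_responders(mk_table("adc", 1.5e-3, 1.5e-3 + 1.1 * 0.2e-3), spec)
  expect_equal(lab2$label, "N")
  expect_equal(lab2$flag, "above")
  # ve increase of 0.08 exceeds the 0.076 band
  lab3 <- label_responders(mk_table("ve", 0.20, 0.28), spec)
  expect_equal(lab3$label, "P")
  expect_equal(lab3$delta, 0.08)
  expect_error(label_responders(mk_table("unknown", 1, 2), spec),
               "missing from RC spec")
})

test_that("relative-band labels are invariant to a common rescaling", {
  spec <- build_rc_spec(0.2e-3)
  for (c_scale in c(0.5, 1, 7)) {
    lab <- label_responders(mk_table("iauc", 10 * c_scale, 14 * c_scale), spec)
    expect_equal(lab$label, "P") # +40% > +32% at any scale
    lab2 <- label_responders(mk_table("iauc", 10 * c_scale, 12 * c_scale), spec)
    expect_equal(lab2$label, "N") # +20% within the band at any scale
  }
})

test_that("classification metrics match the counting definitions", {
  perfect <- classification_metrics(c("P", "N", "P"), c("P", "N", "P"))
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$ba, 1)
  m <- classification_metrics(c("PP", "PN", "PN", "PN"), c("P", "P", "N", "N"))
  expect_equal(m$sensitivity, 0.5)
  expect_equal(m$specificity, 1)
  expect_equal(m$ba, 0.75)
  # equal discordant counts give McNemar p = 1
  eq <- classification_metrics(c("P", "N", "P", "N"), c("N", "P", "P", "N"))
  expect_equal(eq$mcnemar_p, 1)
  # single observed class flags BA as partial
  sc <- classification_metrics(c("P", "P"), c("P", "P"))
  expect_true(sc$single_class)
  expect_true(is.na(sc$specificity))
  expect_equal(sc$ba, 1)
  expect_error(classification_metrics("P", c("P", "N")), "length")
})

test_that("threshold search maximizes BA with the documented tie-breaks", {
  tm <- optimize_threshold(c(1, 2, 3, 4), c("N", "N", "P", "P"), ">")
  expect_equal(tm$cutpoint, 2.5)
  expect_equal(tm$ba, 1)
  expect_equal(tm$sensitivity, 1)
  expect_equal(tm$specificity, 1)
  expect_error(optimize_threshold(1:3, c("P", "P", "P"), ">"), "both")
})

test_that("threshold search equals brute force on random instances", {
  set.seed(14)
  brute <- function(x, y, dirn) {
    cand <- c(-Inf, sort(unique(x)), Inf,
              (sort(unique(x))[-1] + rev(rev(sort(unique(x)))[-1])) / 2)
    max(vapply(cand, function(cc) {
      pred <- if (dirn == ">") ifelse(x > cc, "P", "N") else ifelse(x < cc, "P", "N")
      classification_metrics(pred, y)$ba
    }, 0))
  }
  for (i in 1:30) {
    n <- sample(4:50, 1)
    x <- round(rnorm(n), 2)
    y <- ifelse(runif(n) < 0.5, "P", "N")
    if (length(unique(y)) < 2) y[1:2] <- c("P", "N")
    dirn <- sample(c(">", "<"), 1)
    expect_equal(optimize_threshold(x, y, dirn)$ba, brute(x, y, dirn),
                 tolerance = 1e-12)
  }
})

test_that("random labels give chance-level BA at large n", {
  set.seed(9)
  n <- 4000
  x <- rnorm(n)
  y <- ifelse(runif(n) < 0.5, "P", "N")
  tm <- optimize_threshold(x, y, ">")
  expect_lt(tm$ba, 0.55)
  expect_gte(tm$ba, 0.5)
})

test_that("association statistics recover exact relationships", {
  d <- data.frame(patient_id = "P01", tumor_id = 1:6,
                  parameter = "adc", baseline = 1:6,
                  delta = -(1:6) * 0.3 + 2, label = "N")
  # exact linear data: summary.lm warns about the perfect fit, by design
  st <- suppressWarnings(association_stats(d))
  expect_equal(st$regression$r2, 1)
  expect_equal(st$regression$slope, -0.3)
  # y = x deltas across parameters correlate perfectly
  d2 <- rbind(transform(d, parameter = "adc"),
              transform(d, parameter = "t1"))
  st2 <- suppressWarnings(association_stats(d2))
  expect_equal(st2$correlations$estimate, 1)
  expect_error(association_stats(d[1:2, ]), ">= 3")
})

test_that("ICC(2,1) agrees with a direct ANOVA computation", {
  expect_equal(icc_interobserver(c(1, 2, 3, 4), c(1, 2, 3, 4)), 1)
  x <- c(9, 6, 8, 7); y <- c(10, 8, 9, 5)
  # independent oracle: two-way ANOVA mean squares via aov
  long <- data.frame(v = c(x, y),
                     subj = factor(rep(1:4, 2)),
                     rater = factor(rep(1:2, each = 4)))
  ms <- summary(aov(v ~ subj + rater, data = long))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  n <- 4; k <- 2
  icc_ref <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  expect_equal(icc_interobserver(x, y), icc_ref, tolerance = 1e-12)
  # a fixed offset reduces absolute-agreement ICC below 1
  expect_lt(icc_interobserver(c(1, 2, 3, 4), c(2, 3, 4, 5)), 1)
  # unrelated observers give near-zero ICC
  set.seed(2)
  expect_lt(abs(icc_interobserver(rnorm(300), rnorm(300))), 0.15)
  expect_error(icc_interobserver(1, 2), ">= 2")
  # per-visit output carries one row per visit plus the overall row
  v <- rep(c("baseline", "day1"), each = 4)
  out <- icc_interobserver(rep(x, 2), rep(y, 2), visit = v)
  expect_equal(out$visit, c("baseline", "day1", "all"))
  expect_equal(out$icc[1], icc_ref, tolerance = 1e-12)
})

test_that("null simulation flags ~5% of tumors per parameter", {
  set.seed(31)
  n <- 600
  sigma <- 0.1
  reps <- data.frame(tumor = rep(seq_len(n), each = 2),
                     value = 5 + rnorm(2 * n, 0, sigma))
  rc <- rc_from_replicates(reps)
  delta <- rnorm(n, 0, sigma * sqrt(2)) # day1 - baseline, no effect
  flagged <- abs(delta) > rc$group_rc
  expect_gt(mean(flagged), 0.02)
  expect_lt(mean(flagged), 0.09)
})
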