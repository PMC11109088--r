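# pixel-level responder labeling and the baseline decision-rule model

test_that("pixel RC pools per-pixel replicate variance, with group fallback", {
  expect_equal(pixel_rc(matrix(2, 10, 3))$rc, 0)
  miss <- pixel_rc(NULL)
  expect_equal(miss$rc, 1.4e-3)
  expect_equal(miss$source, "group")
  expect_error(pixel_rc(NULL, group_fallback = NULL), "no replicates")
  # pooled variance equals the brute-force mean of per-pixel variances
  set.seed(4)
  m <- matrix(rnorm(30), 10, 3)
  got <- pixel_rc(m)
  expect_equal(got$rc, 2.77 * sqrt(mean(apply(m, 1, var))), tolerance = 1e-12)
  expect_equal(got$source, "replicates")
})

test_that("group pixel RC uses equal pixel counts per patient", {
  set.seed(8)
  sigma <- 0.05
  per_patient <- lapply(c(200, 900, 400), function(n)
    matrix(rnorm(n * 3, 10, sigma), n, 3))
  rc <- group_pixel_rc(per_patient, seed = 2)
  expect_equal(rc, 2.77 * sigma, tolerance = 0.05)
  expect_identical(rc, group_pixel_rc(per_patient, seed = 2))
})

test_that("pixel labels follow the direction rule and combine with ANY", {
  spec <- build_rc_spec(0.2e-3)
  base <- list(t1 = c(1, 1, 1), vp = c(0.02, 0.02, 0.02))
  deltas <- list(t1 = c(-1.5 * 0.27, 0.1, 0), vp = c(0, 0, 0.009))
  lab <- label_pixels(base, deltas, spec)
  expect_equal(unname(lab$per_parameter[, "t1"]), c(TRUE, FALSE, FALSE))
  expect_equal(unname(lab$per_parameter[, "vp"]), c(FALSE, FALSE, TRUE))
  # pixel 1: T1 response; pixel 2: none; pixel 3: vp-only still counts
  expect_equal(lab$any, c(TRUE, FALSE, TRUE))
  expect_error(label_pixels(base, c(deltas, list(bogus = 1:3)), spec),
               "missing from RC spec")
  # pixel-wise ADC RC overrides the VOI-level band
  lab2 <- label_pixels(list(adc = 1.5e-3), list(adc = -1.0e-3), spec,
                       adc_rc = 1.4e-3)
  expect_false(lab2$any)
  lab3 <- label_pixels(list(adc = 1.5e-3), list(adc = -1.5e-3), spec,
                       adc_rc = 1.4e-3)
  expect_true(lab3$any)
})

test_that("training draws are patient-balanced and class-balanced", {
  ds <- planted_ve_dataset(n_patients = 4, px_per_tumor = 100, seed = 2)
  model <- train_threshold_tree(ds, n_repeats = 3, seed = 1)
  # 85% of the smallest tumor (100 pixels) per patient
  expect_equal(model$n_train_per_patient, 85L)
  set.seed(10)
  for (rep_i in 1:5) {
    rows <- qmripd:::balanced_draw(ds, 85, extra_pos_first = rep_i %% 2 == 1)
    counts <- table(ds$patient_id[rows])
    expect_true(all(counts == 85))
    lab <- ds$label[rows]
    expect_lte(abs(sum(lab) - sum(!lab)), 1)
  }
})

test_that("a separable feature is learned with perfect validation BA", {
  ds <- planted_ve_dataset(n_patients = 4, px_per_tumor = 150, flip = 0,
                           seed = 5)
  model <- train_threshold_tree(ds, max_depth = 1, n_repeats = 3, seed = 1)
  expect_equal(model$rules$feature[1], "ve")
  expect_equal(model$mean_validation_ba, 1, tolerance = 1e-9)
  expect_identical(model$rules,
                   train_threshold_tree(ds, max_depth = 1, n_repeats = 3,
                                        seed = 1)$rules)
})

test_that("the hand-written CART agrees with rpart on a reference problem", {
  skip_if_not_installed("rpart")
  ds <- planted_ve_dataset(n_patients = 2, px_per_tumor = 400, flip = 0.05,
                           seed = 3)
  feats <- c("adc", "t1", "iauc", "ktrans", "ve", "vp")
  ours <- fit_cart(ds[, feats], ds$label, max_depth = 1, min_leaf = 5)
  rp <- rpart::rpart(factor(label) ~ ., data = ds[, c(feats, "label")],
                     method = "class",
                     control = rpart::rpart.control(maxdepth = 1, cp = 0,
                                                    minbucket = 5))
  split_var <- rownames(rp$splits)[1]
  expect_equal(tree_rules(ours)$feature[1], split_var)
  expect_equal(tree_rules(ours)$cut[1], rp$splits[1, "index"],
               tolerance = 0.02)
})

test_that("planted ve rule is recovered near the true cutpoint", {
  feats <- character(0); cuts <- numeric(0)
  for (seed in 1:5) {
    ds <- planted_ve_dataset(n_patients = 6, px_per_tumor = 120,
                             flip = 0.05, seed = seed)
    model <- train_threshold_tree(ds, max_depth = 1, n_repeats = 5,
                                  seed = seed)
    if (nrow(model$rules)) {
      feats <- c(feats, model$rules$feature[1])
      cuts <- c(cuts, model$rules$cut[1])
    }
  }
  expect_equal(names(which.max(table(feats))), "ve")
  expect_lt(abs(median(cuts[feats == "ve"]) - 0.39), 0.05)
})

test_that("leave-one-patient-out reports one BA per patient", {
  ds <- planted_ve_dataset(n_patients = 6, px_per_tumor = 80, flip = 0,
                           seed = 7)
  ev <- lopo_evaluate(ds, max_depth = 1, n_repeats = 2, seed = 1)
  expect_equal(nrow(ev$per_patient), 6)
  expect_setequal(ev$per_patient$patient_id, unique(ds$patient_id))
  expect_equal(ev$mean_ba, mean(ev$per_patient$ba))
  # identical planted rule in all patients, no label noise: perfect transfer
  expect_equal(ev$mean_ba, 1, tolerance = 1e-9)
})

test_that("a single-class held-out patient reports the defined component", {
  ds <- planted_ve_dataset(n_patients = 3, px_per_tumor = 60, flip = 0,
                           seed = 11)
  ds$label[ds$patient_id == "P03"] <- TRUE # all p-responders
  ev <- lopo_evaluate(ds, max_depth = 1, n_repeats = 2, seed = 1)
  row <- ev$per_patient[ev$per_patient$patient_id == "P03", ]
  expect_true(row$single_class)
  expect_true(is.finite(row$ba))
})
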