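# Pixel-level responder labeling and the baseline-parameter decision-rule
# model with patient-balanced sampling and leave-one-patient-out evaluation.

PIXEL_FEATURES <- c("adc", "t1", "iauc", "ktrans", "ve", "vp")

#' Pixel-wise ADC repeatability coefficient for one tumor
#'
#' `RC = 2.77 sqrt(sigma^2)` where `sigma^2` is the per-pixel replicate
#' variance pooled (averaged) over the tumor's pixels. Without replicates
#' the configured group fallback is returned.
#'
#' @param replicate_values matrix `[n_pixels, n_replicates]` of co-registered
#'   replicate ADC values, or NULL when no replicates exist
#' @param group_fallback group pixel-wise RC used when replicates are
#'   missing (default 1.4e-3 mm^2/s)
#' @return list: `rc`, `source` (`"replicates"` or `"group"`)
#' @export
pixel_rc <- function(replicate_values, group_fallback = 1.4e-3) {
  if (is.null(replicate_values) || ncol(replicate_values) < 2) {
    if (is.null(group_fallback))
      stop_qmri("no replicates and no group fallback RC configured")
    return(list(rc = group_fallback, source = "group"))
  }
  sigma2 <- mean(apply(replicate_values, 1, stats::var))
  list(rc = repeatability_coefficient(sigma2), source = "replicates")
}

#' Group pixel-wise repeatability coefficient
#'
#' Pools the per-pixel replicate variance over all patients using an equal
#' number of pixels per patient (so large tumors do not dominate), then
#' applies `RC = 2.77 sqrt(sigma^2)`.
#'
#' @param per_patient list of matrices `[n_pixels, n_replicates]`, one per
#'   patient (patients without >= 2 replicates are dropped)
#' @param n_per_patient pixels sampled per patient (default: the smallest
#'   patient pixel count)
#' @param seed sampling seed
#' @return the group RC
#' @export
group_pixel_rc <- function(per_patient, n_per_patient = NULL, seed = 1L) {
  per_patient <- Filter(function(m) !is.null(m) && ncol(m) >= 2, per_patient)
  assert_that(length(per_patient) > 0, "no patient has pixel replicates")
  n_per_patient <- n_per_patient %||% min(vapply(per_patient, nrow, 0L))
  vars <- with_seed(seed, unlist(lapply(per_patient, function(m) {
    rows <- sample(seq_len(nrow(m)), n_per_patient,
                   replace = n_per_patient > nrow(m))
    apply(m[rows, , drop = FALSE], 1, stats::var)
  })))
  repeatability_coefficient(mean(vars))
}

#' Label pixels as p-responders
#'
#' A pixel is a p-responder in a parameter when its day-1 change lies below
#' -RC (ADC, T1) or above +RC (iAUC, k-trans, ve, vp); the combined label is
#' a response in any parameter. ADC uses the pixel-wise RC (`adc_rc`); the
#' other parameters use the same bands as the VOI analysis.
#'
#' @param baselines named list of per-pixel baseline vectors (parameters
#'   among `adc, t1, iauc, ktrans, ve, vp`)
#' @param deltas named list of per-pixel day-1 change vectors (same names
#'   and lengths)
#' @param spec an [build_rc_spec()] object
#' @param adc_rc pixel-wise ADC RC overriding the spec's VOI-level value
#' @return list: `per_parameter` (logical matrix, one column per parameter),
#'   `any` (combined p-responder label)
#' @export
label_pixels <- function(baselines, deltas, spec, adc_rc = NULL) {
  stopifnot(inherits(spec, "rc_spec"))
  pars <- names(deltas)
  missing <- setdiff(pars, spec$table$parameter)
  if (length(missing))
    stop_qmri("parameter missing from RC spec: ", paste(missing, collapse = ", "))
  assert_that(setequal(names(baselines), pars),
              "baselines and deltas must cover the same parameters")
  n <- length(deltas[[1]])
  out <- matrix(FALSE, n, length(pars), dimnames = list(NULL, pars))
  for (par in pars) {
    assert_that(length(deltas[[par]]) == n && length(baselines[[par]]) == n,
                "pixel vectors differ in length for ", par)
    row <- spec$table[spec$table$parameter == par, ]
    if (par == "adc" && !is.null(adc_rc)) {
      lo <- rep(-adc_rc, n); hi <- rep(adc_rc, n)
    } else if (row$band_type == "absolute") {
      lo <- rep(-row$rc_abs, n); hi <- rep(row$rc_abs, n)
    } else {
      lo <- row$lower_pct / 100 * baselines[[par]]
      hi <- row$upper_pct / 100 * baselines[[par]]
    }
    out[, par] <- if (row$direction == "decrease") deltas[[par]] < lo
                  else deltas[[par]] > hi
  }
  list(per_parameter = out, any = rowSums(out, na.rm = TRUE) > 0)
}

#' Assemble a pixel dataset
#'
#' One record per tumor pixel with the six baseline parameter values, the
#' day-1 changes, and the combined p-responder label.
#'
#' @param patient_id,tumor_id identifiers (recycled)
#' @param baselines,deltas named lists of per-pixel vectors (see
#'   [label_pixels()])
#' @param label logical p-responder label per pixel (e.g. `label_pixels()$any`)
#' @return data.frame with columns patient_id, tumor_id, the six baseline
#'   features, `delta_*` columns and `label`
#' @export
pixel_dataset <- function(patient_id, tumor_id, baselines, deltas, label) {
  n <- length(label)
  d <- data.frame(patient_id = rep_len(patient_id, n),
                  tumor_id = rep_len(tumor_id, n),
                  stringsAsFactors = FALSE)
  for (par in names(baselines)) d[[par]] <- baselines[[par]]
  for (par in names(deltas)) d[[paste0("delta_", par)]] <- deltas[[par]]
  d$label <- as.logical(label)
  d
}

# per-patient class-balanced draw of n_train pixel row indices
balanced_draw <- function(dataset, n_train, extra_pos_first = TRUE) {
  rows <- integer(0)
  pats <- unique(dataset$patient_id)
  extra_pos <- extra_pos_first
  for (p in pats) {
    rp <- which(dataset$patient_id == p & dataset$label)
    rn <- which(dataset$patient_id == p & !dataset$label)
    n_half <- n_train %/% 2
    n_pos <- n_half + as.integer(n_train %% 2 == 1 && extra_pos)
    n_neg <- n_train - n_pos
    if (n_train %% 2 == 1) extra_pos <- !extra_pos
    take <- function(idx, k) {
      if (!length(idx)) return(integer(0))
      idx[sample.int(length(idx), k, replace = k > length(idx))]
    }
    got_p <- if (length(rp)) take(rp, n_pos) else integer(0)
    got_n <- if (length(rn)) take(rn, n_neg) else integer(0)
    deficit <- n_train - length(got_p) - length(got_n)
    if (deficit > 0) { # a class absent in this patient: fill from the other
      pool <- if (length(rp)) rp else rn
      got_n <- c(got_n, take(pool, deficit))
    }
    rows <- c(rows, got_p, got_n)
  }
  rows
}

#' Train the pixel-wise baseline decision-rule model
#'
#' Repeated randomized patient-balanced draws: per repeat, every patient
#' contributes the same number of training pixels — 85% of the pixel count
#' of the smallest tumor in the dataset — drawn class-balanced
#' (p-responder vs p-non-responder); a depth-limited CART tree is fit on
#' the six baseline features, balanced accuracy is evaluated per patient on
#' that patient's held-out pixels, and the model with the highest mean
#' validation BA across repeats is returned.
#'
#' @param dataset a [pixel_dataset()] with >= 2 patients and both classes
#' @param max_depth tree depth cap (default 2)
#' @param n_repeats randomized sampling repeats (default 20)
#' @param seed RNG seed
#' @param train_frac fraction of the smallest tumor's pixels drawn per
#'   patient (default 0.85)
#' @param min_leaf minimum pixels per leaf
#' @param max_redraws redraw attempts when a draw is single-class
#' @return object of class `pixel_tree_model`: `tree`, `rules`,
#'   `training_ba`, `validation_ba` (per patient, best repeat),
#'   `mean_validation_ba`, `n_train_per_patient`
#' @export
train_threshold_tree <- function(dataset, max_depth = 2L, n_repeats = 20L,
                                 seed = 1L, train_frac = 0.85, min_leaf = 5L,
                                 max_redraws = 20L) {
  feats <- intersect(PIXEL_FEATURES, names(dataset))
  assert_that(length(feats) >= 1, "dataset has no baseline feature columns")
  assert_that(length(unique(dataset$patient_id)) >= 2, "need >= 2 patients")
  assert_that(any(dataset$label) && any(!dataset$label),
              "need both pixel classes in the dataset")
  tumor_sizes <- table(paste(dataset$patient_id, dataset$tumor_id))
  n_train <- max(2L, floor(train_frac * min(tumor_sizes)))
  best <- NULL
  with_seed(seed, {
    for (rep_i in seq_len(n_repeats)) {
      rows <- NULL
      for (attempt in seq_len(max_redraws)) {
        cand <- balanced_draw(dataset, n_train, extra_pos_first = rep_i %% 2 == 1)
        if (length(unique(dataset$label[cand])) == 2) { rows <- cand; break }
      }
      if (is.null(rows))
        stop_qmri("training draw single-class after ", max_redraws, " attempts")
      tr <- dataset[rows, ]
      tree <- fit_cart(tr[, feats, drop = FALSE], tr$label,
                       max_depth = max_depth, min_leaf = min_leaf)
      train_ba <- classification_metrics(predict(tree, tr[, feats, drop = FALSE]),
                                         tr$label)$ba
      hold <- dataset[-unique(rows), , drop = FALSE]
      vba <- vapply(unique(hold$patient_id), function(p) {
        h <- hold[hold$patient_id == p, , drop = FALSE]
        if (!nrow(h)) return(NA_real_)
        classification_metrics(predict(tree, h[, feats, drop = FALSE]), h$label)$ba
      }, 0)
      mvb <- mean(vba, na.rm = TRUE)
      if (is.null(best) || mvb > best$mean_validation_ba) {
        best <- list(tree = tree, rules = tree_rules(tree),
                     training_ba = train_ba, validation_ba = vba,
                     mean_validation_ba = mvb,
                     n_train_per_patient = n_train, repeat_index = rep_i)
      }
    }
  })
  structure(best, class = "pixel_tree_model")
}

#' @export
print.pixel_tree_model <- function(x, ...) {
  cat(sprintf("<pixel_tree_model: %d rule(s), train BA %.3f, mean validation BA %.3f, %d px/patient>\n",
              nrow(x$rules), x$training_ba, x$mean_validation_ba,
              x$n_train_per_patient))
  if (nrow(x$rules)) print(x$rules)
  invisible(x)
}

#' Leave-one-patient-out evaluation of the pixel-wise model
#'
#' For each patient, a model is trained on all other patients with the same
#' patient-balanced sampling protocol, then evaluated on every pixel of the
#' held-out patient. A held-out patient with a single class reports the
#' defined component only (flagged). Patients without pixels are skipped
#' with a warning.
#'
#' @param dataset a [pixel_dataset()]
#' @param ... passed to [train_threshold_tree()] (per held-out fold)
#' @return list: `per_patient` (data.frame patient_id, ba, n,
#'   single_class), `mean_ba`
#' @export
lopo_evaluate <- function(dataset, ...) {
  pats <- unique(dataset$patient_id)
  assert_that(length(pats) >= 2, "need >= 2 patients for leave-one-patient-out")
  feats <- intersect(PIXEL_FEATURES, names(dataset))
  out <- list()
  for (p in pats) {
    hold <- dataset[dataset$patient_id == p, , drop = FALSE]
    if (!nrow(hold)) {
      warning("patient ", p, " has no pixels; skipped", call. = FALSE)
      next
    }
    model <- train_threshold_tree(dataset[dataset$patient_id != p, , drop = FALSE], ...)
    m <- classification_metrics(predict(model$tree, hold[, feats, drop = FALSE]),
                                hold$label)
    out[[p]] <- data.frame(patient_id = p, ba = m$ba, n = m$n,
                           single_class = m$single_class,
                           stringsAsFactors = FALSE)
  }
  per_patient <- do.call(rbind, out)
  list(per_patient = per_patient, mean_ba = mean(per_patient$ba))
}
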