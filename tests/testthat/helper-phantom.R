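# shared fixture builders (everything generated in code at test time)

tiny_config <- function(n_patients = 1, ...) {
  phantom_config(n_patients = n_patients, dim = c(32, 32, 6),
                 tumor_radius_vox = c(4, 6), ...)
}

tiny_scene <- function(seed = 3, effects = null_effect_model(), visit = 1) {
  co <- generate_ground_truth(tiny_config(), effects, seed = seed)
  co$patients[[1]]$scenes[[visit]]
}

# constant unit plasma curve from t = 0 (step input for closed-form checks)
step_aif <- function(times) aif(times, rep(1, length(times)))

# pixel dataset with a planted "ve < cut -> p-responder" rule + label noise
planted_ve_dataset <- function(n_patients = 6, px_per_tumor = 120, cut = 0.39,
                               flip = 0.05, seed = 1) {
  withr::with_seed(seed, {
    ds <- lapply(seq_len(n_patients), function(p) {
      n <- px_per_tumor
      base <- list(adc = runif(n, 0.9e-3, 2e-3), t1 = runif(n, 0.8, 1.8),
                   iauc = runif(n, 5, 40), ktrans = runif(n, 0.02, 0.3),
                   ve = runif(n, 0.1, 0.7), vp = runif(n, 0.005, 0.06))
      lab <- base$ve < cut
      lab <- xor(lab, runif(n) < flip)
      deltas <- lapply(base, function(x) rep(0, n))
      pixel_dataset(sprintf("P%02d", p), 1L, base, deltas, lab)
    })
    do.call(rbind, ds)
  })
}
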