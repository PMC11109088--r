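#' Spoiled gradient-echo (SPGR) steady-state signal
#'
#' `S(alpha) = M0 * sin(alpha) * (1 - E1) / (1 - cos(alpha) * E1)` with
#' `E1 = exp(-TR / T1)`. Used as the forward model for variable-flip-angle
#' T1 mapping and for dynamic series simulation. Inputs are recycled.
#'
#' @param m0 equilibrium signal (arbitrary units)
#' @param t1_s longitudinal relaxation time in seconds
#' @param fa_deg flip angle in degrees
#' @param tr_ms repetition time in milliseconds
#' @return signal, same shape as the broadcast inputs
#' @export
spgr_signal <- function(m0, t1_s, fa_deg, tr_ms) {
  assert_that(all(tr_ms > 0), "TR must be positive")
  a <- deg2rad(fa_deg)
  e1 <- exp(-(tr_ms / 1000) / t1_s)
  m0 * sin(a) * (1 - e1) / (1 - cos(a) * e1)
}

# invert SPGR for E1 given signal and known M0; returns E1 (may fall outside
# (0,1) for inconsistent inputs -- callers must mask)
spgr_invert_e1 <- function(signal, m0, fa_deg) {
  a <- deg2rad(fa_deg)
  (m0 * sin(a) - signal) / (m0 * sin(a) - signal * cos(a))
}
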