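---
title: "Quantitative MRI pharmacodynamic response: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative MRI pharmacodynamic response: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qmripd)
```

## What the package computes

`qmripd` analyzes multi-visit quantitative MRI of solid tumors under a
stroma-modifying therapy. From each imaging session it derives six
parameters per voxel and per tumor volume of interest (VOI):

* **ADC** (mm²/s) from diffusion-weighted MRI, via the mono-exponential
  model $S(b) = S_0 e^{-b \cdot \mathrm{ADC}}$ at b = 0 and 450 s/mm²;
* **T1** (s) from a variable-flip-angle (VFA) spoiled gradient-echo series,
  via the SPGR steady-state equation
  $S(\alpha) = M_0 \sin\alpha \, (1 - E_1)/(1 - \cos\alpha \, E_1)$ with
  $E_1 = e^{-TR/T_1}$;
* **gadolinium concentration** from the dynamic (DCE) series,
  $C(t) = (1/T_1(t) - 1/T_1(0))/r_1$, with $T_1(t)$ obtained by inverting
  the SPGR equation frame by frame;
* **iAUC** (mM·s), the trapezoidal area under $C(t)$ over 90 s from the
  injection frame;
* **k^trans^ (min⁻¹), v~e~, v~p~** from the extended Tofts model
  $C_t(t) = v_p C_p(t) + k^{trans}\!\int_0^t C_p(\tau)
  e^{-(k^{trans}/v_e)(t-\tau)} d\tau$, with the arterial input function
  $C_p$ measured from an artery region.

Day-1 changes of the VOI medians are classified against repeatability
coefficients (RC = 2.77 σ, the QIBA convention under which 95% of repeated
measurements fall within ±RC): a tumor is a pharmacodynamic responder (P)
when its change is significant *in the expected direction* — a decrease for
ADC and T1, an increase for iAUC, k^trans^, v~e~ and v~p~ — and a
non-responder (N) otherwise. Baseline thresholds that predict response are
found by exhaustively maximizing balanced accuracy
(BA = (sensitivity + specificity)/2), and a pixel-level analysis trains a
depth-limited decision tree on the six baseline values with patient-balanced
sampling and leave-one-patient-out validation.

Because the clinical images that motivated this pipeline are not public,
the package ships a digital phantom generator that produces multi-visit
cohorts with known ground truth, so every stage can be verified end to end.

## The digital phantom and what it does (and does not) emulate

`phantom_config()` builds per-patient volumes (default 64×64×8 voxels at
1.5×1.5×8 mm) containing a soft-tissue body, a tubular artery and
ellipsoidal tumors. Tumor parameters are drawn per tumor from configurable
ranges (defaults: ADC 0.9–2.0×10⁻³ mm²/s, T1 1.0–1.8 s, k^trans^
0.05–0.25 min⁻¹, v~e~ 0.15–0.55, v~p~ 0.01–0.06 — values typical of
metastatic solid tumors at 1.5 T) with 8% voxel-level heterogeneity.
Scene invariants are enforced: $v_e + v_p \le 1$ everywhere, artery voxels
carry $v_p = 1, v_e = 0$, and the artery region is painted with the
analytic input function so AIF extraction is testable.

`treatment_effect_model()` applies programmed day-1 changes to the
ground-truth maps of responder tumors (not to the signals), so responder
labels have an unambiguous truth. The default effects encode the
pharmacodynamic signature of stromal hyaluronic-acid depletion — ADC and T1
decrease, the perfusion/permeability parameters increase — with magnitudes
equal to **twice** the repeatability bands used in classification
(ADC −0.30×10⁻³ mm²/s, T1 −0.54 s, k^trans^ ×2.66, v~e~ +0.152,
v~p~ +0.0124), i.e. changes a calibrated repeatability analysis should
detect. Later visits retain 30% of the effect, emulating drift back toward
baseline. The iAUC truth is *derived*: it is the 90-s integral of the
noiseless forward model of the true PK maps, so its responder flag follows
from the programmed PK changes.

The simulated AIF is a bolus-rise times biexponential-decay curve
$C_p(t') = (1-e^{-t'/8\,\mathrm{s}})(4 e^{-t'/80\,\mathrm{s}} +
1 \cdot e^{-t'/600\,\mathrm{s}})$ mM — the usual first-pass shape with fast
and slow washout. Noise is Rician (magnitude MRI), applied to the signals;
a Gaussian family exists for analytic tests.

**SNR convention.** The noise level is `reference signal / sigma`. With
TR ≈ 3 ms the SPGR signal is about 1% of the equilibrium signal M0, so an
M0-referenced sigma would be physically meaningless; when no explicit
reference is given, sigma is resolved per series as the median positive
intensity divided by the SNR — i.e. SNR is quoted relative to the
intensities the scanner actually records. Defaults: 50 for DWI and DCE,
150 for the VFA series. The higher VFA figure is deliberate: the original
analysis used a spatially regularized T1 estimator (out of scope here,
replaced by optional Gaussian pre-smoothing), and the unregularized
per-voxel VFA fit needs roughly that effective SNR to operate in its
validity regime. The phantom therefore represents the data *after* the
averaging such an estimator effectively performs.

Not emulated: geometric distortion, motion, inter-visit mis-registration
(phantom visits are voxel-aligned by construction), partial-volume artery
voxels, and B1 inhomogeneity (a flip-angle scale map hook exists in
`fit_t1_vfa()` for externally supplied corrections). Passing tests on the
phantom therefore demonstrate the correctness of the estimators and the
classification logic, not robustness to registration or field artifacts.

## Numerical choices

* **ADC.** Exactly two b-values use the closed form
  $\mathrm{ADC} = \ln(S_1/S_2)/(b_2-b_1)$; more use log-linear least
  squares. Non-positive signals invalidate a voxel (the log is undefined;
  clamping would bias ADC). A missing b = 0 volume is a hard error naming
  the series, and b-values deviating from the configured protocol error or
  warn depending on strictness — deviating series are excluded, not
  adapted to.
* **T1.** The linearized form ($S/\sin\alpha$ on $S/\tan\alpha$, slope
  $E_1$) initializes a bounded per-voxel refinement that is kept only when
  it does not increase the residual. Solutions outside [0.05, 10] s — and
  apparent $E_1$ outside (0, 1), the noise tails of the linearized slope —
  are clipped to the bounds and flagged rather than dropped: dropping them
  deletes one tail of the estimator distribution and biases VOI medians by
  >10% at realistic SNR. The fit is invariant to a global intensity scale,
  and `estimate_intensity_scales()` recovers per-image scale factors (unit
  first image) by alternating a provisional fit with a median data/prediction
  ratio per image.
* **Concentration.** M0 is normalized per voxel from the mean pre-injection
  signal and the pre-contrast T1. Negative concentrations are clipped to
  zero (noise below baseline is unphysical and destabilizes the
  convolution fit); frames before the injection carry C = 0 by
  construction.
* **AIF.** `extract_aif()` averages the top-k artery curves by peak
  (k = 10 by default; partial-volume voxels have damped peaks in real
  data). The pipeline itself averages **all** artery voxels (phantoms have
  no partial volume) and converts the artery with the literature blood T1
  (default 1.4 s at 1.5 T) rather than the fitted map: a fitted blood T1
  propagates its noise into the AIF, and peak-ranked selection then
  systematically picks noise-inflated curves (≈1.9× peak inflation in our
  testing), which halves every downstream PK parameter. Hematocrit
  correction of the artery curve is off by default (optional factor
  $1/(1-\mathrm{Hct})$).
* **Extended Tofts fit.** The convolution uses an exponential-kernel
  recursion that is exact for a piecewise-linear $C_p$ (stable at the 8-s
  frame spacing). Fitting is variable projection over the rate constant
  $k_{ep} = k^{trans}/v_e$: at fixed $k_{ep}$ the model is linear in
  $(k^{trans}, v_p)$ and solved in closed form with non-negativity clamps;
  a 40-point logarithmic $k_{ep}$ grid (0.01–20 min⁻¹) is scanned and the
  per-voxel optimum refined by bracketed 1-D minimization. The returned
  residual is the minimum over everything evaluated, so it never exceeds
  any initialization. k^trans^ is reported per minute; time grids are in
  seconds with explicit conversion. Zero curves are flagged degenerate
  (k^trans^ = 0, v~p~ = 0).
* **iAUC** is anchored at the injection frame (not per-voxel bolus
  arrival), integrating 90 s with linear interpolation at the window edge.
* **Injection detection** takes the first frame whose mean signal (over
  the artery mask when available) exceeds the early-frame mean by
  max(5 SD, 5%); an override short-circuits detection.

## Repeatability and response classification

Per tumor, σ² is the variance of the replicate ADC VOI medians and
RC = 2.77 σ. The **group** RC applies the same formula to the pooled,
degrees-of-freedom-weighted within-tumor variance. Pooling (rather than a
median of per-tumor RCs) matters: with 2–3 replicates the median of
χ-distributed σ̂ estimates sits 25–35% below σ, and the resulting band
would flag far more than 5% of null tumors. The per-tumor RC is used for a
tumor's own ADC band when replicates exist, the group RC otherwise.
Parameters without replicate scans use literature bands: ±0.27 s for T1,
±32% for iAUC, −45%/+83% (asymmetric, relative) for k^trans^, ±0.076 for
v~e~, ±0.0062 for v~p~.

The threshold search scans midpoints of consecutive sorted distinct
baseline values (plus ±∞); ties in BA break toward the cutpoint with the
larger margin to the nearest observation, then the smaller cutpoint. The
McNemar test of a threshold model uses the discordant pairs of the paired
predicted-vs-true table — continuity-corrected χ² with an exact binomial
test below 25 discordant pairs (the paper-level analysis names the test
without its construction; this is our documented choice). Even-count
medians are the mean of the central pair; correlations among parameter
changes default to Pearson. Inter-observer agreement uses ICC(2,1) —
two-way random effects, absolute agreement, single measures — computed
from the ANOVA mean squares.

## Pixel-wise model

Pixel labels follow the same band rule per parameter (ADC uses the
pixel-wise RC: 2.77 times the root of the per-pixel replicate variance
pooled within tumor, group fallback 1.4×10⁻³ mm²/s computed with equal
pixel counts per patient), and the combined label is a response in *any*
parameter. Training draws are patient-balanced — every patient contributes
⌊0.85 × (pixels of the globally smallest tumor)⌋ pixels, class-balanced
within the draw (|responders − non-responders| ≤ 1) — and a CART-style
Gini tree with depth cap 2 (default; the published optimum for this
problem is a depth-1 rule) is fit on the six baseline features. The model
maximizing mean held-out BA across randomized repeats (default 20) is
kept; `lopo_evaluate()` retrains per held-out patient and reports
per-patient and mean BA. Tree depth, split criterion and repeat count are
not specified by the source analysis (it used an external toolkit); the
defaults above are this package's own.

## Problem sizes and verification

The test suite verifies: exact closed forms (two-point ADC, concentration
conversion, constant/ramp iAUC, the step-AIF Tofts solution
$C_t = v_e(1 - e^{-k^{trans} t / v_e})$) to 10⁻⁶; noiseless round trips on
a 64×64×8 phantom (ADC and PK within 1%, T1 within 0.1%); 95% RC-band
coverage on 10⁴ simulated replicate pairs; ~5% null flag rate on 500
tumors; equivalence of the threshold search with exhaustive enumeration on
100 random instances; recovery of a planted v~e~ < 0.39 pixel rule within
±0.05 over 20 seeds; and an end-to-end run of the bundled 6-patient cohort
in which programmed responder labels are recovered with pooled BA ≥ 0.9
when effects are twice the applicable RC. These sizes keep the whole suite
at desk scale (minutes on one CPU) while leaving each statistical check
adequately powered.

## Known limitations

* The VFA T1 estimator is the unregularized per-voxel fit; at tumor-tissue
  SNR below ≈100 its per-voxel error grows quickly, and the optional
  Gaussian pre-smoothing trades that noise against boundary mixing with
  surrounding tissue. The spatially regularized estimator the original
  analysis cites is intentionally not reproduced.
* The AIF is noise-free in shape only at the phantom's artery; measured
  AIFs inherit conversion noise, and top-k peak selection is biased upward
  under noise — prefer averaging all artery voxels when partial volume is
  not a concern.
* Tumors are ellipsoids with mild lognormal-like heterogeneity; real
  tumors are more structured, so pixel-level BA figures on phantoms should
  be read as upper bounds.
* No registration, motion, B0/B1, or partial-volume effects are simulated.
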