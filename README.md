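# qmripd

Quantitative MRI analysis of tumor pharmacodynamic response to
stroma-modifying therapy, with a digital phantom cohort for end-to-end
verification.

Clinical trials of agents that remodel the tumor stroma (such as
hyaluronidase) monitor early drug effect with quantitative MRI: the
apparent diffusion coefficient (ADC) and T1 fall within a day of dosing as
extracellular water is released, while perfusion and permeability measures
rise. `qmripd` implements the full analysis chain used to quantify and
classify such responses, for imaging scientists who need a tested,
reproducible reference pipeline:

* **ADC mapping** — mono-exponential fit `S(b) = S0 exp(-b ADC)` of
  diffusion-weighted series (b = 0/450 s/mm²) with replicate averaging;
* **T1 mapping** — variable-flip-angle SPGR fit
  `S(a) = M0 sin a (1 - E1)/(1 - cos a E1)`, `E1 = exp(-TR/T1)`, with
  inter-image intensity-scale estimation and reference-T1 fallback;
* **DCE quantification** — gadolinium concentration
  `C = (1/T1(t) - 1/T1(0))/r1`, arterial input function extraction, 90-s
  iAUC, and the extended Tofts model
  `Ct = vp Cp + ktrans (Cp * exp(-ktrans t/ve))` fit by variable
  projection;
* **Response classification** — QIBA repeatability coefficients
  (`RC = 2.77 sqrt(sigma^2)`; 95% of replicate differences fall within
  ±RC), pharmacodynamic responder labels (decrease beyond −RC for ADC/T1,
  increase beyond +RC for iAUC/ktrans/ve/vp), baseline thresholds that
  maximize balanced accuracy `BA = (sensitivity + specificity)/2`,
  regression/correlation summaries and inter-observer ICC;
* **Pixel-wise modeling** — p-responder pixel labels, patient-balanced
  class-balanced sampling (85% of the smallest tumor's pixels per
  patient), a depth-limited decision tree on the six baseline parameters,
  and leave-one-patient-out validation;
* **Digital phantoms** — multi-visit, multi-patient ground-truth cohorts
  with programmed treatment effects and Rician noise, so every stage above
  is testable without clinical data.

## Worked example

Simulate a six-patient cohort with day-1 effects equal to twice each
parameter's repeatability band, run the whole pipeline, and check how well
the programmed responder labels are recovered:

```r
library(qmripd)

cfg <- study_config(seed = 7)         # 6 patients, 64x64x8, 2 visits
bundle <- run_pipeline(cfg)

bundle$rc$group_rc
#> [1] 1.300634e-05            # pooled replicate ADC RC, mm^2/s

bundle$truth_evaluation$pooled$ba
#> [1] 1                       # programmed responders recovered exactly

bundle$thresholds$ve
#> <threshold_model ve: baseline < 0.4323 -> P; BA = 1.000 (sens 1.000,
#>  spec 1.000), McNemar p = 1>

bundle$pixel$model
#> <pixel_tree_model: 3 rule(s), train BA 0.765, mean validation BA 0.797,
#>  135 px/patient>
#>      depth feature op       cut
#> 765      1      ve <= 0.3140692
#> ...
```

Reading the output: the replicate-derived ADC repeatability coefficient is
tiny because the phantom's replicate noise is small at the VOI-median
level; the pooled balanced accuracy of 1.0 says every tumor programmed to
respond (and none programmed not to) was flagged by the RC bands; the
baseline-`ve` threshold model and the pixel-level tree both recover
low-`ve` tumors/pixels as the responders, mirroring the biology programmed
into the phantom (low extracellular volume at baseline leaves room for the
drug-induced increase).

A thin command-line wrapper is included:

```sh
Rscript inst/cli/qmripd.R all --out out/ --seed 7
Rscript inst/cli/qmripd.R simulate --out phantom/ --seed 7
```

## Package layout

| Path | Contents |
| --- | --- |
| `R/phantom.R`, `R/noise.R` | ground-truth cohorts, simulators, Rician noise |
| `R/adc.R`, `R/t1.R`, `R/spgr.R` | ADC and VFA T1 fitting |
| `R/dce.R` | concentration, AIF, iAUC, extended Tofts |
| `R/response.R` | RC, responder labels, thresholds, ICC |
| `R/pixelwise.R`, `R/tree.R` | pixel dataset, CART, LOPO |
| `R/pipeline.R`, `R/io.R` | end-to-end driver, NIfTI/CSV I/O |
| `vignettes/qmri-response-methods.Rmd` | models, assumptions, design choices |
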