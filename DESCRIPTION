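Package: qmripd
Title: Quantitative MRI Pharmacodynamic Response Analysis with Digital Phantoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative MRI analysis of tumor pharmacodynamic
    response to stroma-modifying therapy. Fits apparent diffusion coefficient
    (ADC) maps from diffusion-weighted MRI, T1 maps from variable-flip-angle
    spoiled gradient-echo series, converts dynamic contrast-enhanced (DCE)
    series to gadolinium concentration, extracts arterial input functions,
    computes 90-s initial area under the concentration curve (iAUC), and fits
    the extended Tofts pharmacokinetic model. Tumor response is classified
    against QIBA-style repeatability coefficients at the volume-of-interest
    and pixel level, baseline predictive thresholds are discovered by balanced
    accuracy maximization, and a depth-limited decision tree with
    patient-balanced sampling and leave-one-patient-out cross-validation
    models pixel-wise response. A digital phantom generator produces
    multi-visit cohorts with known ground truth so the whole pipeline is
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    RNifti,
    stats,
    utils
Suggests:
    rpart,
    yaml,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
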