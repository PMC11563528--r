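Package: aslperf
Title: Post-Thrombectomy Brain Perfusion Analysis from Arterial Spin Labeling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies cerebral blood flow (CBF) from pseudo-continuous
    arterial spin labeling (pCASL) control/label series with the consensus
    single-compartment model, computes the mirrored-mask percent-CBF-difference
    statistic within a gray-matter-restricted, hematoma-excluded infarct mask,
    classifies the no-reflow phenomenon after mechanical thrombectomy, and runs
    the cohort-level statistical battery (median/IQR descriptives, Mann-Whitney
    U and Fisher's exact group comparisons, stepwise-forward multivariate
    logistic regression with odds ratios and 95 percent confidence intervals).
    Ships a synthetic phantom and cohort generator with known ground truth so
    the full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
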