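Package: dmrsage
Title: Diffusion-Weighted MR Spectroscopy Signal Models and Age-Trajectory
    Analysis of Brain Metabolites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward signal models for diffusion-weighted MR spectroscopy
    (monoexponential, kurtosis representation, astro-sticks and modified
    astro-sticks powder-averaged stick models), bounded Levenberg-Marquardt
    fitting with b-range selection and lower-bound exclusion rules,
    simplified per-transient phase/frequency correction and peak-threshold
    quality control, a synthetic cohort generator matched to a tetrahedral
    six-b-value acquisition protocol, and age-trajectory statistics (OLS
    with confidence and prediction bands, tissue-fraction covariate
    regression, Welch group comparison with Bonferroni control).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    pracma,
    stats,
    utils,
    graphics,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
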