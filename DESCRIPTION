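Package: faaprog
Title: Frontal Alpha Asymmetry Prognostics for Pediatric Status Epilepticus
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pipeline for evaluating frontal alpha asymmetry (FAA) as a
    prognostic EEG marker in pediatric status epilepticus. Implements the
    signal chain from raw multichannel EEG to the FAA index (common average
    re-referencing, 0.3-40 Hz zero-phase bandpass, robust artifact
    rejection, Welch power spectral density, alpha-band power), the
    cohort-level statistical battery (pooled two-sample t tests from raw
    data or published summaries, Pearson chi-square and Fisher exact
    contingency tests, Shapiro-Wilk normality testing, binary logistic
    regression with Wald inference, proportion-based sample-size
    calculation), and ROC analysis with Hanley-McNeil standard errors and
    Youden-optimal cutoff selection. A synthetic-data module generates EEG
    recordings with a controllable asymmetry and patient cohorts with
    configurable group moments, covariate marginals and a logistic outcome
    model, so the full pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    withr
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
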