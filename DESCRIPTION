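Package: deltacwas
Title: Longitudinal Connectome-Wide Association Analysis with Row-Wise FDR
Version: 0.1.0
Authors@R:
    person("Repository", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Mass-univariate analysis of longitudinal resting-state
    functional connectomes. Builds Pearson-correlation connectomes from
    ROI time series over a cortical plus subcortical parcellation,
    computes two-time-point connectivity change (delta rsFC), fits
    edge-wise baseline-adjusted ordinary least-squares regressions of a
    continuous symptom score on connectivity change with sex as a
    covariate, and corrects for multiple comparisons with a
    Benjamini-Hochberg procedure applied independently to each ROI row of
    the connectivity matrix. Includes cortical-integration summaries for
    subcortical seed regions, network frequency tables and signed hub
    scores, a percentile-sweep ROC analysis, a two-group (patients versus
    controls) contrast with sex control, and a synthetic cohort generator
    with planted effects for power and false-discovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    MASS
Suggests:
    testthat (>= 3.0.0),
    Matrix
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
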