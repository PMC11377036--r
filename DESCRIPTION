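Package: sustattn
Title: Connectome-Based Prediction of Sustained Attention and Its Coupling
    with Adolescent Substance Use
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A longitudinal task-fMRI analysis pipeline linking sustained
    attention to substance use in adolescence. Implements stop-signal-task
    behavioural metrics (intra-individual coefficient of variation, SSRT,
    inclusion rules), generalized psychophysiological interaction (gPPI)
    connectivity matrices from ROI time series, connectome-based predictive
    modelling (edge selection by partial correlation, network strength,
    repeated k-fold and leave-site-out cross-validation, consensus edges,
    permutation inference, cross-timepoint model transfer), exploratory
    factor analysis of Timeline-Followback substance-use items (KMO,
    Bartlett, varimax), residualized Spearman association grids with FDR
    control, and a three-wave bivariate latent change score model estimated
    by maximum likelihood. A synthetic cohort generator provides all inputs
    with known ground truth so every stage is testable without restricted
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
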