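Package: molnorm
Title: Molecular-Enriched Functional Connectivity and Normative Deviation Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates receptor-enriched functional networks from resting-state
    BOLD data by two-step (spatial then temporal) multiple regression against
    molecular density templates, summarises them over a parcellation, fits
    per-region hierarchical Bayesian normative models of molecular-enriched
    connectivity on healthy controls (age and sex fixed effects, site random
    effects with shared priors), and scores subjects as uncertainty-normalised
    deviation z-scores. Downstream tools cover principal-component reduction of
    psychometric batteries, between-subject similarity analysis with
    nonparametric group comparisons, permutation-based region-wise ANOVA and
    deviation-symptom regression with false-discovery-rate control, and a
    synthetic-data generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    lme4,
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
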