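Package: compmort
Title: Comparative Age-Specific Morbidity and Mortality in Two-Species Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing age-specific patterns of morbidity and
    mortality between a human-like and a companion-dog-like cohort of death
    records. Implements Gompertz mortality fitting by maximum likelihood for
    exact and interval-censored (age-binned) lifespans, Kaplan-Meier survival
    and kernel-smoothed hazard curves, a one-covariate proportional-hazards
    sex contrast, negative-binomial multimorbidity and comorbidity count
    models, multinomial logistic age-trajectory models of cause-of-death
    proportions with cross-species age rescaling by neoplastic-peak
    alignment and log2 odds-ratio comparison curves, rank-correlation of
    cause-of-death spectra, and a seeded synthetic two-cohort generator with
    a pathophysiological-process by organ-system cause taxonomy, record
    filtering, and veterinary-registry style age binning.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    survival,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    nnet,
    flexsurv,
    yaml
Config/testthat/edition: 3
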