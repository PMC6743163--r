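Package: metcal
Title: Calibrating Questionnaire MET Intensities Against Accelerometer
    Energy Expenditure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates reference metabolic-equivalent (MET) intensity values
    for a seven-item occupational and leisure-time physical activity
    questionnaire by matching questionnaire-implied total energy expenditure
    (TEE) to accelerometer-derived TEE with a Bayesian random-walk
    Metropolis-within-Gibbs sampler. Provides the deterministic energy model
    (body surface area, basal metabolic rate, per-activity energy, TEE with
    the thermic effect of food, MVPA and exercise-volume summaries),
    method-agreement statistics (paired differences, Bland-Altman limits of
    agreement, intraclass correlation), age-group cohort analyses (exclusion
    filtering, one-way ANOVA with Tukey HSD, Jonckheere-Terpstra trend test,
    pairwise Mann-Whitney with Bonferroni adjustment), and seeded synthetic
    cohort generators that emulate the validation and baseline study
    populations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
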