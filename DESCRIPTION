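Package: fgng
Title: Fractional Gluconeogenesis from Heavy-Water Labeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates fractional gluconeogenesis (fGNG) from deuterium
    oxide (heavy water) labeling experiments: selected-ion-monitoring
    intensities of the glucose penta-acetate m/z 169/170 fragment pair are
    converted to fragment enrichment, divided by calibrated body-water
    enrichment, and classified against fed/unfed dietary-adequacy bands.
    Includes the isotopologue forward model (binomial site labeling plus
    natural-abundance background), standard-curve calibration for
    body-water readings, the factorial statistics used on small feeding x
    injury cohorts (Type III two-way ANOVA, pooled t-tests, Tukey-Kramer
    post hoc, and a summary-statistics ANOVA oracle), and a seeded
    synthetic-cohort simulator so the whole pipeline is testable without
    laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
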