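Package: serocontrast
Title: Contrast-Score Classification of Peptide-Array Serology with Stability Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing antibody-binding profiles from high-density
    peptide microarrays in immunotherapy cohorts. Converts replicate-level
    relative fluorescence measurements into patient-positive calls, filters
    peptides by cohort prevalence, selects outcome-associated peptides by
    iterated-subsample chi-square stability selection, classifies samples with
    a contrast-coded sum score that admits an indeterminate class (or a
    one-sided threshold rule), and reports indeterminate-aware performance.
    Includes a synthetic cohort generator that emulates the sparse, bimodal
    binding matrices such assays produce, for power and recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
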