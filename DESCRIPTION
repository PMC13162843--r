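Package: clonotrack
Title: Longitudinal T-Cell Receptor Repertoire Analysis and Clonal
    Expansion Tracking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for longitudinal analysis of bulk TCR-beta CDR3
    repertoire sequencing from peripheral blood and tumor biopsies:
    ingestion of immunoSEQ/AIRR-style clonotype tables, productive
    filtering and clonal frequency computation, Simpson clonality and
    rank-based group comparisons, negative-control-calibrated calling of
    newly detected and increased clonotypes, a beta-binomial
    differential-abundance comparator with dispersion estimation from
    no-treatment control pairs, per-patient clonotype trajectory tracking
    with tumor-infiltrating-lymphocyte annotation, cohort metadata
    summaries, and a synthetic repertoire generator with ground-truth
    labels for validating every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
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
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
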