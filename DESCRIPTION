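Package: elnaml
Title: ELN 2017 and 2022 Genetic Risk Classification for Acute Myeloid
    Leukemia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule engines for the European LeukemiaNet (ELN) 2017 and 2022
    genetic risk classifications of acute myeloid leukemia, built on
    per-patient mutation and karyotype tables. Includes a restricted ISCN
    karyotype parser with edition-aware complex and monosomal karyotype
    logic, variant-reporting filters, cross-edition reclassification
    analysis with reasoned transition tables and Sankey export,
    Kaplan-Meier / log-rank / Cox survival summaries per risk stratum,
    proposed post-2022 refinements (a very-adverse stratum and
    myelodysplasia-gene burden reallocation), and a synthetic-cohort
    generator: a deterministic 546-patient reclassification fixture plus a
    stochastic simulator with median-calibrated exponential survival.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    survival,
    tibble,
    tidyr
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
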