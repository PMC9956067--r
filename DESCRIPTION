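Package: mtlhon
Title: Mitochondrial DNA Variant Interpretation and Cohort Analysis for
    LHON Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for interpreting mitochondrial DNA substitution variants
    in Leber hereditary optic neuropathy (LHON) screening of the three
    complex-I genes MT-ND1, MT-ND4 and MT-ND6.  Parses and normalises
    "m." variant notation on the rCRS coordinate frame, translates protein
    consequences (including light-strand MT-ND6 codons) under the vertebrate
    mitochondrial code, evaluates mtDNA-specific ACMG/AMP evidence codes
    (BS1/BA1, PP3, PS3, PP4, PM5, PS4 with strength modifiers) from a
    curated evidence snapshot, and combines them into five-tier
    classifications.  Cohort-level functions compute diagnostic yield,
    per-gene attribution, familial/sporadic breakdown, variant spectra and
    haplogroup-marker tagging, and a seeded generator simulates screening
    cohorts with Sanger heteroplasmy-detection censoring, including a
    deterministic reconstruction of a published 100-patient Argentinean
    cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    glue,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
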