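Package: oligocarrier
Title: Rare-Variant Carrier Screening and Oligogenic Co-Occurrence Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for rare-variant gene-panel screening in disease
    cohorts: reading and validating genotype matrices, variant annotation
    tables and mode-of-inheritance gene panels; array-design and analysis-stage
    variant prioritisation (consequence class, minor allele frequency,
    SIFT/PolyPhen calls, CADD-PHRED thresholds, LOFTEE confidence,
    gain-of-function exclusion lists); sample quality control with a
    reproducible exclusion ledger and duplicate-genotype concordance by array
    cluster category; per-gene capped carrier load and classification of
    samples into carrier groups consistent or inconsistent with each gene's
    expected mode of inheritance, swept over deleteriousness thresholds and
    panel scopes; and oligogenic statistics - Wald proportion intervals,
    Fisher's exact cohort comparisons, multi-gene carriage, gene-pair
    co-occurrence expected probabilities with exact binomial tests,
    Benjamini-Hochberg adjustment, and carrier-sharing gene-pair edges.
    Includes a seeded synthetic-cohort generator with planted mode-of-
    inheritance structure, gene-pair enrichment, duplicate pairs and QC
    defects for end-to-end testing and calibration.
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
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
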