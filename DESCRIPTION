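Package: smnscreen
Title: Resolving False-Positive SMA Newborn-Screening Results from SMN1
    Primer-Site Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to investigate PCR-based spinal muscular atrophy (SMA)
    newborn-screening results that are false positives caused by rare
    SMN1 coding variants in primer- or probe-binding sites. Provides a
    small HGVS coding-variant engine that derives protein consequences
    (including frameshift fsTer nomenclature) on a transcript model, an
    assay screen that classifies variants by overlap with primer/probe
    annealing intervals, an in-silico restriction digest (DdeI) that
    discriminates SMN1 from SMN2 transcripts and full-length from
    exon-7-skipped isoforms, a Hardy-Weinberg compound-heterozygote
    frequency model reproducing population-level expected counts, and a
    seeded synthetic-cohort generator that supplies every input the
    pipeline needs without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
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
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
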