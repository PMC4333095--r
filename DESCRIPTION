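Package: ztre
Title: Zinc Transcriptional Regulatory Element Scanning and Zinc-Responsive
    Expression Analysis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for locating the zinc transcriptional regulatory element
    (ZTRE), a degenerate near-palindromic DNA element with two half-sites
    separated by a variable 0-50 nt spacer, in promoter and rDNA sequences;
    for counting element footprints and per-kilobase densities in windows
    around transcription start sites; for annotating C2H2 zinc fingers in
    protein sequences by their C-X2-C-X12-H-X3-H spacing; for the arithmetic
    of peptide-mass-fingerprint identification (in-silico tryptic digestion,
    monoisotopic masses, ppm-tolerance peak matching, sequence coverage); and
    for quantifying zinc-responsive expression with the delta-delta-Ct method
    and a rank-product differential-expression statistic. A seeded synthetic
    data generator plants elements, fingers, peaks and fold changes with
    known ground truth so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
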