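Package: ribopause
Title: Codon-Level Ribosome Pausing and Compositional Metagene Analysis for Bacterial Ribo-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of bacterial ribosome-profiling data at codon
    resolution: 3'-end footprint densities, A-site offset calibration from
    start/stop-anchored metagene profiles, per-nucleotide and per-codon pause
    scores, and a compositional (isometric log-ratio + paired Hotelling T2)
    comparison of 10-bin along-ORF density profiles between conditions.
    Includes a seeded footprint simulator with codon-specific dwell times and
    premature drop-off, and an in-silico RNase T1 digestion / average-mass
    calculator for RNA fragments carrying aminoacyl and N-acetyl adducts, for
    interpreting MALDI-TOF spectra of charged and acetylated tRNA.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    stats,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
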