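Package: taillessr
Title: Detection and Analysis of Tailless Retropseudogenes
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens repeat-annotated genomes for 3'-truncated, non-polyadenylated
    ("tailless") retropseudogenes created by LINE1-mediated, internally primed
    target-primed reverse transcription. Provides a target-site-duplication (TSD)
    anchored filter cascade over RepeatMasker annotations, exact Smith-Waterman and
    Needleman-Wunsch aligners with the screen's scoring schemes, element censuses,
    insertion-site and breakpoint motif statistics (position frequency matrices and
    information-content logos), phylogenetic branch assignment of presence/absence
    patterns, and a deterministic synthetic-genome generator with planted ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    Biostrings,
    dplyr,
    tibble,
    tidyr,
    purrr,
    stringr,
    readr,
    rlang,
    ggplot2,
    generics,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
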