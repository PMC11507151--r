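Package: entroplane
Title: Ordinal-Pattern Entropy and Statistical Complexity Analysis of
    Intracranial EEG Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sliding-window Bandt-Pompe ordinal-pattern symbolization,
    normalized permutation Shannon entropy and Martin-Plastino-Rosso (MPR)
    statistical complexity on the complexity-entropy causality plane, and
    Welch power spectral density for intracranial EEG channels, with cohort
    tools to group channels by brain region, hemisphere and sex, enforce
    minimum-patient eligibility, perform age-matched subsampling, and compare
    groups with Mann-Whitney U tests and Benjamini-Hochberg FDR correction.
    Includes a synthetic-cohort generator (colored noise with band-limited
    oscillatory peaks and controlled group effects) so the whole pipeline is
    testable without access to clinical recordings, plus readers for EDF
    signal files and channel metadata tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
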