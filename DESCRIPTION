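Package: isotopt
Title: Isotopologue-Scored Optimization of LC-HRMS Preprocessing Parameters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores and optimizes the parameters of LC-HRMS preprocessing
    (centWave-style peak picking, obiwarp-style retention time alignment and
    density-based feature grouping) without isotope labeling, using the natural
    13C isotopologue peaks present in any biological sample. Peak picking is
    scored by the recovery of parent/M+1 isotopologue pairs (peak picking
    score, PPS); retention time correction by the inverse of the mean
    within-group retention time deviation (RCS); grouping by the ratio of the
    squared number of complete one-peak-per-injection groups to the remaining
    groups (GS). Parameter settings are explored with Box-Behnken designs,
    evaluated through second-order response-surface models, and refined by
    maximum focusing with zoom-in/zoom-out range adjustment. A synthetic
    pooled-sample LC-MS generator with known ground truth (isotope envelopes
    at natural abundance, retention time drift, noise) makes the whole
    pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    MASS,
    Matrix,
    mzR,
    optparse,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
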