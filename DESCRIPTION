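Package: persisterfit
Title: Quantification of Bacterial Persister Fractions from Antibiotic Kill Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits a two-state (normal/persister) phenotypic-switching model to
    biphasic antibiotic time-kill curves by Poisson maximum likelihood on raw
    colony counts, resolves the model's identifiability degeneracy by reporting
    the feasible persister-fraction interval, and provides study-level analyses:
    cross-antibiotic rank correlation of persister fractions, classification of
    combination-treatment survival (exclusive, independent, coincident), and
    correlation of fractions with switching and death rates. Includes a
    synthetic kill-curve generator emulating serial-dilution spot plating and
    an exact stochastic event simulator of the switching process.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
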