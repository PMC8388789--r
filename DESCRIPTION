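Package: pedconnect
Title: Pedigree-Based Genetic Diversity and Flock Connectedness Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pedigree-based monitoring of genetic diversity and
    across-flock genetic evaluation design in livestock breeding programs.
    Reads, validates and topologically orders pedigrees; computes pedigree
    quality metrics (per-generation completeness, pedigree completeness
    index, equivalent complete generations, fully traced and maximum
    generations); inbreeding and kinship coefficients and the sparse inverse
    numerator relationship matrix; effective population size from the mean
    rate of increase in coancestry with sliding birth-year windows and trend
    regression; and four mixed-model genetic connectedness statistics
    between management units (individual and group prediction error variance
    of differences, coefficient of determination, and prediction error
    correlation). Includes seeded simulators for multi-flock populations
    with overlapping generations and for idealized random-mating populations,
    providing known-truth fixtures for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
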