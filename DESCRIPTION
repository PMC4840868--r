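Package: shadowspline
Title: Reference-Free Sequencing Error Rates from Shadow Counts and
    Smoothing Splines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates per-read error rates for fixed-length short-read
    sequencing samples without a reference genome.  Reads are tallied into
    distinct-sequence counts, the most frequent sequences are taken as
    error free, and the reads within two substitutions of each one (its
    "shadows") are counted.  Error rates are estimated from the resulting
    read-shadow relationship by robust linear regression (the shadow
    regression error rate, SRER) and by cubic and iteratively reweighted
    robust smoothing splines (empirical error rates, EER).  Also provides
    a frequency-based Monte Carlo simulator that draws read/shadow pairs
    from a binned joint distribution, a calibration simulator that injects
    base-specific substitution errors (with optional polymorphism and
    duplication perturbations), replicate study drivers, and a
    known-truth synthetic fixture generator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
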