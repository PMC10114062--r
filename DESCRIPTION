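Package: mrscreen
Title: Bidirectional Two-Sample Mendelian Randomization Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for screening candidate traits for causal relationships with
    an index trait using two-sample Mendelian randomization on GWAS summary
    statistics. Implements trait screening on study metadata, summary-statistic
    harmonization, LD clumping and proxy substitution, Steiger directionality
    filtering, instrument-strength F statistics, the multiplicative
    random-effects inverse-variance-weighted estimator, MR-Egger with the
    I2GX/NOME diagnostic and SIMEX correction, weighted median and weighted
    mode estimators, MR-PRESSO global and outlier tests, a Bayesian
    sharing-versus-causal model comparison scored by expected log pointwise
    posterior density, multiple-testing control, staged evidence
    classification, and a synthetic GWAS summary-statistic generator so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
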