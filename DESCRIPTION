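Package: modred
Title: Systematic Reduction of Mechanistic Simulation Models by Variable Replacement
Version: 0.1.0
Authors@R:
    person("Model", "Reduction Maintainers", email = "modred@example.org",
           role = c("aut", "cre"))
Description: Tools for systematic reduction of daily-time-step mechanistic
    simulation models. Internal model variables are replaced by fitted
    constants, screened one at a time against observations via a weighted
    residual sum of squares, and then explored in combination with a
    Metropolis-Hastings walk scored by an informal (GLUE-style)
    pseudo-likelihood. Per-variable replacement probabilities classify
    variables as contributing, redundant, or noise. Includes a declarative
    model language with switch variables, Nash-Sutcliffe skill metrics, an
    exhaustive-enumeration oracle for small candidate sets, and a synthetic
    crop-like fixture with planted variable roles for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo:
    Rcpp
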