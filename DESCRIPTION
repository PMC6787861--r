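Package: fuelmoist
Title: Nonlinear Mixed-Effects Modelling of Seasonal Live Fuel Moisture Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling the seasonal drying of live fuel moisture
    content (LFMC) with nonlinear mixed-effects models. Implements a
    four-parameter declining logistic mean with leaf-type fixed effects,
    plot-level random effects, per-stratum (varIdent) residual variances and
    ARMA residual autocorrelation, fitted by exact or adaptive Gauss-Hermite
    marginal maximum likelihood. Includes the stepwise AIC selection protocol
    (random structure, then variance/correlation, then fixed effects), a suite
    of simpler alternative models for comparison, Wald contrasts between leaf
    types, residual diagnostics, and a synthetic-data generator emulating the
    two-site, plot-nested field design so that every stage of the analysis can
    be exercised and calibrated by simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    nlme,
    patchwork,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
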