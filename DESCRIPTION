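Package: clogfit
Title: Empirical Fractional Models and Blocking-Law Diagnostics for
    Membrane Filtration Clogging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for modeling the clogging of constant-pressure membrane
    filtration from cumulative volume-time curves. Provides eight empirical
    fractional (rational and exponential-saturation) volume-time models, a
    dragonfly-algorithm global search with Levenberg-Marquardt refinement
    minimizing the relative root mean squared error, a goodness-of-fit suite
    (SSR, R2, VAF, RMSE/nRMSE, MAE/nMAE, Chi/nChi, SEP and calculated-versus-
    observed regression vectors), a simulator for the unified Hermia blocking
    law, and a clogging-index estimator that identifies the fouling mechanism
    (cake, intermediate, standard, complete) from the log-log regression of
    the second on the first derivative of filtration time with respect to
    volume.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    optparse,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
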