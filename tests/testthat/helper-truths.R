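# Study conditions for the parameter-recovery suite: one generating truth
# per model, chosen (via a Fisher-information design analysis, see the
# methods vignette) so the judged quantities are practically identifiable
# at the study noise level (sd = 1% of the asymptotic volume, M = 100).
recovery_truths <- function() {
  list(
    `1` = list(params = c(a = 2, b = 0.3, n = 1.5, m = 1.5), horizon = 20),
    `2` = list(params = c(vinf = 2, a = 0.5, n = 1.2), horizon = 20),
    `3` = list(params = c(vinf = 2, a = 2, n = 1.2), horizon = 20),
    `4` = list(params = c(vinf = 2.5, a = 0.8, n = 1.2, m = 1.5), horizon = 20),
    `5` = list(params = c(a = 2^(1 / 0.7), b = 0.5, c = 1, d = 1, n = 2, m = 0.7),
               horizon = 20),
    `6` = list(params = c(a = 2, b = 1, n = 1.2), horizon = 20),
    `7` = list(params = c(vinf = 2, a = 0.1, b = 0.3, c = 1), horizon = 40),
    `8` = list(params = c(vinf = 2, a = 0.05, b = 0.25, c = 2, n = 1.4),
               horizon = 40)
  )
}

# The identifiable quantities each model is judged on: parameters (or
# canonical combinations, for the over-parametrized models) whose asymptotic
# relative standard error at the study conditions is below ~2.3%.
judged_quantities <- function(id, params) {
  p <- as.list(params)
  out <- switch(as.character(id),
    `1` = c(a = p$a, m = p$m),
    `4` = c(a_vinf = p$a * p$vinf, n = p$n, m = p$m),
    `5` = c(v_inf = (p$a / p$b)^p$m * p$d),
    `7` = c(a = p$a, v_eff = p$vinf / (1 + p$c)),
    `8` = c(n = p$n, v_eff = p$vinf / (1 + p$c)),
    p)
  unlist(out)
}

# noise-free generator curve for one model truth
truth_series <- function(id, n_points = 100, noise_sd = 0, seed = NULL) {
  tr <- recovery_truths()[[as.character(id)]]
  suppressWarnings(generate_series(
    list(model = as.integer(id), params = tr$params),
    horizon = tr$horizon, n_points = n_points,
    noise_sd = noise_sd, noise_kind = "additive", seed = seed
  ))
}

# small search configuration for unit tests that only need a decent fit
quick_config <- function(seed = 1, ...) {
  fit_config(n_restarts = 3, swarm_size = 20, n_iterations = 200, seed = seed, ...)
}
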