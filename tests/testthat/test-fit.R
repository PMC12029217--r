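test_that("fit_config validates its fields", {
  expect_s3_class(fit_config(), "fit_config")
  expect_error(fit_config(n_restarts = 0), class = "clogfit_config_error")
  expect_error(fit_config(swarm_size = 1), class = "clogfit_config_error")
  expect_error(fit_config(n_iterations = 0), class = "clogfit_config_error")
  expect_error(fit_config(bounds = list(a = c(2, 1))),
               class = "clogfit_config_error")
})

test_that("local refinement is a descent step that honors bounds", {
  fs <- generate_series(list(model = 6, params = c(a = 2, b = 1, n = 1)),
                        horizon = 10, n_points = 50)
  y <- fs$volume
  resid_fn <- function(p) y - evaluate_model(6, p, fs$time)
  lower <- c(a = 1e-3, b = 1e-3, n = 0.05)
  upper <- c(a = 1e3, b = 1e3, n = 10)

  # stationary at the truth
  truth <- c(a = 2, b = 1, n = 1)
  out <- refine_local(resid_fn, truth, lower, upper)
  expect_equal(out, truth, tolerance = 1e-8)

  # 10% perturbation converges back to the generating parameters
  out2 <- refine_local(resid_fn, truth * 1.1, lower, upper)
  expect_equal(out2, truth, tolerance = 1e-6)

  # descent property from random starts
  set.seed(21)
  for (i in 1:50) {
    init <- c(a = runif(1, 0.5, 4), b = runif(1, 0.3, 3), n = runif(1, 0.5, 2))
    ref <- refine_local(resid_fn, init, lower, upper)
    expect_lte(sum(resid_fn(ref)^2), sum(resid_fn(init)^2) + 1e-12)
    expect_true(all(ref >= lower & ref <= upper))
  }

  # non-finite residuals at the start: warn and return the start
  bad <- function(p) rep(NaN, 3)
  expect_warning(out3 <- refine_local(bad, truth, lower, upper))
  expect_identical(out3, truth)
})

test_that("noise-free model 6 data are recovered essentially exactly", {
  fs <- generate_series(list(model = 6, params = c(a = 2, b = 1, n = 1.2)),
                        horizon = 20, n_points = 100)
  fit <- fit_model(fs, 6, fit_config(seed = 1))
  expect_equal(unname(fit$params["a"]), 2, tolerance = 1e-3)
  expect_equal(unname(fit$params["b"]), 1, tolerance = 1e-3)
  expect_equal(unname(fit$params["n"]), 1.2, tolerance = 1e-3)
  expect_gte(fit$metrics$R2, 1 - 1e-10)
  expect_true(fit$refined || fit$objective_value < 1e-8)
})

test_that("the reported objective is the best across refined restarts", {
  fs <- truth_series(6, noise_sd = 0.02, seed = 5)
  fit <- fit_model(fs, 6, quick_config(seed = 2))
  expect_equal(fit$objective_value, min(fit$restart_objectives))
  expect_length(fit$restart_objectives, 3)
  expect_true(all(is.finite(fit$restart_objectives)))
})

test_that("zero-noise generation is recovered for every model (identifiable quantities)", {
  for (id in 1:8) {
    tr <- recovery_truths()[[as.character(id)]]
    fs <- truth_series(id)
    fit <- fit_model(fs, id, fit_config(seed = 1))
    got <- judged_quantities(id, fit$params)
    want <- judged_quantities(id, tr$params)
    expect_equal(got, want, tolerance = 1e-3,
                 label = paste("model", id, "zero-noise recovery"))
  }
})

test_that("insufficient data and unknown models are rejected", {
  tiny <- filtration_series(data.frame(time = 1:3, volume = c(0.1, 0.2, 0.3)))
  expect_error(fit_model(tiny, 5, quick_config()),
               class = "clogfit_insufficient_data_error")
  expect_error(fit_model(tiny, 9, quick_config()),
               class = "clogfit_usage_error")
})

test_that("fit_models ranks by nRMSE and carries quality labels", {
  fs <- suppressWarnings(
    generate_series(list(model = 6, params = c(a = 2, b = 1, n = 1.2)),
                    horizon = 20, n_points = 60, noise_sd = 0.005,
                    noise_kind = "multiplicative", seed = 9))
  rk <- fit_models(fs, models = c(2, 6), config = quick_config())
  expect_s3_class(rk, "clog_fit_set")
  expect_equal(rk$nRMSE, sort(rk$nRMSE))
  expect_true(all(c("R2_label", "nRMSE_label") %in% names(rk)))
  expect_lte(rk$nRMSE[1], rk$nRMSE[2])
})

test_that("broom-style methods return tidy structures", {
  fs <- truth_series(6, noise_sd = 0.02, seed = 5)
  fit <- fit_model(fs, 6, quick_config())
  td <- tidy(fit)
  expect_true(all(c("a", "b", "n", "v_inf") %in% td$term))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("nRMSE", "R2", "SEP", "alpha", "beta", "R") %in% names(gl)))
  au <- augment(fit)
  expect_equal(au$.resid, au$observed - au$.fitted, tolerance = 1e-12)
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
  # fixed parameter d reported for model 5
  fit5 <- fit_model(truth_series(5, noise_sd = 0, seed = 1), 5, quick_config())
  td5 <- tidy(fit5)
  expect_true(td5$fixed[td5$term == "d"])
})
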