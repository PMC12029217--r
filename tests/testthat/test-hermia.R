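test_that("closed-form solutions match hand integrations", {
  # cake filtration: t(v) = v/q0 + (k/2) v^2
  expect_equal(hermia_time(2, N = 0, k = 0.5, q0 = 1), 3, tolerance = 1e-12)
  # complete blocking: v(t) = (q0/k)(1 - e^{-kt})
  tt <- c(0.5, 1, 4)
  expect_equal(hermia_volume(tt, N = 2, k = 0.5, q0 = 1),
               2 * (1 - exp(-tt / 2)), tolerance = 1e-12)
  # time and volume forms are mutually inverse for assorted N
  for (N in c(0, 0.5, 1, 1.3, 1.5, 2)) {
    v <- seq(0.05, 0.8, length.out = 9) *
      min(ifelse(N > 1, 1^(N - 1) / ((N - 1) * 0.4), 5), 5)
    t <- hermia_time(v, N, k = 0.4, q0 = 1)
    expect_equal(hermia_volume(t, N, k = 0.4, q0 = 1), v, tolerance = 1e-9,
                 label = paste("inverse pair at N =", N))
  }
})

test_that("simulated curves are increasing and concave; domains enforced", {
  s <- simulate_hermia(N = 1.5, k = 0.3, q0 = 1, n_points = 100, horizon = 20)
  expect_true(all(diff(s$volume) > 0))
  expect_true(all(diff(diff(s$volume)) < 1e-12))  # concave in t
  # volume beyond the asymptote is a domain error (v_inf = q0/k for N = 2)
  expect_error(simulate_hermia(N = 2, k = 0.5, q0 = 1, grid = "volume", v_max = 2.5),
               class = "clogfit_domain_error")
  expect_error(hermia_time(2.1, N = 2, k = 0.5, q0 = 1),
               class = "clogfit_domain_error")
  expect_error(simulate_hermia(N = 1.5, k = -1, q0 = 1, horizon = 5),
               class = "clogfit_domain_error")
})

test_that("closed forms agree with the ODE integrator", {
  # one canonical index here; the full sweep lives in the acceptance suite
  s_cl <- simulate_hermia(N = 1.5, k = 0.3, q0 = 2, n_points = 50, horizon = 15)
  s_ode <- simulate_hermia(N = 1.5, k = 0.3, q0 = 2, n_points = 50, horizon = 15,
                           method = "ode")
  expect_equal(s_ode$volume, s_cl$volume, tolerance = 1e-8)
})

test_that("finite-difference route recovers the generating index", {
  s <- simulate_hermia(N = 1, k = 0.3, q0 = 1, n_points = 200, grid = "volume",
                       v_max = 6)
  est <- estimate_clogging_index(s)
  expect_lt(abs(est$N - 1), 0.02)
  expect_lt(abs(est$k - 0.3) / 0.3, 0.05)
  expect_equal(est$mechanism, "intermediate")

  s13 <- simulate_hermia(N = 1.3, k = 0.3, q0 = 1, n_points = 200,
                         grid = "volume", v_max = 0.85 * 1^(0.3) / (0.3 * 0.3))
  est13 <- estimate_clogging_index(s13)
  expect_lt(abs(est13$N - 1.3), 0.02)
  expect_equal(est13$mechanism, "mixed: intermediate/standard")
})

test_that("model-6 analytic route obeys the standard-blocking identity", {
  set.seed(2)
  for (i in 1:5) {
    a <- runif(1, 0.5, 5); b <- runif(1, 0.1, 3)
    est <- clogging_index_model6(a, b, n = 1)
    expect_equal(est$N, 1.5, tolerance = 1e-8)
    expect_equal(est$C, log(2 * b / sqrt(a)), tolerance = 1e-8)
    expect_equal(est$r_squared, 1, tolerance = 1e-10)
  }
})

test_that("mechanism classification follows the canonical bands", {
  expect_equal(classify_mechanism(1.5028), "standard")
  expect_equal(classify_mechanism(1.3470), "mixed: intermediate/standard")
  expect_equal(classify_mechanism(0), "cake")
  expect_equal(classify_mechanism(0.98), "intermediate")
  expect_equal(classify_mechanism(2.04), "complete")
  expect_equal(classify_mechanism(0.5), "mixed: cake/intermediate")
  expect_equal(classify_mechanism(1.75), "mixed: standard/complete")
  expect_equal(classify_mechanism(2.2), "unclassified (N > 2)")
  expect_equal(classify_mechanism(-0.2), "unclassified (N < 0)")
  expect_equal(classify_mechanism(1.4, tol = 0.1), "standard")
})

test_that("too few usable points raises an insufficient-data error", {
  s <- simulate_hermia(N = 1.5, k = 0.3, q0 = 1, n_points = 5, horizon = 5)
  expect_error(estimate_clogging_index(s),
               class = "clogfit_insufficient_data_error")
})

test_that("noisy non-monotone points are excluded and counted", {
  s <- generate_series(list(N = 1.5, k = 0.3, q0 = 1), horizon = 20,
                       n_points = 200, noise_sd = 0.002, noise_kind = "additive",
                       seed = 8)
  est <- estimate_clogging_index(s)
  expect_gte(est$n_excluded, 1)
  expect_true(is.finite(est$N))
  # noise wrecks finite-difference curvature estimates (the analytic route
  # exists for exactly this reason), but the regression diagnostics expose it
  expect_lt(est$r_squared, 0.99)
  expect_equal(est$n_points_used + est$n_excluded,
               length(est$data$ln_dt_dv) + est$n_excluded)
})

test_that("reference models behave as theory predicts", {
  s <- generate_series(list(N = 1.5, k = 2, q0 = 0.5), horizon = 30,
                       n_points = 60)
  cfg <- quick_config(seed = 4)
  std <- reference_model_fit(s, "standard", cfg)
  expect_gte(std$metrics$R2, 1 - 1e-8)
  # the combined model nests the standard one
  comb <- reference_model_fit(s, "combined", cfg)
  expect_lte(comb$metrics$SSR, std$metrics$SSR + 1e-10)

  # cake-filtration data: the standard law is misspecified, model 6 is not
  sc <- simulate_hermia(N = 0, k = 8, q0 = 0.5, n_points = 60, grid = "volume",
                        v_max = 1.5)
  std_c <- reference_model_fit(sc, "standard", cfg)
  m6_c <- fit_model(sc, 6, cfg)
  expect_lt(std_c$metrics$R2, m6_c$metrics$R2)
})

test_that("hermia_fit tidiers and plot work", {
  est <- clogging_index_model6(2, 1, 1)
  expect_equal(tidy(est)$term, c("N", "C", "k"))
  gl <- glance(est)
  expect_equal(gl$mechanism, "standard")
  expect_s3_class(autoplot(est), "ggplot")
})
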