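test_that("model registry resolves ids and names", {
  reg <- clog_models()
  expect_equal(nrow(reg), 8)
  expect_equal(model_spec(6)$name, "rational")
  expect_equal(model_spec("rational")$id, 6)
  expect_error(model_spec(9), class = "clogfit_usage_error")
  expect_error(model_spec("nope"), class = "clogfit_usage_error")
  # model 5's d frozen by default, free on request
  expect_equal(model_spec(5)$n_free, 5)
  expect_equal(model_spec(5, free_d = TRUE)$n_free, 6)
})

test_that("evaluation matches hand values and boundary conditions", {
  expect_equal(evaluate_model(6, c(a = 2, b = 1, n = 1), 1), 1)
  # v(0) = 0 for every model
  params <- list(
    `1` = c(a = 2, b = 1, n = 1.2, m = 1.2),
    `2` = c(vinf = 2, a = 0.5, n = 1.2),
    `3` = c(vinf = 2, a = 2, n = 1.2),
    `4` = c(vinf = 2, a = 0.8, n = 1.2, m = 1.5),
    `5` = c(a = 2, b = 1, c = 1, n = 1.2, m = 1.5),
    `6` = c(a = 2, b = 1, n = 1.2),
    `7` = c(vinf = 2, a = 0.3, b = 0.2, c = 0.5),
    `8` = c(vinf = 2, a = 0.3, b = 0.2, c = 0.5, n = 1.1)
  )
  for (id in 1:8) {
    expect_identical(evaluate_model(id, params[[id]], 0), 0,
                     label = paste("model", id, "at t = 0"))
  }
  # saturation limit of model 6
  expect_equal(evaluate_model(6, c(a = 2, b = 1, n = 1), 1e6), 2,
               tolerance = 1e-4)
  expect_error(evaluate_model(6, c(a = 2, b = 1, n = 1), -1),
               class = "clogfit_domain_error")
  expect_error(evaluate_model(6, c(a = 2, b = -1, n = 1), 1),
               regexp = "'b'", class = "clogfit_domain_error")
})

test_that("asymptotic volumes follow the boundary conditions", {
  expect_equal(asymptotic_volume(6, c(a = 3, b = 2))$value, 1.5)
  expect_equal(asymptotic_volume(2, c(vinf = 5, a = 1, n = 1))$value, 5)
  d1 <- asymptotic_volume(1, c(a = 1, b = 1, n = 2, m = 1))
  expect_false(d1$finite)
  expect_equal(asymptotic_volume(1, c(a = 1, b = 1, n = 1, m = 2))$value, 0)
  expect_equal(asymptotic_volume(4, c(vinf = 2, a = 0.8, n = 1, m = 1))$value, 1.6)
  expect_equal(asymptotic_volume(5, c(a = 2, b = 1, c = 3, d = 2, m = 1.5))$value,
               2 * 2^1.5)
  expect_equal(asymptotic_volume(7, c(vinf = 3, a = 1, b = 1, c = 0.5))$value, 2)
})

test_that("curves are non-decreasing on dense grids (saturating regimes)", {
  tt <- seq(0, 50, length.out = 600)
  params <- list(
    `1` = c(a = 2, b = 0.3, n = 1.5, m = 1.5),  # n >= m: saturating branch
    `2` = c(vinf = 2, a = 0.5, n = 1.2),
    `3` = c(vinf = 2, a = 2, n = 1.2),
    `4` = c(vinf = 2.5, a = 0.8, n = 1.2, m = 1.5),
    `5` = c(a = 2, b = 0.5, c = 1, n = 2, m = 0.7),
    `6` = c(a = 2, b = 1, n = 1.2),
    `7` = c(vinf = 2, a = 0.1, b = 0.3, c = 1),  # a <= b: monotone branch
    `8` = c(vinf = 2, a = 0.05, b = 0.25, c = 2, n = 1.4)
  )
  for (id in 1:8) {
    v <- evaluate_model(id, params[[id]], tt)
    expect_true(all(diff(v) >= -1e-12), label = paste("model", id, "monotone"))
    expect_true(all(is.finite(v)), label = paste("model", id, "finite"))
  }
})

test_that("reparameterization equivalences hold to 1e-12", {
  tt <- seq(0, 30, length.out = 200)
  # model 3 with a  ==  model 2 with a' = 1/a
  v3 <- evaluate_model(3, c(vinf = 2, a = 4, n = 1.3), tt)
  v2 <- evaluate_model(2, c(vinf = 2, a = 1 / 4, n = 1.3), tt)
  expect_equal(v3, v2, tolerance = 1e-12)
  # model 6 (a, b, n)  ==  model 2 with vinf = a/b, shape b
  v6 <- evaluate_model(6, c(a = 2, b = 0.5, n = 1.3), tt)
  v2b <- evaluate_model(2, c(vinf = 4, a = 0.5, n = 1.3), tt)
  expect_equal(v6, v2b, tolerance = 1e-12)
})

test_that("model-6 inverse round-trips and rejects the asymptote", {
  p <- c(a = 2, b = 1, n = 1)
  expect_identical(model6_inverse(p, 0), 0)
  t3 <- model6_inverse(c(a = 2, b = 1, n = 1.3), evaluate_model(6, c(a = 2, b = 1, n = 1.3), 3))
  expect_equal(t3, 3, tolerance = 1e-10)
  expect_error(model6_inverse(p, 2), class = "clogfit_domain_error")
  expect_error(model6_inverse(p, 2.5), class = "clogfit_domain_error")
  # identity on a grid of (0, a/b)
  v <- seq(0.01, 1.99, length.out = 50)
  vv <- evaluate_model(6, p, model6_inverse(p, v))
  expect_equal(vv, v, tolerance = 1e-10)
})

test_that("model-6 analytic derivatives match hand values and a symbolic oracle", {
  d <- model6_derivatives(c(a = 2, b = 1, n = 1), 1)
  expect_equal(d$dt_dv, 2)    # a/(a - b v)^2
  expect_equal(d$d2t_dv2, 4)  # 2ab/(a - b v)^3

  # symbolic oracle: stats::deriv of t(v) = (v/(a - b v))^(1/n)
  sym <- stats::deriv(~ (v / (a - b * v))^(1 / n), "v", hessian = TRUE,
                      function.arg = c("v", "a", "b", "n"))
  set.seed(7)
  for (i in 1:200) {
    a <- runif(1, 0.5, 5); b <- runif(1, 0.2, 3); n <- runif(1, 0.5, 2)
    v <- runif(1, 0.02, 0.95) * a / b
    got <- model6_derivatives(c(a = a, b = b, n = n), v)
    s <- sym(v, a, b, n)
    expect_equal(got$dt_dv, as.numeric(attr(s, "gradient")), tolerance = 1e-9)
    expect_equal(got$d2t_dv2, as.numeric(attr(s, "hessian")), tolerance = 1e-9)
  }
  expect_error(model6_derivatives(c(a = 2, b = 1, n = 1), 0),
               class = "clogfit_domain_error")
})

test_that("derivatives are positive where the inverse map is convex (n <= 1)", {
  set.seed(11)
  for (i in 1:100) {
    a <- runif(1, 0.5, 5); b <- runif(1, 0.2, 3); n <- runif(1, 0.3, 1)
    v <- runif(1, 0.02, 0.95) * a / b
    d <- model6_derivatives(c(a = a, b = b, n = n), v)
    expect_gt(d$dt_dv, 0)
    expect_gt(d$d2t_dv2, 0)
  }
  # for n > 1 the early-time curve is S-shaped: d2t/dv2 < 0 near v = 0
  d <- model6_derivatives(c(a = 2, b = 1, n = 1.5), 0.01)
  expect_lt(d$d2t_dv2, 0)
})
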