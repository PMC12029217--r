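# The eight empirical fractional volume-time models. All satisfy v(0) = 0 by
# construction; with the default positivity bounds every denominator is
# bounded away from zero on t >= 0.
#
#   1  v = a t^n / (1 + b t^m)
#   2  v = vinf a t^n / (1 + a t^n)
#   3  v = vinf t^n / (a + t^n)
#   4  v = a vinf [t^n / (1 + t^n)]^m
#   5  v = d [a t^n / (c + b t^n)]^m        (d frozen at 1 by default)
#   6  v = a t^n / (1 + b t^n)
#   7  v = vinf (1 - e^{-a t}) / (1 + c (1 - e^{-b t}))
#   8  v = vinf (1 - e^{-a t^n}) / (1 + c (1 - e^{-b t^n}))

model_names <- c("rational-two-exponent", "saturating-vinf", "saturating-vinf-alt",
                 "power-saturating", "generalized-rational-power", "rational",
                 "exponential-saturation", "stretched-exponential-saturation")

# parameter classes drive the default search bounds:
#   amplitude      - same scale as the observed volumes
#   rate           - wide positive box, searched in log space (parameters
#                    whose magnitude couples to an exponent, e.g. 1/t_half^n)
#   volume_rate    - rate carrying volume units (model 1/6 'a', q0):
#                    the wide box scaled by the observed volume magnitude
#   time_rate      - a pure 1/time rate (model 7/8 'a', 'b'): bounded by
#                    what the observation window can resolve
#   gain           - dimensionless denominator gain (model 7/8 'c')
#   inverse_volume - reciprocal-volume rate (combined model's Ki)
#   exponent       - (0.05, 10]
model_param_classes <- list(
  `1` = c(a = "volume_rate", b = "rate", n = "exponent", m = "exponent"),
  `2` = c(vinf = "amplitude", a = "rate", n = "exponent"),
  `3` = c(vinf = "amplitude", a = "rate", n = "exponent"),
  `4` = c(vinf = "amplitude", a = "rate", n = "exponent", m = "exponent"),
  `5` = c(a = "rate", b = "rate", c = "rate", d = "rate",
          n = "exponent", m = "exponent"),
  `6` = c(a = "volume_rate", b = "rate", n = "exponent"),
  `7` = c(vinf = "amplitude", a = "time_rate", b = "time_rate", c = "gain"),
  `8` = c(vinf = "amplitude", a = "time_rate", b = "time_rate", c = "gain",
          n = "exponent")
)

#' Model registry
#'
#' Lists the eight empirical fractional volume-time models with their
#' parameter names. Models are addressable by integer id (1-8) or by name in
#' every function that takes a `model` argument.
#'
#' @return A tibble with columns `model_id`, `name`, `params`, `n_params`.
#' @export
clog_models <- function() {
  tibble(
    model_id = 1:8,
    name = model_names,
    params = purrr::map(model_param_classes, names),
    n_params = purrr::map_int(model_param_classes, length)
  )
}

#' Resolve a model specification
#'
#' @param model Integer id in 1-8 or a model name from [clog_models()].
#' @param free_d For model 5 only: free the redundant scale parameter `d`
#'   instead of freezing it at 1. Model 5 is over-parametrized (only the
#'   product `d * (a/c)^m` is identifiable), so `d` is frozen by default.
#' @return An object of class `clog_model`: id, name, free and fixed
#'   parameter names, and the parameter-class map used for default bounds.
#' @export
model_spec <- function(model, free_d = FALSE) {
  if (inherits(model, "clog_model")) return(model)
  if (is.character(model)) {
    id <- match(model, model_names)
    if (is.na(id)) {
      suppressWarnings(id <- as.integer(model))
    }
  } else {
    id <- as.integer(model)
  }
  if (is.na(id) || length(id) != 1 || id < 1 || id > 8) {
    stop_usage(paste0("Unknown model '", paste(model, collapse = ","),
                      "'. Valid ids are 1-8; valid names: ",
                      paste(model_names, collapse = ", "), "."))
  }
  classes <- model_param_classes[[id]]
  fixed <- numeric(0)
  if (id == 5 && !free_d) fixed <- c(d = 1)
  free <- setdiff(names(classes), names(fixed))
  structure(list(id = id, name = model_names[id],
                 params = names(classes), free = free, fixed = fixed,
                 classes = classes, n_free = length(free)),
            class = "clog_model")
}

#' @export
print.clog_model <- function(x, ...) {
  cat("<clog_model ", x$id, "> ", x$name, " | free: ",
      paste(x$free, collapse = ", "),
      if (length(x$fixed)) paste0(" | fixed: ",
                                  paste(names(x$fixed), x$fixed, sep = "=",
                                        collapse = ", ")),
      "\n", sep = "")
  invisible(x)
}

# full named parameter vector (free + fixed) from a possibly partial one
complete_params <- function(spec, params) {
  p <- as.list(params)
  miss <- setdiff(spec$params, c(names(p), names(spec$fixed)))
  if (length(miss) > 0) {
    stop_usage(paste0("Model ", spec$id, " needs parameter(s): ",
                      paste(miss, collapse = ", "), "."))
  }
  full <- c(unlist(p)[intersect(names(p), spec$params)], spec$fixed)
  full <- full[!duplicated(names(full))]
  if (any(!is.finite(full))) stop_domain("Model parameters must be finite.")
  full[spec$params]
}

# t^n for vector t (>= 0) and per-column exponent vector n; 0^n := 0 (n > 0)
pow_cols <- function(t, n) {
  M <- length(t); k <- length(n)
  out <- matrix(0, M, k)
  pos <- t > 0
  if (any(pos)) out[pos, ] <- exp(outer(log(t[pos]), n))
  out
}

# Batch evaluation: P is a k x n_params matrix (columns in spec$params
# order, fixed parameters included), times a length-M vector. Returns an
# M x k matrix of predicted volumes. This is the fitting engine's hot path.
eval_batch <- function(spec, P, times) {
  P <- matrix(P, ncol = length(spec$params))
  colnames(P) <- spec$params
  M <- length(times); k <- nrow(P)
  byrow <- function(x) matrix(x, M, k, byrow = TRUE)
  id <- spec$id
  if (is.character(id)) {
    # Hermia-law reference models (see reference_model_fit)
    q0 <- byrow(P[, "q0"]); ks <- byrow(P[, "ks"])
    vs <- q0 * times / (1 + (ks * sqrt(q0) / 2) * times)
    if (id == "standard") return(vs)
    ki <- byrow(P[, "ki"])
    return(log1p(ki * vs) / ki)
  }
  if (id == 1) {
    tn <- pow_cols(times, P[, "n"]); tm <- pow_cols(times, P[, "m"])
    V <- byrow(P[, "a"]) * tn / (1 + byrow(P[, "b"]) * tm)
  } else if (id == 2) {
    tn <- pow_cols(times, P[, "n"])
    atn <- byrow(P[, "a"]) * tn
    V <- byrow(P[, "vinf"]) * atn / (1 + atn)
  } else if (id == 3) {
    tn <- pow_cols(times, P[, "n"])
    V <- byrow(P[, "vinf"]) * tn / (byrow(P[, "a"]) + tn)
  } else if (id == 4) {
    tn <- pow_cols(times, P[, "n"])
    base <- tn / (1 + tn)
    V <- byrow(P[, "a"] * P[, "vinf"]) * pow_base(base, P[, "m"])
  } else if (id == 5) {
    tn <- pow_cols(times, P[, "n"])
    base <- byrow(P[, "a"]) * tn / (byrow(P[, "c"]) + byrow(P[, "b"]) * tn)
    V <- byrow(P[, "d"]) * pow_base(base, P[, "m"])
  } else if (id == 6) {
    tn <- pow_cols(times, P[, "n"])
    V <- byrow(P[, "a"]) * tn / (1 + byrow(P[, "b"]) * tn)
  } else if (id == 7) {
    u <- 1 - exp(-outer(times, P[, "a"]))
    w <- 1 - exp(-outer(times, P[, "b"]))
    V <- byrow(P[, "vinf"]) * u / (1 + byrow(P[, "c"]) * w)
  } else {
    tn <- pow_cols(times, P[, "n"])
    u <- 1 - exp(-tn * byrow(P[, "a"]))
    w <- 1 - exp(-tn * byrow(P[, "b"]))
    V <- byrow(P[, "vinf"]) * u / (1 + byrow(P[, "c"]) * w)
  }
  V
}

# elementwise base^m with per-column exponents; 0^m := 0
pow_base <- function(base, m) {
  out <- base * 0
  pos <- base > 0
  if (any(pos)) {
    mm <- matrix(m, nrow(base), ncol(base), byrow = TRUE)
    out[pos] <- exp(log(base[pos]) * mm[pos])
  }
  out
}

#' Evaluate an empirical clogging model
#'
#' Computes the predicted cumulative volume `v(t)` for one of the eight
#' empirical fractional models. Every model satisfies `v(0) = 0`.
#'
#' @inheritParams model_spec
#' @param params Named numeric vector or list of parameter values (fixed
#'   parameters such as model 5's `d` may be omitted).
#' @param times Non-negative time values.
#' @return Numeric vector of predicted volumes, one per time.
#' @examples
#' evaluate_model(6, c(a = 2, b = 1, n = 1), times = c(0, 1, 10))
#' @export
evaluate_model <- function(model, params, times) {
  spec <- model_spec(model)
  full <- complete_params(spec, params)
  times <- as.numeric(times)
  if (any(!is.finite(times)) || any(times < 0)) {
    stop_domain("`times` must be finite and non-negative.")
  }
  check_denominators(spec, full)
  unname(drop(eval_batch(spec, matrix(full, nrow = 1), times)))
}

# with positive parameters no denominator can vanish on t >= 0; name the
# offending parameter otherwise
check_denominators <- function(spec, full) {
  bad <- switch(as.character(spec$id),
    `1` = if (full["b"] <= 0) "b",
    `3` = if (full["a"] <= 0) "a",
    `5` = if (full["c"] <= 0) "c" else if (full["b"] < 0) "b",
    `6` = if (full["b"] <= 0) "b",
    `7` = if (full["c"] < 0) "c",
    `8` = if (full["c"] < 0) "c",
    NULL)
  if (!is.null(bad)) {
    stop_domain(paste0("Parameter '", bad, "' = ", full[bad],
                       " makes a denominator vanish for some t >= 0."))
  }
  invisible(NULL)
}

#' Asymptotic volume of a model
#'
#' The t -> infinity limit of the model curve: the predicted maximal
#' cumulative volume at which the membrane is fully clogged. Model 1
#' diverges when `n > m` and decays to zero when `n < m`; the other models
#' always saturate under positive parameters.
#'
#' @inheritParams evaluate_model
#' @return A list with `value` (the limit; `Inf` when divergent) and
#'   `finite` (logical divergence flag).
#' @examples
#' asymptotic_volume(6, c(a = 3, b = 2))$value  # 1.5
#' @export
asymptotic_volume <- function(model, params) {
  spec <- model_spec(model)
  # exponents are irrelevant to most limits; tolerate their absence
  p <- as.list(params)
  getp <- function(nm) {
    if (!is.null(p[[nm]])) as.numeric(p[[nm]])
    else if (nm %in% names(spec$fixed)) spec$fixed[[nm]]
    else stop_usage(paste0("Model ", spec$id, " asymptote needs parameter '", nm, "'."))
  }
  lim <- switch(as.character(spec$id),
    `1` = {
      n <- getp("n"); m <- getp("m")
      if (n > m) Inf else if (n < m) 0 else getp("a") / getp("b")
    },
    `2` = getp("vinf"),
    `3` = getp("vinf"),
    `4` = getp("a") * getp("vinf"),
    `5` = getp("d") * (getp("a") / getp("b"))^getp("m"),
    `6` = getp("a") / getp("b"),
    `7` = getp("vinf") / (1 + getp("c")),
    `8` = getp("vinf") / (1 + getp("c")))
  list(value = lim, finite = is.finite(lim))
}

#' Invert model 6: time as a function of volume
#'
#' Model 6, `v = a t^n / (1 + b t^n)`, inverts in closed form to
#' `t = (v / (a - b v))^{1/n}` on `0 <= v < a/b`. This inverse underlies the
#' analytic clogging-index route.
#'
#' @param params Named vector with `a`, `b`, `n` (all positive).
#' @param v Volume value(s) in `[0, a/b)`.
#' @return Time value(s).
#' @export
model6_inverse <- function(params, v) {
  p <- complete_params(model_spec(6), params)
  a <- p["a"]; b <- p["b"]; n <- p["n"]
  if (a <= 0 || b <= 0 || n <= 0) stop_domain("Model 6 requires a, b, n > 0.")
  v <- as.numeric(v)
  if (any(!is.finite(v)) || any(v < 0) || any(v >= a / b)) {
    stop_domain(paste0("Volume must lie in [0, a/b) = [0, ", a / b,
                       "): the asymptote is unreachable in finite time."))
  }
  unname((v / (a - b * v))^(1 / n))
}

#' Analytic derivatives of the model-6 inverse map
#'
#' First and second derivatives of `t(v) = g(v)^m`, with
#' `g = v / (a - b v)` and `m = 1/n`:
#' `dt/dv = m g^{m-1} g'` and
#' `d2t/dv2 = m (m-1) g^{m-2} g'^2 + m g^{m-1} g''`, where
#' `g' = a/(a - b v)^2` and `g'' = 2 a b/(a - b v)^3`. For `n = 1` these
#' reduce to `a/(a-bv)^2` and `2ab/(a-bv)^3`, which obey the exact
#' standard-blocking identity `d2t/dv2 = (2b/sqrt(a)) (dt/dv)^{3/2}`.
#'
#' `dt/dv` is strictly positive on the open domain; `d2t/dv2` is strictly
#' positive whenever `n <= 1` (for `n > 1` the volume-time curve is S-shaped
#' and the early-time second derivative is negative).
#'
#' @inheritParams model6_inverse
#' @param v Volume value(s) strictly inside `(0, a/b)`.
#' @return A tibble with columns `v`, `dt_dv`, `d2t_dv2`.
#' @export
model6_derivatives <- function(params, v) {
  p <- complete_params(model_spec(6), params)
  a <- p["a"]; b <- p["b"]; n <- p["n"]
  if (a <= 0 || b <= 0 || n <= 0) stop_domain("Model 6 requires a, b, n > 0.")
  v <- as.numeric(v)
  if (any(!is.finite(v)) || any(v <= 0) || any(v >= a / b)) {
    stop_domain(paste0("Volume must lie strictly inside (0, a/b) = (0, ",
                       a / b, ")."))
  }
  m <- 1 / n
  den <- a - b * v
  g <- v / den
  g1 <- a / den^2
  g2 <- 2 * a * b / den^3
  dt <- m * g^(m - 1) * g1
  d2t <- m * (m - 1) * g^(m - 2) * g1^2 + m * g^(m - 1) * g2
  tibble(v = v, dt_dv = unname(dt), d2t_dv2 = unname(d2t))
}

# Default search bounds per parameter class. v_max is the largest observed
# volume (amplitude parameters must bracket the eventual asymptote); t_range
# is the span of positive observation times, which limits the pure time
# rates the data can resolve.
default_bounds <- function(spec, v_max, t_range = c(0.01, 100)) {
  cls <- spec$classes[spec$free]
  lower <- vapply(cls, function(cl) switch(cl,
    amplitude = 0.1 * v_max, rate = 1e-6, volume_rate = 1e-6 * v_max,
    time_rate = 0.01 / t_range[2], gain = 1e-3,
    inverse_volume = 1e-9 / v_max, exponent = 0.05), 0)
  upper <- vapply(cls, function(cl) switch(cl,
    amplitude = 10 * v_max, rate = 1e6, volume_rate = 1e6 * v_max,
    time_rate = 10 / t_range[1], gain = 1e3,
    inverse_volume = 1e6 / v_max, exponent = 10), 0)
  list(lower = setNames(lower, spec$free), upper = setNames(upper, spec$free))
}
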