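# Unified blocking law of constant-pressure filtration:
#
#   d2t/dv2 = k (dt/dv)^N,   t(0) = 0,  dt/dv(0) = 1/q0
#
# N identifies the mechanism (0 cake, 1 intermediate, 1.5 standard,
# 2 complete). Writing p = dt/dv, p(v) integrates in closed form:
#   N = 1:      p = e^{k v} / q0
#   N != 1:     p = [q0^{N-1} + (1-N) k v]^{1/(1-N)}
# and a second integration gives t(v); for N > 1 the admissible volume is
# bounded by v_inf = q0^{N-1} / ((N-1) k).

hermia_vinf <- function(N, k, q0) {
  if (N > 1) q0^(N - 1) / ((N - 1) * k) else Inf
}

#' Filtration time as a function of volume under the Hermia law
#'
#' Closed-form `t(v)` for arbitrary clogging index `N >= 0`.
#'
#' @param v Cumulative volume value(s), within the admissible range
#'   (`v < v_inf` when `N > 1`).
#' @param N Clogging index.
#' @param k Filtration (clogging) constant, > 0.
#' @param q0 Initial volumetric flow `dv/dt` at `t = 0`, > 0.
#' @return Time value(s).
#' @export
hermia_time <- function(v, N, k, q0) {
  check_hermia_args(N, k, q0)
  v <- as.numeric(v)
  if (any(!is.finite(v)) || any(v < 0)) stop_domain("`v` must be finite and >= 0.")
  vinf <- hermia_vinf(N, k, q0)
  if (any(v >= vinf)) {
    stop_domain(paste0("Requested volume reaches or exceeds the blocking asymptote v_inf = ",
                       signif(vinf, 8), " (N = ", N, ")."))
  }
  if (N == 1) {
    (exp(k * v) - 1) / (k * q0)
  } else if (N == 2) {
    log(q0 / (q0 - k * v)) / k
  } else {
    u <- q0^(N - 1) + (1 - N) * k * v
    (u^((2 - N) / (1 - N)) - q0^(N - 2)) / ((2 - N) * k)
  }
}

#' Cumulative volume as a function of time under the Hermia law
#'
#' Closed-form inverse of [hermia_time()].
#'
#' @param t Time value(s), >= 0. For `N > 2` the flow stops at a finite
#'   time; beyond it a domain error is raised.
#' @inheritParams hermia_time
#' @return Volume value(s).
#' @export
hermia_volume <- function(t, N, k, q0) {
  check_hermia_args(N, k, q0)
  t <- as.numeric(t)
  if (any(!is.finite(t)) || any(t < 0)) stop_domain("`t` must be finite and >= 0.")
  if (N == 1) {
    log1p(k * q0 * t) / k
  } else if (N == 2) {
    (q0 / k) * (1 - exp(-k * t))
  } else {
    arg <- q0^(N - 2) + (2 - N) * k * t
    if (any(arg <= 0)) {
      stop_domain(paste0("Time beyond the finite stopping time for N = ", N, "."))
    }
    u <- arg^((1 - N) / (2 - N))
    (u - q0^(N - 1)) / ((1 - N) * k)
  }
}

check_hermia_args <- function(N, k, q0) {
  if (!is.finite(N) || N < 0) stop_domain("Clogging index `N` must be finite and >= 0.")
  if (!is.finite(k) || k <= 0) stop_domain("Filtration constant `k` must be > 0.")
  if (!is.finite(q0) || q0 <= 0) stop_domain("Initial flow `q0` must be > 0.")
  invisible(NULL)
}

#' Simulate a constant-pressure filtration curve from the Hermia law
#'
#' Samples the blocking-law solution either on a uniform time grid (volumes
#' from the closed form, or from numerical integration of the governing
#' ODE with `method = "ode"`) or on a uniform volume grid (times from the
#' closed form). The ODE route integrates `dv/dt = q`,
#' `dq/dt = -k q^{3-N}` with [deSolve::lsoda] at tight tolerances and
#' exists mainly as an independent cross-check of the closed forms.
#'
#' @inheritParams hermia_time
#' @param n_points Number of samples (>= 3).
#' @param horizon Largest time (required for `grid = "time"`).
#' @param v_max Largest volume (required for `grid = "volume"`; must be
#'   below `v_inf` when `N > 1`).
#' @param grid `"time"` or `"volume"`.
#' @param method `"closed"` (default) or `"ode"`.
#' @param label Optional series label.
#' @return A [filtration_series]; the generating `N`, `k`, `q0` are kept in
#'   the `"truth"` attribute.
#' @examples
#' simulate_hermia(N = 2, k = 0.5, q0 = 1, n_points = 5, horizon = 4)
#' @export
simulate_hermia <- function(N, k, q0, n_points = 200, horizon = NULL,
                            v_max = NULL, grid = c("time", "volume"),
                            method = c("closed", "ode"), label = NULL) {
  grid <- match.arg(grid)
  method <- match.arg(method)
  check_hermia_args(N, k, q0)
  if (n_points < 3) stop_insufficient("`n_points` must be >= 3.")
  vinf <- hermia_vinf(N, k, q0)
  if (grid == "volume") {
    if (is.null(v_max)) stop_config("`v_max` is required for a volume grid.")
    if (v_max >= vinf) {
      stop_domain(paste0("`v_max` must be below v_inf = ", signif(vinf, 8), "."))
    }
    v <- v_max * seq_len(n_points) / n_points
    t <- if (method == "closed") {
      hermia_time(v, N, k, q0)
    } else {
      ode_over_volume(v, N, k, q0)
    }
  } else {
    if (is.null(horizon)) stop_config("`horizon` is required for a time grid.")
    if (horizon <= 0) stop_config("`horizon` must be > 0.")
    t <- horizon * seq_len(n_points) / n_points
    v <- if (method == "closed") {
      hermia_volume(t, N, k, q0)
    } else {
      ode_over_time(t, N, k, q0)
    }
  }
  out <- filtration_series(data.frame(time = t, volume = v),
                           label = label %||% paste0("hermia N=", N))
  attr(out, "truth") <- list(kind = "hermia", N = N, k = k, q0 = q0)
  out
}

ode_over_time <- function(t, N, k, q0) {
  deriv <- function(time, state, parms) {
    q <- state[2]
    list(c(q, -k * q^(3 - N)))
  }
  sol <- deSolve::lsoda(y = c(v = 0, q = q0), times = c(0, t), func = deriv,
                        parms = NULL, rtol = 1e-11,
                        atol = 1e-14 * max(q0 * max(t), 1))
  unname(sol[-1, "v"])
}

ode_over_volume <- function(v, N, k, q0) {
  deriv <- function(vol, state, parms) {
    p <- state[2]
    list(c(p, k * p^N))
  }
  sol <- deSolve::lsoda(y = c(t = 0, p = 1 / q0), times = c(0, v), func = deriv,
                        parms = NULL, rtol = 1e-11,
                        atol = 1e-14 * max(max(v) / q0, 1))
  unname(sol[-1, "t"])
}

#' Classify the clogging mechanism from the index N
#'
#' Maps the fitted clogging index to the canonical Hermia mechanisms: 0
#' cake filtration, 1 intermediate blocking, 1.5 standard blocking, 2
#' complete blocking. Values within `tol` of a canonical index take its
#' label; values between two canonical indices are labelled
#' `"mixed: <lower>/<upper>"`.
#'
#' @param N Clogging index (finite).
#' @param tol Closeness tolerance around the canonical values; default 0.05.
#' @return A mechanism label string.
#' @examples
#' classify_mechanism(1.5028)
#' classify_mechanism(1.347)
#' @export
classify_mechanism <- function(N, tol = 0.05) {
  if (!is.finite(N)) stop_domain("`N` must be finite.")
  canon <- c(cake = 0, intermediate = 1, standard = 1.5, complete = 2)
  d <- abs(N - canon)
  if (min(d) <= tol + 1e-9) return(names(canon)[which.min(d)])
  if (N < 0) return("unclassified (N < 0)")
  if (N > 2) return("unclassified (N > 2)")
  lo <- max(which(canon < N))
  paste0("mixed: ", names(canon)[lo], "/", names(canon)[lo + 1])
}

#' Estimate the clogging index from a filtration curve
#'
#' Recovers the blocking-law exponent `N` and constant `k` by ordinary
#' least-squares regression of `ln(d2t/dv2)` on `ln(dt/dv)`; the slope is
#' `N`, the intercept `C` gives `k = exp(C)`.
#'
#' Two derivative routes are provided. For a raw [filtration_series], both
#' derivatives are estimated by centered finite differences of `t` with
#' respect to `v`, after which a fraction of points is trimmed at each end
#' (derivatives are ill-conditioned as `v -> 0` and near the asymptote).
#' For a fitted model-6 `clog_fit`, the analytic derivatives of the
#' model-6 inverse map are evaluated on a volume grid below the fitted
#' asymptote `a/b` — the preferred route, since model 6 fits these curves
#' well with the fewest constants. Points with non-positive derivative
#' estimates are excluded and counted.
#'
#' @param source A [filtration_series] or a model-6 `clog_fit`.
#' @param ... Passed to methods.
#' @return A `hermia_fit` object with fields `N`, `C`, `k`, `r_squared`,
#'   `mechanism`, `n_points_used`, `n_excluded`, `method`.
#' @export
estimate_clogging_index <- function(source, ...) {
  UseMethod("estimate_clogging_index")
}

#' @rdname estimate_clogging_index
#' @param trim Fraction of points dropped at each end (default 0.1).
#' @param min_points Minimum usable points after trimming and exclusion.
#' @export
estimate_clogging_index.filtration_series <- function(source, trim = 0.1,
                                                      min_points = 10, ...) {
  t <- source$time; v <- source$volume
  M <- length(t)
  i <- 2:(M - 1)
  dv2 <- v[i + 1] - v[i - 1]
  dt_dv <- (t[i + 1] - t[i - 1]) / dv2
  d2t_dv2 <- 2 * ((t[i + 1] - t[i]) / (v[i + 1] - v[i]) -
                    (t[i] - t[i - 1]) / (v[i] - v[i - 1])) / dv2
  k_trim <- floor(trim * M)
  keep <- i >= (1 + k_trim) & i <= (M - k_trim)
  hermia_regression(dt_dv[keep], d2t_dv2[keep], method = "finite_diff",
                    min_points = min_points,
                    note = paste0("trim = ", trim, " (", k_trim,
                                  " points per end)"))
}

#' @rdname estimate_clogging_index
#' @param n_grid Number of volume grid points for the analytic route.
#' @param v_range Volume interval over which the analytic derivatives are
#'   evaluated. Defaults to the observed volume range of the fitted series
#'   (clipped below the fitted asymptote `a/b`): the fitted curve only
#'   represents the data there, and extrapolating the derivatives towards
#'   `v = 0` or the asymptote injects model behaviour the data never
#'   constrained.
#' @export
estimate_clogging_index.clog_fit <- function(source, n_grid = 200,
                                             v_range = NULL,
                                             min_points = 10, ...) {
  if (!identical(source$model_id, 6L) && !identical(source$model_id, 6)) {
    stop_usage("The analytic derivative route requires a model-6 fit.")
  }
  p <- source$params
  a <- p[["a"]]; b <- p[["b"]]
  if (is.null(v_range)) {
    obs <- source$data$observed
    v_range <- c(max(min(obs), 1e-9 * a / b), min(max(obs), 0.99 * a / b))
  }
  if (v_range[1] <= 0 || v_range[2] >= a / b || v_range[1] >= v_range[2]) {
    stop_domain("`v_range` must lie strictly inside (0, a/b).")
  }
  v <- seq(v_range[1], v_range[2], length.out = n_grid)
  d <- model6_derivatives(c(a = a, b = b, n = p[["n"]]), v)
  hermia_regression(d$dt_dv, d$d2t_dv2, method = "analytic",
                    min_points = min_points,
                    note = paste0("model-6 grid: ", n_grid, " points on [",
                                  signif(v_range[1], 6), ", ",
                                  signif(v_range[2], 6), "]"))
}

#' Analytic clogging index of a model-6 curve
#'
#' Evaluates the analytic derivatives of the model-6 inverse map on a
#' uniform volume grid `(0, v_upper_frac * a/b]` and regresses
#' `ln(d2t/dv2)` on `ln(dt/dv)`. For `n = 1` the relation is an exact
#' power law with slope 1.5 (standard blocking) and intercept
#' `ln(2 b / sqrt(a))`.
#'
#' @param a,b,n Model-6 parameters (positive).
#' @inheritParams estimate_clogging_index.clog_fit
#' @inheritParams estimate_clogging_index.filtration_series
#' @return A `hermia_fit`.
#' @examples
#' clogging_index_model6(a = 2, b = 1, n = 1)$N  # exactly 1.5
#' @export
clogging_index_model6 <- function(a, b, n = 1, n_grid = 200,
                                  v_upper_frac = 0.9, min_points = 10) {
  v_hi <- v_upper_frac * a / b
  v <- v_hi * seq_len(n_grid) / n_grid
  d <- model6_derivatives(c(a = a, b = b, n = n), v)
  hermia_regression(d$dt_dv, d$d2t_dv2, method = "analytic",
                    min_points = min_points,
                    note = paste0("model-6 grid: ", n_grid, " points on (0, ",
                                  signif(v_hi, 6), "]"))
}

hermia_regression <- function(dt_dv, d2t_dv2, method, min_points = 10,
                              note = NULL) {
  ok <- is.finite(dt_dv) & is.finite(d2t_dv2) & dt_dv > 0 & d2t_dv2 > 0
  n_excluded <- sum(!ok)
  x <- log(dt_dv[ok]); y <- log(d2t_dv2[ok])
  if (length(x) < min_points) {
    stop_insufficient(paste0("Only ", length(x), " usable points for the ",
                             "log-log regression (need >= ", min_points, "; ",
                             n_excluded, " excluded",
                             if (!is.null(note)) paste0("; ", note), ")."))
  }
  if (stats::sd(x) == 0) {
    stop_clogfit("ln(dt/dv) is constant: the log-log regression is degenerate.",
                 "clogfit_degenerate_regression_error")
  }
  fit <- lm(y ~ x)
  r2 <- suppressWarnings(summary(fit)$r.squared)  # exact power laws fit perfectly
  N <- unname(coef(fit)[2]); C <- unname(coef(fit)[1])
  structure(list(N = N, C = C, k = exp(C), r_squared = r2,
                 mechanism = classify_mechanism(N),
                 n_points_used = length(x), n_excluded = n_excluded,
                 method = method, note = note,
                 data = tibble(ln_dt_dv = x, ln_d2t_dv2 = y)),
            class = "hermia_fit")
}

#' @export
print.hermia_fit <- function(x, ...) {
  cat("<hermia_fit> N = ", signif(x$N, 6), " (", x$mechanism, ")",
      " | k = ", signif(x$k, 6), " | R2 = ", signif(x$r_squared, 6),
      " | ", x$n_points_used, " points (", x$method, ")\n", sep = "")
  invisible(x)
}

#' @export
tidy.hermia_fit <- function(x, ...) {
  tibble(term = c("N", "C", "k"),
         estimate = c(x$N, x$C, x$k))
}

#' @export
glance.hermia_fit <- function(x, ...) {
  tibble(N = x$N, C = x$C, k = x$k, r_squared = x$r_squared,
         mechanism = x$mechanism, n_points_used = x$n_points_used,
         n_excluded = x$n_excluded, method = x$method)
}
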