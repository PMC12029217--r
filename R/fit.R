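#' Fitting configuration
#'
#' Controls the global-search protocol: `n_restarts` independent
#' dragonfly-algorithm searches (default 10), each polished by a damped
#' least-squares (Levenberg-Marquardt) step, keeping the best point found
#' overall. The search minimizes the relative root mean squared error
#' (nRMSE) by default; the refinement minimizes the sum of squared
#' residuals from each swarm optimum, and a refined point is kept only when
#' it does not degrade the configured objective.
#'
#' @param n_restarts Independent swarm searches (>= 1); default 10.
#' @param swarm_size Agents per search (>= 2); default 30.
#' @param n_iterations Swarm updates per search (>= 1); default 500.
#' @param seed Integer base seed; restart `r` uses `seed + r - 1`.
#' @param bounds Optional named list of `c(lower, upper)` per parameter,
#'   overriding the scale-aware defaults.
#' @param refine Run the Levenberg-Marquardt refinement? Default `TRUE`.
#' @param objective `"nRMSE"` (default) or `"SSR"`.
#' @return A `fit_config` object.
#' @export
fit_config <- function(n_restarts = 10, swarm_size = 30, n_iterations = 500,
                       seed = 1L, bounds = NULL, refine = TRUE,
                       objective = c("nRMSE", "SSR")) {
  objective <- match.arg(objective)
  if (n_restarts < 1) stop_config("`n_restarts` must be >= 1.")
  if (swarm_size < 2) stop_config("`swarm_size` must be >= 2.")
  if (n_iterations < 1) stop_config("`n_iterations` must be >= 1.")
  if (!is.null(bounds)) {
    ok <- is.list(bounds) && !is.null(names(bounds)) &&
      all(vapply(bounds, function(b) length(b) == 2 && all(is.finite(b)) &&
                   b[1] > 0 && b[1] <= b[2], TRUE))
    if (!ok) stop_config("`bounds` must be a named list of positive c(lower, upper) pairs.")
  }
  structure(list(n_restarts = as.integer(n_restarts),
                 swarm_size = as.integer(swarm_size),
                 n_iterations = as.integer(n_iterations),
                 seed = as.integer(seed), bounds = bounds,
                 refine = isTRUE(refine), objective = objective),
            class = "fit_config")
}

#' Local least-squares refinement
#'
#' Polishes a parameter point with the Levenberg-Marquardt algorithm
#' ([minpack.lm::nls.lm]) under box constraints. Returns a point whose sum
#' of squared residuals is never above that of the starting point: if the
#' local step fails or degrades the fit, the starting point is returned.
#'
#' @param residual_fn Function mapping a named parameter vector to the
#'   vector of residuals (observed - predicted).
#' @param init Named starting parameter vector, within bounds.
#' @param lower,upper Named bound vectors.
#' @return The refined (or original) named parameter vector.
#' @export
refine_local <- function(residual_fn, init, lower, upper) {
  r0 <- tryCatch(residual_fn(init), error = function(e) NA_real_)
  if (any(!is.finite(r0))) {
    warn("Residuals non-finite at the starting point; refinement skipped.")
    return(init)
  }
  safe_fn <- function(p) {
    r <- tryCatch(residual_fn(p), error = function(e) rep(1e150, length(r0)))
    r[!is.finite(r)] <- 1e150
    r
  }
  out <- tryCatch(
    suppressWarnings(minpack.lm::nls.lm(
      par = init, lower = lower, upper = upper, fn = safe_fn,
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                           ptol = 1e-15)
    )),
    error = function(e) NULL
  )
  if (is.null(out)) {
    warn("Levenberg-Marquardt refinement failed; starting point returned.")
    return(init)
  }
  p_new <- pmin(pmax(out$par, lower), upper)
  if (sum(safe_fn(p_new)^2) > sum(r0^2)) init else p_new
}

# assemble the full parameter matrix (spec$params order) from a free-only one
full_param_matrix <- function(spec, P_free) {
  P_free <- matrix(P_free, ncol = spec$n_free)
  full <- matrix(0, nrow(P_free), length(spec$params))
  colnames(full) <- spec$params
  full[, spec$free] <- P_free
  for (nm in names(spec$fixed)) full[, nm] <- spec$fixed[[nm]]
  full
}

# per-column objective values for a batch of free-parameter rows
objective_batch <- function(spec, P_free, times, y, objective) {
  V <- eval_batch(spec, full_param_matrix(spec, P_free), times)
  R <- V - y
  ssr <- colSums(R^2)
  if (objective == "SSR") {
    val <- ssr
  } else {
    mcal <- colMeans(V)
    val <- 100 * sqrt(ssr / length(y)) / mcal
    val[!is.finite(val) | mcal <= 0] <- 1e300
  }
  val[!is.finite(val)] <- 1e300
  val
}

# model-specific identifiable combinations, reported alongside the raw
# parameters (models 4 and 5 are over-parametrized)
derived_quantities <- function(spec, p) {
  id <- as.character(spec$id)
  if (id == "standard") {
    return(c(v_inf = unname(2 * sqrt(p["q0"]) / p["ks"])))
  }
  if (id == "combined") {
    vs_inf <- 2 * sqrt(p["q0"]) / p["ks"]
    return(c(v_inf = unname(log1p(p["ki"] * vs_inf) / p["ki"])))
  }
  asym <- asymptotic_volume(spec, p)
  out <- c(v_inf = unname(asym$value))
  if (spec$id == 4) out <- c(out, a_vinf = unname(p["a"] * p["vinf"]))
  if (spec$id == 5) {
    out <- c(out,
             amplitude = unname(p["d"] * (p["a"] / p["c"])^p["m"]),
             rate = unname(p["b"] / p["c"]))
  }
  out
}

#' Fit an empirical clogging model to a filtration series
#'
#' Runs `n_restarts` independent dragonfly-algorithm searches over the
#' (log-transformed) parameter box minimizing the configured objective
#' (nRMSE by default), refines each restart's optimum with a bounded
#' Levenberg-Marquardt step, keeps the best point overall, and returns the
#' fitted model with the full goodness-of-fit suite.
#'
#' Ties across restarts are broken by the lowest restart index. All
#' parameters are strictly positive and searched in log space; default
#' bounds adapt the rate box to the volume scale of the data.
#'
#' @param series A [filtration_series] (or a data frame with `time` and
#'   `volume` columns).
#' @param model Model id 1-8, model name, or a spec from [model_spec()].
#' @param config A [fit_config()].
#' @return A `clog_fit` object; see [tidy.clog_fit()], [glance.clog_fit()],
#'   [augment.clog_fit()] and [autoplot.clog_fit()].
#' @examples
#' \donttest{
#' fs <- generate_series(list(model = 6, params = c(a = 2, b = 1, n = 1.2)),
#'                       horizon = 10, n_points = 60, seed = 1)
#' fit <- fit_model(fs, 6, fit_config(n_restarts = 2, n_iterations = 150, seed = 1))
#' glance(fit)
#' }
#' @export
fit_model <- function(series, model, config = fit_config()) {
  spec <- if (inherits(model, "clog_model")) model else model_spec(model)
  if (!inherits(series, "filtration_series")) {
    series <- filtration_series(as.data.frame(series))
  }
  stopifnot(inherits(config, "fit_config"))
  times <- series$time; y <- series$volume
  M <- length(y)
  if (M <= spec$n_free) {
    stop_insufficient(paste0("Model ", spec$id, " has ", spec$n_free,
                             " free parameters but the series has only ", M,
                             " points (need M > dim)."))
  }
  t_pos <- times[times > 0]
  b <- default_bounds(spec, max(y), range(t_pos))
  if (!is.null(config$bounds)) {
    for (nm in intersect(names(config$bounds), spec$free)) {
      b$lower[nm] <- config$bounds[[nm]][1]
      b$upper[nm] <- config$bounds[[nm]][2]
    }
  }
  ll <- log(b$lower); uu <- log(b$upper)

  obj_log <- function(XL) {
    objective_batch(spec, exp(XL), times, y, config$objective)
  }
  obj_of <- function(p) objective_batch(spec, matrix(p, 1), times, y, config$objective)
  resid_fn <- function(p) {
    y - drop(eval_batch(spec, full_param_matrix(spec, matrix(p, 1)), times))
  }
  # each restart: one swarm search, locally refined; the refined point is
  # kept when it does not degrade the reported objective (the LM step
  # minimizes SSR, whose optimum differs slightly from nRMSE's)
  restarts <- purrr::map(seq_len(config$n_restarts), function(r) {
    da <- dragonfly_search(obj_log, ll, uu, swarm_size = config$swarm_size,
                           n_iterations = config$n_iterations,
                           seed = config$seed + r - 1L, vectorized = TRUE)
    par <- setNames(exp(da$par), spec$free)
    val <- obj_of(par)
    refined <- FALSE
    if (config$refine && val < 1e300) {
      lm_par <- refine_local(resid_fn, par, b$lower, b$upper)
      lm_val <- obj_of(lm_par)
      if (lm_val <= val + 1e-12) {
        refined <- !identical(unname(lm_par), unname(par))
        par <- lm_par
        val <- min(val, lm_val)
      }
    }
    list(par = par, value = val, refined = refined)
  })
  values <- purrr::map_dbl(restarts, "value")
  if (all(values >= 1e300)) {
    stop_fit(paste0("All ", config$n_restarts,
                    " restarts produced non-finite objectives for model ",
                    spec$id, "."))
  }
  best_i <- which.min(values)  # ties -> lowest index
  final_par <- restarts[[best_i]]$par
  refined <- restarts[[best_i]]$refined

  params <- c(final_par, spec$fixed)[spec$params]
  v_fit <- drop(eval_batch(spec, matrix(params, 1), times))
  metrics <- metric_suite(y, v_fit, dim = spec$n_free)
  structure(list(
    model_id = spec$id,
    model_name = spec$name,
    spec = spec,
    params = params,
    derived = derived_quantities(spec, params),
    objective = config$objective,
    objective_value = unname(obj_of(final_par)),
    restart_objectives = values,
    refined = refined,
    seed = config$seed,
    config = config,
    bounds = b,
    metrics = metrics,
    regression = regression_vector(y, v_fit),
    quality = classify_fit(metrics),
    data = tibble(time = times, observed = y, fitted = v_fit),
    series_label = attr(series, "label")
  ), class = "clog_fit")
}

#' Fit several models and rank them by nRMSE
#'
#' @inheritParams fit_model
#' @param models Vector of model ids/names (default all eight).
#' @return A `clog_fit_set`: a tibble ranked by nRMSE with one row per
#'   model (`model_id`, `name`, `n_params`, `nRMSE`, `R2`, `SSR`, quality
#'   labels) and the fitted objects in the `fit` list-column.
#' @export
fit_models <- function(series, models = 1:8, config = fit_config()) {
  fits <- purrr::map(models, function(m) fit_model(series, m, config))
  ranking_table(fits)
}

ranking_table <- function(fits) {
  out <- purrr::map_dfr(fits, function(f) {
    tibble(model_id = as.character(f$model_id), name = f$model_name,
           n_params = f$spec$n_free,
           nRMSE = f$metrics$nRMSE, R2 = f$metrics$R2, SSR = f$metrics$SSR,
           R2_label = f$quality$R2_label, nRMSE_label = f$quality$nRMSE_label)
  })
  out$fit <- fits
  out <- dplyr::arrange(out, .data$nRMSE)
  class(out) <- c("clog_fit_set", class(out))
  out
}

#' Fit a Hermia-law reference model
#'
#' Fits one of the two theory-based reference curves used for side-by-side
#' comparison with the empirical models: the integrated standard-blocking
#' law `v(t) = q0 t / (1 + (ks sqrt(q0)/2) t)` (2 parameters), or a
#' reconstructed combined intermediate-to-standard model in the Bolton
#' serial-composition form `v(t) = ln(1 + Ki vs(t)) / Ki` with `vs` the
#' standard-blocking curve (3 parameters). The combined model nests the
#' standard one (Ki -> 0), so its SSR can never be meaningfully higher; the
#' fit additionally refines from the standard solution with Ki at its lower
#' bound to guarantee this numerically.
#'
#' @inheritParams fit_model
#' @param which `"standard"` or `"combined"`.
#' @return A `clog_fit`, with `model_id` `"standard"` or `"combined"`.
#' @export
reference_model_fit <- function(series, which = c("standard", "combined"),
                                config = fit_config()) {
  which <- match.arg(which)
  spec <- ref_model_spec(which)
  fit <- fit_model(series, spec, config)
  if (which == "combined") {
    std <- fit_model(series, ref_model_spec("standard"), config)
    b <- fit$bounds
    init <- c(q0 = unname(std$params["q0"]), ks = unname(std$params["ks"]),
              ki = unname(b$lower["ki"]))
    init <- pmin(pmax(init, b$lower), b$upper)
    times <- fit$data$time; y <- fit$data$observed
    resid_fn <- function(p) {
      y - drop(eval_batch(spec, full_param_matrix(spec, matrix(p, 1)), times))
    }
    alt <- refine_local(resid_fn, init, b$lower, b$upper)
    ssr_of <- function(p) sum(resid_fn(p)^2)
    if (ssr_of(alt) < ssr_of(fit$params)) {
      v_fit <- y - resid_fn(alt)
      metrics <- metric_suite(y, v_fit, dim = spec$n_free)
      fit$params <- alt[spec$params]
      fit$derived <- derived_quantities(spec, fit$params)
      fit$metrics <- metrics
      fit$objective_value <- unname(
        objective_batch(spec, matrix(alt, 1), times, y, config$objective))
      fit$regression <- regression_vector(y, v_fit)
      fit$quality <- classify_fit(metrics)
      fit$data$fitted <- v_fit
      fit$refined <- TRUE
    }
  }
  fit
}

ref_model_spec <- function(which) {
  if (which == "standard") {
    classes <- c(q0 = "volume_rate", ks = "rate")
    name <- "hermia-standard-blocking"
  } else {
    classes <- c(q0 = "volume_rate", ks = "rate", ki = "inverse_volume")
    name <- "combined-intermediate-standard"
  }
  structure(list(id = which, name = name, params = names(classes),
                 free = names(classes), fixed = numeric(0),
                 classes = classes, n_free = length(classes)),
            class = "clog_model")
}

#' Compare empirical and reference models on one series
#'
#' Fits the requested empirical models plus the standard-blocking and
#' combined reference models and returns the ranked comparison table
#' (nRMSE, R2, SSR per model).
#'
#' @inheritParams fit_models
#' @param reference Character vector among `"standard"`, `"combined"`.
#' @return A `clog_fit_set` tibble (see [fit_models()]).
#' @export
compare_models <- function(series, models = 1:8,
                           reference = c("standard", "combined"),
                           config = fit_config()) {
  fits <- c(
    purrr::map(models, function(m) fit_model(series, m, config)),
    purrr::map(reference, function(w) reference_model_fit(series, w, config))
  )
  ranking_table(fits)
}

#' @export
print.clog_fit <- function(x, ...) {
  cat("<clog_fit> model ", x$model_id, " (", x$model_name, ")\n", sep = "")
  cat("  parameters: ",
      paste(names(x$params), signif(x$params, 6), sep = " = ", collapse = ", "),
      "\n", sep = "")
  cat("  ", x$objective, " = ", signif(x$objective_value, 6),
      " | R2 = ", signif(x$metrics$R2, 6),
      " (", x$quality$R2_label, "; nRMSE ", x$quality$nRMSE_label, ")\n",
      sep = "")
  invisible(x)
}

#' Tidy a fitted clogging model
#'
#' @param x A `clog_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `estimate`,
#'   `fixed`, `lower`, `upper`, plus rows for derived identifiable
#'   quantities (marked in `kind`).
#' @export
tidy.clog_fit <- function(x, ...) {
  spec <- x$spec
  base <- tibble(
    term = spec$params,
    estimate = unname(x$params[spec$params]),
    fixed = spec$params %in% names(spec$fixed),
    lower = unname(x$bounds$lower[spec$params]),
    upper = unname(x$bounds$upper[spec$params]),
    kind = "parameter"
  )
  der <- tibble(term = names(x$derived), estimate = unname(x$derived),
                fixed = FALSE, lower = NA_real_, upper = NA_real_,
                kind = "derived")
  dplyr::bind_rows(base, der)
}

#' One-row summary of a fitted clogging model
#'
#' @param x A `clog_fit`.
#' @param ... Unused.
#' @return A one-row tibble: model identity, the full metric suite, the
#'   calculated-vs-observed regression vector and the quality labels.
#' @export
glance.clog_fit <- function(x, ...) {
  dplyr::bind_cols(
    tibble(model_id = as.character(x$model_id), name = x$model_name,
           objective = x$objective, objective_value = x$objective_value,
           refined = x$refined, seed = x$seed),
    x$metrics, x$regression, x$quality
  )
}

#' Observation-level results of a fitted clogging model
#'
#' @param x A `clog_fit`.
#' @param ... Unused.
#' @return The observed series with `.fitted` and `.resid` columns.
#' @export
augment.clog_fit <- function(x, ...) {
  dplyr::mutate(x$data, .fitted = .data$fitted, .resid = .data$observed - .data$fitted,
                fitted = NULL)
}

#' Predict volumes from a fitted clogging model
#'
#' @param object A `clog_fit`.
#' @param times Non-negative times at which to predict.
#' @param ... Unused.
#' @return Numeric vector of predicted volumes.
#' @export
predict.clog_fit <- function(object, times, ...) {
  drop(eval_batch(object$spec, matrix(object$params, 1), as.numeric(times)))
}
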