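#' Plot a filtration series
#'
#' @param object A [filtration_series].
#' @param ... Unused.
#' @return A ggplot: cumulative volume against time.
#' @export
autoplot.filtration_series <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$time, y = .data$volume)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = paste0("time (", attr(object, "time_unit") %||% "min", ")"),
                  y = "cumulative volume",
                  title = attr(object, "label")) +
    ggplot2::theme_minimal()
}

#' Plot a fitted clogging model over the observations
#'
#' @param object A `clog_fit`.
#' @param n_curve Number of points for the smooth fitted curve.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.clog_fit <- function(object, n_curve = 200, ...) {
  tt <- seq(0, max(object$data$time), length.out = n_curve)
  curve <- tibble(time = tt, fitted = predict(object, tt))
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed), alpha = 0.7) +
    ggplot2::geom_line(data = curve, ggplot2::aes(y = .data$fitted),
                       color = "#2166ac") +
    ggplot2::labs(x = "time", y = "cumulative volume",
                  title = paste0("model ", object$model_id, " (",
                                 object$model_name, ")"),
                  subtitle = paste0("nRMSE = ",
                                    signif(object$metrics$nRMSE, 4), "%")) +
    ggplot2::theme_minimal()
}

#' Overlay plot of a ranked model set
#'
#' @param object A `clog_fit_set` from [fit_models()] or [compare_models()].
#' @param n_curve Points per fitted curve.
#' @param ... Unused.
#' @return A ggplot with the observed points and one curve per model.
#' @export
autoplot.clog_fit_set <- function(object, n_curve = 200, ...) {
  fits <- object$fit
  obs <- fits[[1]]$data
  tt <- seq(0, max(obs$time), length.out = n_curve)
  curves <- purrr::map_dfr(fits, function(f) {
    tibble(model = paste0(f$model_id, ": ", f$model_name),
           time = tt, fitted = predict(f, tt))
  })
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed), alpha = 0.6) +
    ggplot2::geom_line(data = curves,
                       ggplot2::aes(y = .data$fitted, color = .data$model)) +
    ggplot2::labs(x = "time", y = "cumulative volume", color = NULL) +
    ggplot2::theme_minimal()
}

#' Log-log diagnostic plot of a clogging-index estimate
#'
#' Shows the points of the `ln(d2t/dv2)` versus `ln(dt/dv)` regression and
#' the fitted line whose slope is the clogging index N.
#'
#' @param object A `hermia_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hermia_fit <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$ln_dt_dv, y = .data$ln_d2t_dv2)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = object$N, intercept = object$C,
                         color = "#b2182b") +
    ggplot2::labs(x = "ln(dt/dv)", y = expression(ln(d^2 * t / d * v^2)),
                  title = paste0("N = ", signif(object$N, 5), " (",
                                 object$mechanism, ")")) +
    ggplot2::theme_minimal()
}
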