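#' Goodness-of-fit metric suite
#'
#' The statistical error indices used to judge a fitted clogging curve
#' against the observations:
#' \describe{
#'   \item{SSR}{sum of squared residuals, `sum((y_exp - y_cal)^2)`}
#'   \item{R2}{`1 - SSR / sum((y_exp - mean(y_exp))^2)`}
#'   \item{VAF}{variance accounted for, `(1 - var(y_exp - y_cal)/var(y_exp)) * 100`,
#'     with population variances (divide by M)}
#'   \item{RMSE / nRMSE}{`sqrt(SSR/M)`; nRMSE normalizes by the mean of the
#'     *calculated* values, in percent}
#'   \item{MAE / nMAE}{mean absolute error and its percent version, same
#'     normalization}
#'   \item{Chi / nChi}{reduced chi-square `SSR/(M - dim)` and its percent
#'     version, same normalization}
#'   \item{SEP}{standard error of prediction, `RMSE / mean(y_exp) * 100`}
#' }
#' Note the n-prefixed metrics are normalized by the mean of the calculated
#' (not observed) values; SEP is the one normalized by the observed mean.
#' Percentages are stored on the percent scale (an nRMSE of 2.5 means 2.5%).
#'
#' @param y_exp Observed (experimental) volumes.
#' @param y_cal Calculated (model-predicted) volumes.
#' @param dim Number of free model parameters (enters the reduced
#'   chi-square denominator `M - dim`).
#' @return A one-row tibble with columns `SSR`, `R2`, `VAF`, `RMSE`,
#'   `nRMSE`, `MAE`, `nMAE`, `Chi`, `nChi`, `SEP`, `M`, `dim`.
#' @examples
#' metric_suite(c(1, 2, 3), c(1, 2, 4), dim = 1)
#' @export
metric_suite <- function(y_exp, y_cal, dim) {
  y_exp <- as.numeric(y_exp); y_cal <- as.numeric(y_cal)
  M <- length(y_exp)
  if (length(y_cal) != M) {
    stop_validation("`y_exp` and `y_cal` must have equal length.")
  }
  if (any(!is.finite(y_exp)) || any(!is.finite(y_cal))) {
    stop_validation("Metric inputs must be finite.")
  }
  if (M <= dim) {
    stop_insufficient(paste0("Reduced chi-square undefined: M = ", M,
                             " points but dim = ", dim, " parameters."))
  }
  mean_cal <- mean(y_cal)
  mean_exp <- mean(y_exp)
  if (mean_cal <= 0) {
    stop_clogfit(paste0("Cannot normalize: mean of calculated values is ",
                        mean_cal, " (must be > 0)."),
                 "clogfit_normalization_error")
  }
  if (mean_exp <= 0) {
    stop_clogfit("Cannot normalize: mean of observed values must be > 0.",
                 "clogfit_normalization_error")
  }
  e <- y_exp - y_cal
  ssr <- sum(e^2)
  tss <- sum((y_exp - mean_exp)^2)
  if (tss == 0) {
    stop_clogfit("Observed values are constant: R2 undefined.",
                 "clogfit_degenerate_regression_error")
  }
  pvar <- function(x) mean((x - mean(x))^2)  # population variance, / M
  rmse <- sqrt(ssr / M)
  mae <- mean(abs(e))
  chi <- ssr / (M - dim)
  tibble(
    SSR = ssr,
    R2 = 1 - ssr / tss,
    VAF = (1 - pvar(e) / pvar(y_exp)) * 100,
    RMSE = rmse,
    nRMSE = rmse / mean_cal * 100,
    MAE = mae,
    nMAE = mae / mean_cal * 100,
    Chi = chi,
    nChi = chi / mean_cal * 100,
    SEP = rmse / mean_exp * 100,
    M = M,
    dim = as.integer(dim)
  )
}

#' Classify fit quality
#'
#' Maps R2 and nRMSE to the conventional accuracy bands: R2 above 0.9 is
#' excellent and above 0.5 satisfactory; nRMSE below 10% is excellent,
#' 10-20% good, 20-30% fair, above 30% low. Band boundaries are assigned to
#' the better class (an nRMSE of exactly 10 is still "excellent").
#'
#' @param metrics A one-row data frame or named list containing `R2` and
#'   `nRMSE` (as returned by [metric_suite()]).
#' @return A one-row tibble with `R2_label` and `nRMSE_label`.
#' @examples
#' classify_fit(list(R2 = 0.95, nRMSE = 2.3))
#' @export
classify_fit <- function(metrics) {
  r2 <- as.numeric(metrics[["R2"]])
  nrmse <- as.numeric(metrics[["nRMSE"]])
  if (is.na(r2) || is.na(nrmse)) stop_validation("`metrics` must contain finite R2 and nRMSE.")
  r2_label <- if (r2 > 0.9) "excellent" else if (r2 > 0.5) "satisfactory" else "unsatisfactory"
  nrmse_label <- if (nrmse <= 10) "excellent" else if (nrmse <= 20) "good" else
    if (nrmse <= 30) "fair" else "low"
  tibble(R2_label = r2_label, nRMSE_label = nrmse_label)
}

#' Calculated-versus-observed regression vector
#'
#' Ordinary least-squares line of the calculated volumes against the
#' observed ones. For an ideal model the vector is (slope, intercept,
#' correlation) = (1, 0, 1).
#'
#' @inheritParams metric_suite
#' @return A one-row tibble with `alpha` (slope), `beta` (intercept) and
#'   `R` (Pearson correlation).
#' @export
regression_vector <- function(y_exp, y_cal) {
  y_exp <- as.numeric(y_exp); y_cal <- as.numeric(y_cal)
  if (length(y_exp) != length(y_cal) || length(y_exp) < 3) {
    stop_validation("Need >= 3 paired observations.")
  }
  if (var(y_exp) == 0) {
    stop_clogfit("Observed values are constant: regression is degenerate.",
                 "clogfit_degenerate_regression_error")
  }
  fit <- lm(y_cal ~ y_exp)
  r <- if (var(y_cal) == 0) NA_real_ else unname(cor(y_exp, y_cal))
  tibble(alpha = unname(coef(fit)[2]), beta = unname(coef(fit)[1]), R = r)
}
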