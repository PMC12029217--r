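#' Write a structured fit or mechanism report
#'
#' Serializes a `clog_fit` or `hermia_fit` to JSON with stable key names,
#' at full numeric precision, so reports round-trip losslessly through
#' [read_report()]. A fit report carries the parameters, bounds, derived
#' quantities, the ten-metric suite, the regression vector, quality labels,
#' per-restart objectives, the seed and the fitted curve; a mechanism
#' report carries `N`, `C`, `k`, the regression R2 and the mechanism label.
#'
#' @param result A `clog_fit` or `hermia_fit`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path) {
  rep <- if (inherits(result, "clog_fit")) {
    list(
      type = "fit",
      package = "clogfit",
      version = as.character(utils::packageVersion("clogfit")),
      model_id = result$model_id,
      model_name = result$model_name,
      params = as.list(result$params),
      fixed = as.list(result$spec$fixed),
      derived = as.list(result$derived),
      bounds = list(lower = as.list(result$bounds$lower),
                    upper = as.list(result$bounds$upper)),
      objective = result$objective,
      objective_value = result$objective_value,
      restart_objectives = result$restart_objectives,
      refined = result$refined,
      seed = result$seed,
      config = result$config[c("n_restarts", "swarm_size", "n_iterations",
                               "refine", "objective")],
      metrics = as.list(result$metrics),
      regression = as.list(result$regression),
      quality = as.list(result$quality),
      series_label = result$series_label,
      data = as.list(result$data)
    )
  } else if (inherits(result, "hermia_fit")) {
    list(
      type = "hermia",
      package = "clogfit",
      version = as.character(utils::packageVersion("clogfit")),
      N = result$N, C = result$C, k = result$k,
      r_squared = result$r_squared,
      mechanism = result$mechanism,
      n_points_used = result$n_points_used,
      n_excluded = result$n_excluded,
      method = result$method,
      note = result$note,
      data = as.list(result$data)
    )
  } else {
    stop_usage("`result` must be a clog_fit or hermia_fit.")
  }
  ok <- tryCatch({
    suppressWarnings(jsonlite::write_json(rep, path, auto_unbox = TRUE,
                                          digits = NA, null = "null"))
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop_clogfit(paste0("Cannot write report to '", path, "': ",
                        conditionMessage(ok)), "clogfit_io_error")
  }
  invisible(path)
}

#' Read a report written by [write_report()]
#'
#' @param path Path to a JSON report.
#' @return A `clog_fit` or `hermia_fit` object (fit reports are rebuilt
#'   without the search configuration's bounds overrides).
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop_format(paste0("File not found: ", path))
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(rep$type, "fit")) {
    id <- rep$model_id
    spec <- if (is.character(id)) ref_model_spec(id) else model_spec(id, free_d = length(rep$fixed) == 0)
    structure(list(
      model_id = if (is.character(id)) id else as.integer(id),
      model_name = rep$model_name,
      spec = spec,
      params = unlist(rep$params)[spec$params],
      derived = unlist(rep$derived),
      objective = rep$objective,
      objective_value = rep$objective_value,
      restart_objectives = rep$restart_objectives,
      refined = rep$refined,
      seed = rep$seed,
      config = rep$config,
      bounds = list(lower = unlist(rep$bounds$lower),
                    upper = unlist(rep$bounds$upper)),
      metrics = as_tibble(rep$metrics),
      regression = as_tibble(rep$regression),
      quality = as_tibble(rep$quality),
      data = as_tibble(rep$data),
      series_label = rep$series_label
    ), class = "clog_fit")
  } else if (identical(rep$type, "hermia")) {
    structure(list(
      N = rep$N, C = rep$C, k = rep$k, r_squared = rep$r_squared,
      mechanism = rep$mechanism, n_points_used = rep$n_points_used,
      n_excluded = rep$n_excluded, method = rep$method, note = rep$note,
      data = as_tibble(rep$data)
    ), class = "hermia_fit")
  } else {
    stop_format(paste0("Unrecognized report type in ", path, "."))
  }
}
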