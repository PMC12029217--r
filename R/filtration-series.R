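#' Construct a filtration series
#'
#' A filtration series is the basic observation unit: ordered pairs of
#' elapsed filtration time and cumulative permeate volume recorded during a
#' constant-pressure run. It is stored as a tibble with columns `time` and
#' `volume` plus metadata attributes, so it pipes through dplyr verbs while
#' keeping validation and provenance attached.
#'
#' Validation distinguishes hard errors from soft warnings: time stamps must
#' be strictly increasing, finite, and non-negative (duplicate or reordered
#' times would bias derivative estimates downstream and are never averaged
#' away); volume dips, which real digitized data do contain, raise a warning
#' naming the offending rows but are retained.
#'
#' @param data A data frame with at least the time and volume columns.
#' @param time,volume Column names (tidy-select style strings) holding times
#'   and cumulative volumes. Defaults `"time"` and `"volume"`.
#' @param label Free-text identifier (e.g. solution + pressure).
#' @param pressure Optional operating transmembrane pressure, in psi.
#' @param time_unit Unit of the time axis; default `"min"`.
#' @param volume_unit Opaque unit tag for volumes (never converted).
#'
#' @return A `filtration_series` tibble with columns `time` and `volume`.
#' @examples
#' fs <- filtration_series(data.frame(time = 0:5, volume = c(0, 1, 1.8, 2.4, 2.8, 3)))
#' fs
#' @export
filtration_series <- function(data, time = "time", volume = "volume",
                              label = NULL, pressure = NULL,
                              time_unit = "min", volume_unit = NULL) {
  if (!is.data.frame(data)) {
    stop_validation("`data` must be a data frame of time/volume observations.")
  }
  missing_cols <- setdiff(c(time, volume), names(data))
  if (length(missing_cols) > 0) {
    stop_format(paste0("Column(s) not found in input: ",
                       paste(missing_cols, collapse = ", "), "."))
  }
  out <- tibble(time = as.numeric(data[[time]]),
                volume = as.numeric(data[[volume]]))
  validate_series_frame(out)
  structure(out,
            class = c("filtration_series", class(tibble())),
            label = label,
            pressure = pressure,
            time_unit = time_unit,
            volume_unit = volume_unit)
}

# Hard invariants (error) + soft monotonicity (warning). Row numbers in
# messages refer to the input order.
validate_series_frame <- function(df) {
  m <- nrow(df)
  if (m < 3) {
    stop_insufficient(paste0("A filtration series needs at least 3 observations; got ", m, "."))
  }
  if (anyNA(df$time) || anyNA(df$volume) ||
      any(!is.finite(df$time)) || any(!is.finite(df$volume))) {
    stop_validation("All times and volumes must be finite (no NA/Inf).")
  }
  if (any(df$time < 0) || any(df$volume < 0)) {
    stop_validation("Times and volumes must be non-negative.")
  }
  dt <- diff(df$time)
  if (any(dt <= 0)) {
    bad <- which(dt <= 0)[1] + 1L
    kind <- if (df$time[bad] == df$time[bad - 1L]) "duplicates" else "is not greater than"
    stop_validation(paste0("Time must be strictly increasing: row ", bad,
                           " (t = ", df$time[bad], ") ", kind,
                           " the previous time stamp."))
  }
  dips <- which(diff(df$volume) < 0) + 1L
  if (length(dips) > 0) {
    warn(paste0("Cumulative volume decreases at ", length(dips), " row(s) (e.g. row ",
                dips[1], "); points retained."),
         class = "clogfit_monotonicity_warning")
  }
  invisible(df)
}

#' @export
print.filtration_series <- function(x, ...) {
  lab <- attr(x, "label")
  pr <- attr(x, "pressure")
  cat("<filtration_series> ", nrow(x), " points",
      if (!is.null(lab)) paste0(" | ", lab),
      if (!is.null(pr)) paste0(" | ", pr, " psi"),
      " | time in ", attr(x, "time_unit") %||% "min", "\n", sep = "")
  NextMethod()
}

#' Read a filtration series from a delimited text file
#'
#' Reads comma- or tab-delimited time/volume tables. Columns may be
#' addressed by name (default `time` and `volume`, matched case-insensitively
#' when a header is present) or by position when `header = FALSE`.
#'
#' @param path Path to the file.
#' @param delim Field delimiter; `NULL` (default) auto-detects comma vs tab
#'   from the first line.
#' @param header Does the file carry a header row? Default `TRUE`.
#' @param time_col,volume_col Column name (with header) or 1-based position
#'   (without) of the time and volume fields.
#' @inheritParams filtration_series
#' @return A [filtration_series].
#' @export
read_series <- function(path, delim = NULL, header = TRUE,
                        time_col = "time", volume_col = "volume",
                        label = NULL, pressure = NULL,
                        time_unit = "min", volume_unit = NULL) {
  if (!file.exists(path)) {
    stop_format(paste0("File not found: ", path))
  }
  if (is.null(delim)) {
    first <- readLines(path, n = 1L, warn = FALSE)
    delim <- if (grepl("\t", first)) "\t" else ","
  }
  df <- as.data.frame(readr::read_delim(
    path, delim = delim, col_names = header, trim_ws = TRUE,
    show_col_types = FALSE, progress = FALSE
  ))
  if (nrow(df) == 0) stop_insufficient(paste0("No data rows in ", path, "."))
  pick <- function(col, what) {
    if (is.numeric(col)) {
      if (col > ncol(df)) {
        stop_format(paste0("Requested ", what, " column ", col, " but file has ",
                           ncol(df), " column(s)."))
      }
      df[[col]]
    } else {
      idx <- match(tolower(col), tolower(names(df)))
      if (is.na(idx)) {
        stop_format(paste0("Missing '", col, "' column in ", path,
                           " (found: ", paste(names(df), collapse = ", "), ")."))
      }
      df[[idx]]
    }
  }
  if (!header && is.character(time_col)) time_col <- 1L
  if (!header && is.character(volume_col)) volume_col <- 2L
  out <- data.frame(time = pick(time_col, "time"),
                    volume = pick(volume_col, "volume"))
  if (is.null(label)) label <- basename(path)
  filtration_series(out, label = label, pressure = pressure,
                    time_unit = time_unit, volume_unit = volume_unit)
}

#' Write a filtration series to a delimited text file
#'
#' @param series A [filtration_series].
#' @param path Output path.
#' @param delim Delimiter, default comma.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path, delim = ",") {
  stopifnot(inherits(series, "filtration_series"))
  readr::write_delim(as_tibble(series)[, c("time", "volume")], path,
                     delim = delim)
  invisible(path)
}
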