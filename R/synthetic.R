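#' Generate a synthetic filtration series
#'
#' Samples a noise-free clogging curve on a uniform time grid and perturbs
#' the volumes (times are exact: digitized chart data err mainly on the
#' ordinate). The generating truth is attached for recovery tests.
#'
#' @param source Either `list(model = , params = )` naming an empirical
#'   model and its parameters, or `list(N = , k = , q0 = )` for a Hermia
#'   blocking-law source.
#' @param horizon Largest time on the grid (> 0).
#' @param n_points Number of samples (>= 3).
#' @param noise_sd Noise standard deviation: a relative fraction for
#'   `"multiplicative"` noise, volume units for `"additive"`. Default 0.
#' @param noise_kind `"multiplicative"` (default) or `"additive"`.
#' @param seed Optional integer seed for reproducibility.
#' @param label Optional series label.
#' @return A [filtration_series] with a `"truth"` attribute. Noisy volumes
#'   are clipped at zero and never re-monotonized; if more than 20% of the
#'   increments are negative a generation warning reports the count.
#' @examples
#' generate_series(list(model = 6, params = c(a = 2, b = 1, n = 1)),
#'                 horizon = 10, n_points = 20, noise_sd = 0.01, seed = 1)
#' @export
generate_series <- function(source, horizon, n_points = 50, noise_sd = 0,
                            noise_kind = c("multiplicative", "additive"),
                            seed = NULL, label = NULL) {
  noise_kind <- match.arg(noise_kind)
  if (n_points < 3) stop_insufficient("`n_points` must be >= 3.")
  if (!is.numeric(horizon) || horizon <= 0) stop_config("`horizon` must be > 0.")
  if (noise_sd < 0) stop_config("`noise_sd` must be >= 0.")
  t <- horizon * seq_len(n_points) / n_points
  if (!is.null(source$N)) {
    v0 <- hermia_volume(t, source$N, source$k, source$q0)
    truth <- list(kind = "hermia", N = source$N, k = source$k, q0 = source$q0)
  } else if (!is.null(source$model)) {
    spec <- model_spec(source$model)
    v0 <- evaluate_model(spec, source$params, t)
    truth <- list(kind = "model", model_id = spec$id,
                  params = complete_params(spec, source$params))
  } else {
    stop_usage("`source` must carry either N/k/q0 (Hermia) or model/params.")
  }
  v <- v0
  if (noise_sd > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit({
        if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
      }, add = TRUE)
      set.seed(as.integer(seed))
    }
    eps <- rnorm(n_points, 0, noise_sd)
    v <- if (noise_kind == "multiplicative") v0 * (1 + eps) else v0 + eps
    v <- pmax(v, 0)
    n_dips <- sum(diff(v) < 0)
    if (n_dips > 0.2 * (n_points - 1)) {
      warn(paste0("Noise is large relative to the curve: ", n_dips, " of ",
                  n_points - 1, " increments are negative."),
           class = "clogfit_generation_warning")
    }
  }
  out <- suppressWarnings(
    filtration_series(data.frame(time = t, volume = v), label = label)
  )
  attr(out, "truth") <- c(truth, list(noise_sd = noise_sd,
                                      noise_kind = noise_kind, seed = seed))
  out
}

#' Demonstration fixture set
#'
#' Generates eight labelled series emulating the two experimental designs
#' the package targets: four "BSA-like" runs (85-minute horizon, pure
#' standard blocking N = 1.5, pressures 2/5/10/20 psi with initial flow
#' increasing in pressure, asymptotic volumes of order 1e-4) and four
#' "plasmid-like" runs (35-minute horizon, mixed indices N between 1 and
#' 1.5, asymptotic volumes of order 1e-6), each with 1% multiplicative
#' noise and a fixed per-fixture seed so regeneration is byte-identical.
#'
#' The blocking constants are set so each noise-free curve reaches roughly
#' 85-90% of its asymptote at the end of the run.
#'
#' @param seed Base seed; fixture `i` uses `seed + i`.
#' @param n_points Points per series; default 50.
#' @return A named list of eight [filtration_series] objects.
#' @export
make_demo_series <- function(seed = 101, n_points = 50) {
  # volume dips at the plateau are by design here (noise exceeds the tiny
  # late-time increments), so the generation warning is muffled
  generate_quiet <- function(...) {
    withCallingHandlers(generate_series(...),
      clogfit_generation_warning = function(w) invokeRestart("muffleWarning"))
  }
  # BSA-like: N = 1.5, v(85) ~ 0.9 v_inf  =>  ks sqrt(q0)/2 = 9/85 per min
  beta <- 9 / 85
  db01 <- tibble(
    name = paste0("db01_", c(2, 5, 10, 20), "psi"),
    pressure = c(2, 5, 10, 20),
    vinf = c(1.0e-4, 2.2e-4, 5.2e-4, 6.4e-4)
  )
  # plasmid-like: mixed intermediate/standard indices, q0 = 0.6 vinf / min
  db02 <- tibble(
    name = c("db02_pQR150_5psi", "db02_pQR150_8psi",
             "db02_pGEc47_5psi", "db02_pGEc47_8psi"),
    pressure = c(5, 8, 5, 8),
    N = c(1.35, 1.42, 1.44, 1.31),
    vinf = c(4.2e-6, 4.7e-6, 6.6e-6, 6.2e-6)
  )
  out <- list()
  for (i in seq_len(4)) {
    q0 <- db01$vinf[i] * beta
    ks <- 2 * beta / sqrt(q0)
    out[[db01$name[i]]] <- generate_quiet(
      list(N = 1.5, k = ks, q0 = q0), horizon = 85, n_points = n_points,
      noise_sd = 0.01, noise_kind = "multiplicative", seed = seed + i,
      label = paste0("BSA-like ", db01$pressure[i], " psi"))
    attr(out[[db01$name[i]]], "pressure") <- db01$pressure[i]
  }
  for (i in seq_len(4)) {
    N <- db02$N[i]
    q0 <- 0.6 * db02$vinf[i]
    k <- q0^(N - 1) / ((N - 1) * db02$vinf[i])
    out[[db02$name[i]]] <- generate_quiet(
      list(N = N, k = k, q0 = q0), horizon = 35, n_points = n_points,
      noise_sd = 0.01, noise_kind = "multiplicative", seed = seed + 4 + i,
      label = paste0(sub("db02_", "", db02$name[i]), " (plasmid-like)"))
    attr(out[[db02$name[i]]], "pressure") <- db02$pressure[i]
  }
  out
}
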