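#' Dragonfly-algorithm global search
#'
#' Box-constrained global minimization with the dragonfly swarm algorithm:
#' agents move under five behaviours (separation, alignment, cohesion,
#' attraction to the best position found, distraction from the worst), with
#' inertia and behaviour weights decaying linearly over iterations and a
#' Levy flight for agents with no neighbours. Used by [fit_model()] to find
#' starting values for local refinement; exposed directly for testing and
#' reuse.
#'
#' @param fn Objective function. By default it receives a single parameter
#'   vector and returns a scalar; with `vectorized = TRUE` it receives a
#'   matrix (one point per row) and returns one value per row. Non-finite
#'   values are treated as +Inf.
#' @param lower,upper Finite per-dimension bounds.
#' @param swarm_size Number of agents (>= 2); default 30.
#' @param n_iterations Number of swarm updates (>= 1); default 500.
#' @param seed Optional integer seed; given the same seed the search is
#'   fully reproducible. The caller's RNG state is restored on exit.
#' @param vectorized Does `fn` accept a matrix of points?
#' @return A list: `par` (best point found), `value` (its objective),
#'   `trace` (best-so-far objective per iteration, non-increasing).
#' @examples
#' res <- dragonfly_search(function(x) sum((x - 2)^2), lower = -5, upper = 5,
#'                         swarm_size = 20, n_iterations = 100, seed = 1)
#' res$value
#' @export
dragonfly_search <- function(fn, lower, upper, swarm_size = 30,
                             n_iterations = 500, seed = NULL,
                             vectorized = FALSE) {
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  if (length(lower) == 0 || length(lower) != length(upper)) {
    stop_config("`lower` and `upper` must be non-empty and of equal length.")
  }
  if (any(!is.finite(lower)) || any(!is.finite(upper))) {
    stop_config("Bounds must be finite.")
  }
  if (any(lower > upper)) {
    stop_config("Every lower bound must be <= its upper bound.")
  }
  if (swarm_size < 2) stop_config("`swarm_size` must be >= 2.")
  if (n_iterations < 1) stop_config("`n_iterations` must be >= 1.")

  batch <- if (vectorized) {
    function(X) {
      v <- as.numeric(fn(X))
      v[!is.finite(v)] <- 1e300
      v
    }
  } else {
    function(X) {
      v <- apply(X, 1, function(p) {
        out <- tryCatch(as.numeric(fn(p))[1], error = function(e) NA_real_)
        out
      })
      v[!is.finite(v)] <- 1e300
      v
    }
  }

  run <- function() .da_core(batch, lower, upper, as.integer(swarm_size),
                             as.integer(n_iterations))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  out <- run()
  names(out$par) <- names(lower)
  out
}
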