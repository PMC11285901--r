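# Time integration of the kinetic system and asymptotic-outcome labelling.

#' Simulate the model forward in time
#'
#' Integrates the initial-value problem with a compiled adaptive embedded
#' Runge-Kutta (Dormand-Prince 5(4)) solver at relative tolerance `1e-8` and
#' absolute tolerance `1e-10`, sampling the solution on a uniform grid of at
#' least 500 time points. Components that dip below zero by round-off
#' (magnitude below `1e-9`) are clipped to exactly zero, so returned states
#' are non-negative. The system's rates span roughly `1e-3` to `1` per
#' month, a mild stiffness ratio of order `1e3` for which the explicit
#' adaptive method is accurate and cheap.
#'
#' @param init An [ad_state()] or numeric 5-vector (u, up, m, M, I), all
#'   components non-negative.
#' @param p An [ad_params()] object.
#' @param t_end Final time in months (> 0).
#' @param n_out Number of output samples (>= 2; default 500).
#' @param rtol,atol Solver tolerances.
#' @return An object of class `ad_trajectory`: list with `times` (months,
#'   starting at 0), `states` (`n_out` x 5 matrix, columns u, up, m, M, I)
#'   and `params`.
#' @examples
#' p <- ad_params("table2", d = 0.15)
#' tr <- simulate_model(ad_state("table3", I = 0.4), p, t_end = 500)
#' tail(as.data.frame(tr), 1)
#' @export
simulate_model <- function(init, p, t_end, n_out = 500L,
                           rtol = 1e-8, atol = 1e-10) {
  p <- validate_ad_params(p)
  y0 <- .as_state_vec(init)
  if (any(y0 < 0)) stop("initial state must be non-negative")
  if (!is.finite(t_end) || t_end <= 0) stop("t_end must be positive")
  n_out <- max(2L, as.integer(n_out))
  times <- seq(0, t_end, length.out = n_out)
  states <- ad_integrate_cpp(y0, unclass(p), times, rtol = rtol, atol = atol)
  colnames(states) <- .state_names
  structure(list(times = times, states = states, params = p),
            class = "ad_trajectory")
}

#' @export
as.data.frame.ad_trajectory <- function(x, ...) {
  data.frame(time = x$times, x$states)
}

#' @export
print.ad_trajectory <- function(x, ...) {
  n <- length(x$times)
  cat("Trajectory over", format(x$times[n]), "months (", n, "samples )\n")
  cat("final state:\n")
  print(x$states[n, ])
  invisible(x)
}

#' Classify the asymptotic outcome of an initial condition
#'
#' Integrates on doubling horizons (default 2000, 4000, 8000 months,
#' continuing each run from the previous endpoint) until the state lies
#' within Euclidean distance `dist_tol` of one of the steady states of the
#' parameter set, then labels the run `"disease-free"` or `"persistent"`
#' according to the kind of the matched equilibrium. If no horizon decides,
#' returns `"undecided"` (a value, not an error): near the basin boundary
#' the transient can be arbitrarily long.
#'
#' The distance is unweighted: all benchmark equilibria are of order 1 or
#' smaller, so no component scaling is needed. The slowest relaxation rate
#' in the benchmark set is `sigma = 1e-3` per month (time scale `1e3`
#' months); the horizons resolve it several-fold.
#'
#' @param init An [ad_state()] or numeric 5-vector.
#' @param p An [ad_params()] object.
#' @param equilibria Optional precomputed [find_steady_states()] result
#'   (avoids re-enumeration inside parameter sweeps).
#' @param horizons Increasing integration checkpoints (months).
#' @param dist_tol Match distance to an equilibrium (mol/l).
#' @param rtol,atol Solver tolerances, passed to the integrator.
#' @return Character label: `"disease-free"`, `"persistent"` or
#'   `"undecided"`.
#' @examples
#' p <- ad_params("table2", d = 0.15)
#' classify_outcome(ad_state("table3", I = 0.15), p)  # "disease-free"
#' @export
classify_outcome <- function(init, p, equilibria = NULL,
                             horizons = c(2000, 4000, 8000),
                             dist_tol = 1e-4, rtol = 1e-8, atol = 1e-10) {
  p <- validate_ad_params(p)
  if (is.null(equilibria)) equilibria <- find_steady_states(p)
  targets <- lapply(equilibria, function(e) .as_state_vec(e$state))
  kinds <- vapply(equilibria, `[[`, character(1), "kind")

  y <- .as_state_vec(init)
  if (any(y < 0)) stop("initial state must be non-negative")
  t_prev <- 0
  for (t_h in horizons) {
    times <- seq(t_prev, t_h, length.out = 200L)
    y <- ad_integrate_cpp(y, unclass(p), times, rtol = rtol, atol = atol)[200L, ]
    dists <- vapply(targets, function(tg) sqrt(sum((y - tg)^2)), numeric(1))
    i <- which.min(dists)
    if (dists[i] < dist_tol)
      return(if (kinds[i] == "disease-free") "disease-free" else "persistent")
    t_prev <- t_h
  }
  "undecided"
}
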