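# Bifurcation branch tracing in the degradation rate d and critical
# initial-condition threshold maps (hysteresis analysis).

#' Trace the equilibrium branches over a grid of degradation rates
#'
#' For each `d` in `d_grid`, enumerates the steady states and classifies
#' their stability. For `d` below the critical rate the positive branch
#' appears as a pair (the larger interleukin equilibrium stable, the smaller
#' unstable); above it only the stable disease-free row remains. This is the
#' saddle-node bifurcation diagram in `d`, usually plotted as the
#' equilibrium interleukin concentration `I` against `d`.
#'
#' @param d_grid Positive increasing vector of degradation rates (1/month).
#' @param p An [ad_params()] object (its `d` entry is overridden per grid
#'   point; any placeholder value is accepted).
#' @return A data frame of class `ad_bifurcation` with columns `d`, `kind`,
#'   `u`, `up`, `m`, `M`, `I`, `marginal`, `max_real_eigenvalue`,
#'   `stability`.
#' @examples
#' br <- sweep_bifurcation(c(0.15, 0.35, 0.55), ad_params("table2", d = 1))
#' table(br$d, br$kind)
#' @export
sweep_bifurcation <- function(d_grid, p) {
  if (any(!is.finite(d_grid)) || any(d_grid <= 0)) stop("d_grid must be positive")
  if (is.unsorted(d_grid, strictly = TRUE)) stop("d_grid must be increasing")
  if (inherits(p, "ad_params") && is.na(unclass(p)[["d"]])) p[["d"]] <- 1
  p <- validate_ad_params(p)
  rows <- lapply(d_grid, function(d) {
    pd <- p; pd[["d"]] <- d
    df <- steady_state_table(pd)
    cbind(d = d, df)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("ad_bifurcation", "data.frame")
  out
}

#' Critical initial condition separating the two basins of attraction
#'
#' For a fixed degradation rate `d` below the critical rate, the outcome of
#' the initial-value problem flips from disease-free to persistent as the
#' initial inflammation (`axis = "I0"`) or the initial monomer load
#' (`axis = "m0"`) crosses a threshold. The threshold is located by
#' bisection on the varied component: the upper bracket is found by doubling
#' from 1 until the outcome is persistent (capped at 2^10), then the bracket
#' is narrowed to absolute width `tol` and its midpoint returned.
#'
#' Bisection assumes the outcome is monotone in the varied component, which
#' holds throughout the benchmark regime; [basin_map()] provides a
#' grid-based cross-check of that monotonicity.
#'
#' @param d Degradation rate (1/month).
#' @param axis `"I0"` (vary initial interleukins, base preset `"table3"`) or
#'   `"m0"` (vary initial monomers, base preset `"table4"`).
#' @param p An [ad_params()] object; its `d` entry is overridden.
#' @param base_init Base initial state; defaults to the preset matching
#'   `axis` with the varied component set to 0.
#' @param tol Absolute bisection tolerance (mol/l).
#' @param ... Passed to [classify_outcome()].
#' @return The critical concentration (mol/l), or `NA_real_` ("none") when
#'   `d` is at or above the critical degradation rate, or — with a warning —
#'   when no persistent outcome is found below the doubling cap.
#' @examples
#' \donttest{
#' critical_initial(0.15, "I0", ad_params("table2", d = 0.15))  # ~0.2
#' }
#' @export
critical_initial <- function(d, axis = c("I0", "m0"), p, base_init = NULL,
                             tol = 1e-3, ...) {
  axis <- match.arg(axis)
  if (!is.finite(d) || d <= 0) stop("d must be positive")
  if (inherits(p, "ad_params") && is.na(unclass(p)[["d"]])) p[["d"]] <- d
  p <- validate_ad_params(p)
  p[["d"]] <- d
  if (d >= critical_d(p)) return(NA_real_)

  comp <- if (axis == "I0") "I" else "m"
  if (is.null(base_init)) {
    base_init <- if (axis == "I0") ad_state("table3", I = 0) else
      ad_state("table4", m = 0)
  }
  base <- .as_state_vec(base_init)
  eqs <- find_steady_states(p)
  outcome_at <- function(x) {
    y <- base
    y[match(comp, .state_names)] <- x
    classify_outcome(y, p, equilibria = eqs, ...)
  }

  hi <- 1
  while (outcome_at(hi) != "persistent") {
    hi <- hi * 2
    if (hi > 2^10) {
      warning("no persistent outcome found below the doubling cap at d = ", d,
              " (possible undecided band); returning NA")
      return(NA_real_)
    }
  }
  lo <- 0
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (outcome_at(mid) == "persistent") hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Threshold curve over a grid of degradation rates
#'
#' Runs [critical_initial()] at each `d`; entries at or beyond the critical
#' degradation rate carry `NA` ("none": the disease never persists there).
#'
#' @inheritParams critical_initial
#' @param d_grid Positive increasing vector of degradation rates.
#' @return A data frame of class `ad_threshold` with columns `d`,
#'   `critical_value`, `axis`.
#' @export
threshold_curve <- function(d_grid, axis = c("I0", "m0"), p,
                            base_init = NULL, tol = 1e-3, ...) {
  axis <- match.arg(axis)
  if (any(!is.finite(d_grid)) || any(d_grid <= 0)) stop("d_grid must be positive")
  if (is.unsorted(d_grid, strictly = TRUE)) stop("d_grid must be increasing")
  vals <- vapply(d_grid, critical_initial, numeric(1),
                 axis = axis, p = p, base_init = base_init, tol = tol, ...)
  out <- data.frame(d = d_grid, critical_value = vals, axis = axis)
  class(out) <- c("ad_threshold", "data.frame")
  out
}

#' Outcome grid over degradation rate and one initial-condition axis
#'
#' Classifies the asymptotic outcome at every pair `(d, x)` of the two
#' grids, with `x` substituted into the varied component (`I0` over the
#' inflammation preset, `m0` over the monomer-load preset). The persistent
#' region lies above the threshold curve and to the left of the critical
#' degradation rate.
#'
#' @inheritParams critical_initial
#' @param d_grid Positive increasing degradation rates (1/month).
#' @param x_grid Non-negative increasing initial values (mol/l).
#' @return A data frame of class `ad_basin` with columns `d`, `x`, `axis`,
#'   `outcome`.
#' @export
basin_map <- function(d_grid, x_grid, axis = c("I0", "m0"), p,
                      base_init = NULL, ...) {
  axis <- match.arg(axis)
  if (any(!is.finite(d_grid)) || any(d_grid <= 0)) stop("d_grid must be positive")
  if (is.unsorted(d_grid, strictly = TRUE)) stop("d_grid must be increasing")
  if (any(!is.finite(x_grid)) || any(x_grid < 0)) stop("x_grid must be non-negative")
  if (is.unsorted(x_grid, strictly = TRUE)) stop("x_grid must be increasing")
  if (inherits(p, "ad_params") && is.na(unclass(p)[["d"]])) p[["d"]] <- 1
  p <- validate_ad_params(p)

  comp <- if (axis == "I0") "I" else "m"
  if (is.null(base_init)) {
    base_init <- if (axis == "I0") ad_state("table3", I = 0) else
      ad_state("table4", m = 0)
  }
  base <- .as_state_vec(base_init)
  ci <- match(comp, .state_names)

  rows <- lapply(d_grid, function(d) {
    pd <- p; pd[["d"]] <- d
    eqs <- find_steady_states(pd)
    outc <- vapply(x_grid, function(x) {
      y <- base; y[ci] <- x
      classify_outcome(y, pd, equilibria = eqs, ...)
    }, character(1))
    data.frame(d = d, x = x_grid, axis = axis, outcome = outc)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("ad_basin", "data.frame")
  out
}
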