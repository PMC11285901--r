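# Linear stability of equilibria via eigenvalues of the analytic Jacobian.

#' Classify the linear stability of an equilibrium
#'
#' Computes the eigenvalues of the analytic Jacobian [ad_jacobian()] at the
#' equilibrium state and labels it `"stable"` if every eigenvalue has real
#' part below `-tol`, `"unstable"` if some real part exceeds `+tol`, and
#' `"marginal"` otherwise. The default `tol = 1e-8` is far below the
#' smallest degradation rate in the benchmark parameter set (`1e-3`), so
#' genuine eigenvalues are well separated from the dead band.
#'
#' At the disease-free equilibrium the Jacobian is triangular up to a single
#' superdiagonal stress entry and its spectrum is
#' `{-gamma0 - tau0, -taup, -d, -sigma, -tau3}`: the disease-free state is
#' locally asymptotically stable for every positive parameter set.
#'
#' @param e An equilibrium (an element of [find_steady_states()] output) or
#'   an [ad_state()]/numeric 5-vector at which to evaluate the Jacobian.
#' @param p An [ad_params()] object.
#' @param tol Dead band around zero for the real parts.
#' @return An object of class `ad_stability`: list with `eigenvalues`
#'   (complex 5-vector, sorted by decreasing real part), `max_real_part`,
#'   and `label`.
#' @examples
#' p <- ad_params("table2", d = 0.15)
#' classify_stability(disease_free_state(p), p)$label  # "stable"
#' @export
classify_stability <- function(e, p, tol = 1e-8) {
  s <- if (is.list(e) && !is.null(e$state)) e$state else e
  J <- ad_jacobian(s, p)
  ev <- eigen(J, only.values = TRUE)$values
  ev <- ev[order(-Re(ev))]
  mx <- max(Re(ev))
  label <- if (mx < -tol) "stable" else if (mx > tol) "unstable" else "marginal"
  structure(list(eigenvalues = ev, max_real_part = mx, label = label),
            class = "ad_stability")
}

#' @export
print.ad_stability <- function(x, ...) {
  cat("Equilibrium is", x$label,
      sprintf("(max Re(eigenvalue) = %.3e)\n", x$max_real_part))
  print(x$eigenvalues)
  invisible(x)
}

#' Steady states with stability labels
#'
#' Convenience wrapper: [find_steady_states()] followed by
#' [classify_stability()] on every equilibrium.
#'
#' @param p An [ad_params()] object.
#' @param ... Passed to [find_steady_states()].
#' @return A data frame with one row per equilibrium: `kind`, the five state
#'   components, `marginal`, `max_real_eigenvalue`, `stability`.
#' @export
steady_state_table <- function(p, ...) {
  eqs <- find_steady_states(p, ...)
  df <- as.data.frame(eqs)
  st <- lapply(eqs, classify_stability, p = p)
  df$max_real_eigenvalue <- vapply(st, `[[`, numeric(1), "max_real_part")
  df$stability <- vapply(st, `[[`, character(1), "label")
  df
}
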