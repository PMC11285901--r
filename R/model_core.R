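#' Neural stress function S(u, I)
#'
#' Monomer production by stressed neurons, stimulated linearly by the
#' interleukin concentration and shut down by the unfolded protein response
#' at high oligomer load:
#' \deqn{S(u, I) = \frac{\tau_S \, I}{1 + C u^n}.}
#' At `u = 0` it equals `tauS * I`; it is monotone decreasing in `u` and
#' tends to 0 as `u` grows for fixed `I`.
#'
#' @param u Free-oligomer concentration (mol/l), `>= 0`.
#' @param I Interleukin concentration (mol/l), `>= 0`.
#' @param p An [ad_params()] object.
#' @return Production rate (mol/l/month). Vectorized over `u` and `I`.
#' @examples
#' p <- ad_params("table2", d = 0.15)
#' stress_S(0, 1, p)   # tauS * I
#' @export
stress_S <- function(u, I, p) {
  p <- validate_ad_params(p)
  if (any(!is.finite(u)) || any(!is.finite(I))) stop("u and I must be finite")
  if (any(u < 0)) stop("u must be non-negative")
  if (any(I < 0)) stop("I must be non-negative")
  p[["tauS"]] * I / (1 + p[["C"]] * u^p[["n"]])
}

#' Microglia-dependent plaque recruitment rate gamma(M)
#'
#' Saturating recruitment rate of free oligomers into amyloid plaques,
#' \deqn{\gamma(M) = \gamma_0 + \frac{\gamma_1 M}{1 + \gamma_2 M},}
#' provided for completeness. The homogeneous system studied here uses the
#' constant baseline `gamma0` (an average recruitment rate); see [ad_rhs()].
#'
#' @param M Microglial concentration (mol/l), `>= 0`.
#' @param p An [ad_params()] object.
#' @return Recruitment rate (1/month), bounded by `gamma0 + gamma1/gamma2`
#'   when `gamma2 > 0`. Vectorized over `M`.
#' @export
gamma_of_M <- function(M, p) {
  p <- validate_ad_params(p)
  if (any(!is.finite(M))) stop("M must be finite")
  if (any(M < 0)) stop("M must be non-negative")
  p[["gamma0"]] + p[["gamma1"]] * M / (1 + p[["gamma2"]] * M)
}

#' Right-hand side of the homogeneous five-species system
#'
#' Time derivatives (per month) of (u, up, m, M, I):
#' \deqn{u' = r_1 m^2 - \gamma_0 u - \tau_0 u}
#' \deqn{u_p' = \gamma_0 u - \tau_p u_p}
#' \deqn{m' = S(u, I) - d m - r_2 u m - r_1 m^2}
#' \deqn{M' = \frac{\alpha_1 u}{1 + \alpha_2 u}(\hat M - M) M - \sigma M + \lambda_M}
#' \deqn{I' = \frac{\tau_1 u}{1 + \tau_2 u} M - \tau_3 I}
#' The vector field is quasi-positive on the non-negative orthant, so
#' trajectories from non-negative data stay non-negative. `tau0` defaults to 0
#' (highly stable oligomers) but the degradation term is retained.
#'
#' @param s An [ad_state()] or numeric 5-vector (u, up, m, M, I).
#' @param p An [ad_params()] object.
#' @return Named numeric 5-vector of rates.
#' @examples
#' p <- ad_params("table2", d = 0.15)
#' ad_rhs(disease_free_state(p), p)  # all zero
#' @export
ad_rhs <- function(s, p) {
  p <- validate_ad_params(p)
  y <- .as_state_vec(s)
  setNames(ad_rhs_cpp(y, unclass(p)), .state_names)
}

#' Analytic Jacobian of the vector field
#'
#' Matrix of partial derivatives of [ad_rhs()] with respect to the state,
#' derived by hand from the kinetic equations. At the disease-free state
#' the matrix is triangular up to the single stress entry `tauS` in the
#' monomer row, and its eigenvalues are
#' `{-gamma0 - tau0, -taup, -d, -sigma, -tau3}`.
#'
#' @param s An [ad_state()] or numeric 5-vector.
#' @param p An [ad_params()] object.
#' @return A 5 x 5 numeric matrix with dimnames (u, up, m, M, I).
#' @export
ad_jacobian <- function(s, p) {
  p <- validate_ad_params(p)
  y <- .as_state_vec(s)
  u <- y[1]; m <- y[3]; M <- y[4]; I <- y[5]
  r1 <- p[["r1"]]; r2 <- p[["r2"]]; d <- p[["d"]]
  g0 <- p[["gamma0"]]; t0 <- p[["tau0"]]; tp <- p[["taup"]]
  tS <- p[["tauS"]]; t1 <- p[["tau1"]]; t2 <- p[["tau2"]]; t3 <- p[["tau3"]]
  Cc <- p[["C"]]; n <- p[["n"]]
  a1 <- p[["alpha1"]]; a2 <- p[["alpha2"]]
  Mh <- p[["Mhat"]]; sg <- p[["sigma"]]

  # d/du of u^n at u = 0: n for n = 1 (derivative 1), 0 for n > 1
  dun <- if (u > 0) n * u^(n - 1) else if (n == 1) 1 else 0
  den_s <- 1 + Cc * u^n

  J <- matrix(0, 5, 5, dimnames = list(.state_names, .state_names))
  J[1, 1] <- -g0 - t0
  J[1, 3] <- 2 * r1 * m
  J[2, 1] <- g0
  J[2, 2] <- -tp
  J[3, 1] <- -tS * I * Cc * dun / den_s^2 - r2 * m
  J[3, 3] <- -d - r2 * u - 2 * r1 * m
  J[3, 5] <- tS / den_s
  J[4, 1] <- a1 / (1 + a2 * u)^2 * (Mh - M) * M
  J[4, 4] <- a1 * u / (1 + a2 * u) * (Mh - 2 * M) - sg
  J[5, 1] <- t1 / (1 + t2 * u)^2 * M
  J[5, 4] <- t1 * u / (1 + t2 * u)
  J[5, 5] <- -t3
  J
}
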