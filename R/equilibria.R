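# Steady states of the homogeneous system via the scalar reduction in m.
#
# At a stationary point every component is an explicit function of the
# monomer concentration m:
#   u = rho m^2 (rho = r1/gamma0 with tau0 = 0; rho = r1/(gamma0 + tau0)
#   in general), up = (gamma0/taup) u, M solves a quadratic in u, and
#   I = (tau1/tau3) u/(1 + tau2 u) M.  Substituting into the monomer
#   equation leaves the scalar problem  P(m) + d = F(m).

#' Positive root of the microglial steady-state quadratic
#'
#' Solves `alpha1 u/(1 + alpha2 u) (Mhat - M) M - sigma M + lambdaM = 0`
#' for M at a given free-oligomer concentration `u`, taking the positive
#' branch. Evaluated in the rationalized, division-safe form
#' \deqn{M(u) = \frac{2 \lambda_M (1 + \alpha_2 u)}{\sqrt{\Delta(u)} + \sigma + b u}, \quad
#'       b = \sigma\alpha_2 - \hat M \alpha_1,}
#' with \eqn{\Delta(u) = (\sigma + b u)^2 + 4 \lambda_M \alpha_1 u (1 + \alpha_2 u)},
#' algebraically identical to the textbook quadratic-formula root but finite
#' and accurate at and near `u = 0`, where it reduces to `lambdaM/sigma`.
#'
#' @param u Free-oligomer concentration (mol/l), `>= 0`. Vectorized.
#' @param p An [ad_params()] object.
#' @return Microglial concentration(s) (mol/l).
#' @export
M_of_u <- function(u, p) {
  p <- validate_ad_params(p)
  if (any(!is.finite(u)) || any(u < 0)) stop("u must be finite and non-negative")
  a1 <- p[["alpha1"]]; a2 <- p[["alpha2"]]
  lM <- p[["lambdaM"]]; Mh <- p[["Mhat"]]; sg <- p[["sigma"]]
  b <- sg * a2 - Mh * a1
  disc <- (sg + b * u)^2 + 4 * lM * a1 * u * (1 + a2 * u)
  2 * lM * (1 + a2 * u) / (sqrt(disc) + sg + b * u)
}

# rho = r1 / (gamma0 + tau0): steady-state ratio u/m^2. The published
# reduction assumes tau0 = 0; keeping tau0 in the denominator makes the
# reduction exact for the retained oligomer-degradation term as well.
.rho <- function(p) p[["r1"]] / (p[["gamma0"]] + p[["tau0"]])

#' Reconstruct a full steady state from its monomer concentration
#'
#' Applies the steady-state reduction: `u = rho m^2`,
#' `up = (gamma0/taup) u`, `M = M_of_u(u)`, `I = (tau1/tau3) u/(1+tau2 u) M`,
#' where `rho = r1/(gamma0 + tau0)`. At `m = 0` this is the disease-free
#' state. If `m` is a root of the scalar stationarity equation
#' `P(m) + d = F(m)`, the returned state zeroes the full vector field.
#'
#' @param m Monomer concentration (mol/l), `>= 0`.
#' @param p An [ad_params()] object.
#' @return An [ad_state()].
#' @export
reduce_from_m <- function(m, p) {
  p <- validate_ad_params(p)
  if (!is.finite(m) || m < 0) stop("m must be finite and non-negative")
  u <- .rho(p) * m^2
  up <- p[["gamma0"]] / p[["taup"]] * u
  M <- M_of_u(u, p)
  I <- p[["tau1"]] / p[["tau3"]] * u / (1 + p[["tau2"]] * u) * M
  ad_state(u = u, up = up, m = m, M = M, I = I)
}

#' Loss and gain sides of the scalar stationarity equation
#'
#' Positive steady states are the roots `m > 0` of `P(m) + d = F(m)`:
#' `P(m) = r2 rho m^2 + r1 m` collects polymerization losses of monomers
#' (per unit monomer), and `F(m)` is the inflammation-driven production
#' chain (stress function composed with the steady-state interleukin and
#' microglia levels),
#' \deqn{F(m) = \frac{2 \tau_1 \tau_S \lambda_M \rho m (1 + \alpha_2 \rho m^2) / \tau_3}
#'  {[\sqrt{\Delta(\rho m^2)} + \sigma + b\rho m^2](1 + \tau_2 \rho m^2)(1 + C \rho^n m^{2n})}.}
#' `F(0) = 0`, `F > 0` on `m > 0`, `F -> 0` as `m -> Inf`, and
#' `F'(0) = r1 tau1 tauS lambdaM / (sigma gamma0 tau3)` when `tau0 = 0`.
#'
#' @param m Monomer concentration(s) (mol/l), `>= 0`. Vectorized.
#' @param p An [ad_params()] object.
#' @return Rate value(s) (1/month).
#' @export
F_of_m <- function(m, p) {
  p <- validate_ad_params(p)
  if (any(!is.finite(m)) || any(m < 0)) stop("m must be finite and non-negative")
  rho <- .rho(p)
  u <- rho * m^2
  a1 <- p[["alpha1"]]; a2 <- p[["alpha2"]]
  lM <- p[["lambdaM"]]; Mh <- p[["Mhat"]]; sg <- p[["sigma"]]
  b <- sg * a2 - Mh * a1
  disc <- (sg + b * u)^2 + 4 * lM * a1 * u * (1 + a2 * u)
  num <- 2 * p[["tau1"]] * p[["tauS"]] * lM * rho * m * (1 + a2 * u) / p[["tau3"]]
  den <- (sqrt(disc) + sg + b * u) * (1 + p[["tau2"]] * u) * (1 + p[["C"]] * u^p[["n"]])
  num / den
}

#' @rdname F_of_m
#' @export
P_of_m <- function(m, p) {
  p <- validate_ad_params(p)
  if (any(!is.finite(m)) || any(m < 0)) stop("m must be finite and non-negative")
  p[["r2"]] * .rho(p) * m^2 + p[["r1"]] * m
}

#' Persistence condition for positive steady states
#'
#' `TRUE` iff `sigma * gamma0 * tau3 < tau1 * tauS * lambdaM` (strict),
#' i.e. the slope of the inflammation gain `F` at the origin exceeds the
#' slope of the loss `P`, which guarantees positive steady states for small
#' monomer degradation rates `d`.
#'
#' @param p An [ad_params()] object.
#' @return Logical scalar.
#' @export
persistence_condition <- function(p) {
  p <- validate_ad_params(p)
  p[["sigma"]] * p[["gamma0"]] * p[["tau3"]] < p[["tau1"]] * p[["tauS"]] * p[["lambdaM"]]
}

# Log-spaced scan grid for the scalar equation. m_max is grown by powers of
# 10 until the polynomial loss P dominates twice the largest observed gain F,
# beyond which G = F - P - d < 0 is guaranteed (F -> 0, P -> Inf).
.scan_grid <- function(p, n_grid = 2000L, m_lo = 1e-8) {
  m_hi <- 1
  repeat {
    g <- exp(seq(log(m_lo), log(m_hi), length.out = n_grid))
    if (P_of_m(m_hi, p) > 2 * max(F_of_m(g, p)) || m_hi >= 1e8) break
    m_hi <- m_hi * 10
  }
  g
}

#' Enumerate all non-negative steady states
#'
#' Returns the always-present disease-free equilibrium plus one equilibrium
#' per sign-isolated root of `G(m) = F(m) - P(m) - d` on a log-spaced scan
#' grid, each root refined by bracketed root-finding (Brent) to relative
#' tolerance `1e-10` and expanded to a full state via [reduce_from_m()].
#' A grid point where `G` vanishes to round-off without a sign change (the
#' saddle-node tangency at the critical degradation rate) is reported as a
#' single equilibrium flagged `marginal = TRUE`.
#'
#' @param p An [ad_params()] object (must include the degradation rate `d`).
#' @param n_grid Number of scan points (default 2000).
#' @return An object of class `ad_equilibria`: a list of equilibria sorted by
#'   `m`, each a list with elements `state` ([ad_state()]), `kind`
#'   (`"disease-free"` or `"positive"`), `m_root` (`NA` for disease-free)
#'   and `marginal` (logical).
#' @examples
#' eq <- find_steady_states(ad_params("table2", d = 0.15))
#' length(eq)  # 3: disease-free + unstable + stable positive
#' @export
find_steady_states <- function(p, n_grid = 2000L) {
  p <- validate_ad_params(p)
  d <- p[["d"]]
  G <- function(m) F_of_m(m, p) - P_of_m(m, p) - d
  grid <- .scan_grid(p, n_grid)
  gv <- G(grid)
  if (any(!is.finite(gv))) stop("non-finite values of F - P - d on the scan grid")

  eqs <- list(list(state = disease_free_state(p), kind = "disease-free",
                   m_root = NA_real_, marginal = FALSE))

  sgn <- sign(gv)
  flips <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  for (i in flips) {
    root <- uniroot(G, lower = grid[i], upper = grid[i + 1],
                    tol = 1e-10 * grid[i])
    if (is.null(root$root))
      stop("failed to refine a bracketed root in [", grid[i], ", ",
           grid[i + 1], "]")
    eqs[[length(eqs) + 1L]] <- list(state = reduce_from_m(root$root, p),
                                    kind = "positive", m_root = root$root,
                                    marginal = FALSE)
  }
  # tangency: G touches zero from below without changing sign
  if (!length(flips) && any(sgn == 0)) {
    m0 <- grid[which(sgn == 0)[1]]
    eqs[[length(eqs) + 1L]] <- list(state = reduce_from_m(m0, p),
                                    kind = "positive", m_root = m0,
                                    marginal = TRUE)
  }
  ord <- order(vapply(eqs, function(e) e$state[["m"]], numeric(1)))
  structure(eqs[ord], class = "ad_equilibria")
}

#' @export
print.ad_equilibria <- function(x, ...) {
  cat(length(x), "equilibria:\n")
  print(as.data.frame(x))
  invisible(x)
}

#' @export
as.data.frame.ad_equilibria <- function(x, ...) {
  rows <- lapply(x, function(e) {
    s <- unclass(e$state)
    data.frame(kind = e$kind, u = s[["u"]], up = s[["up"]], m = s[["m"]],
               M = s[["M"]], I = s[["I"]], marginal = e$marginal)
  })
  do.call(rbind, rows)
}

#' Critical monomer degradation rate for disease persistence
#'
#' The largest degradation rate `d` admitting positive steady states,
#' `d_c = max_{m > 0} (F(m) - P(m))`: for `d < d_c` the scalar equation
#' `P + d = F` has (generically two) positive roots, for `d > d_c` none.
#' Located by a coarse log-grid scan followed by bounded golden-section /
#' parabolic maximization to tolerance `1e-8`. Returns 0 when the
#' persistence condition fails, since `F - P` then has non-positive slope at
#' the origin and no positive maximum is guaranteed.
#'
#' @param p An [ad_params()] object; its `d` entry is ignored (set to 1 if
#'   absent so validation passes).
#' @return Critical rate (1/month).
#' @examples
#' critical_d(ad_params("table2", d = 0.15))  # ~0.4779
#' @export
critical_d <- function(p) {
  if (inherits(p, "ad_params") && is.na(unclass(p)[["d"]])) p[["d"]] <- 1
  p <- validate_ad_params(p)
  if (!persistence_condition(p)) return(0)
  H <- function(m) F_of_m(m, p) - P_of_m(m, p)
  grid <- .scan_grid(p)
  hv <- H(grid)
  i <- which.max(hv)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  opt <- optimize(H, lower = lo, upper = hi, maximum = TRUE, tol = 1e-8)
  max(opt$objective, 0)
}
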