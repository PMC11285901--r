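#' @useDynLib abetadyn, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats optimize setNames uniroot
#' @importFrom utils modifyList
"_PACKAGE"

# Canonical parameter order shared with the compiled code. Do not reorder.
.param_names <- c(
  "r1", "r2", "d", "gamma0", "gamma1", "gamma2", "tau0", "taup",
  "tauS", "tau1", "tau2", "tau3", "C", "n",
  "alpha1", "alpha2", "lambdaM", "Mhat", "sigma"
)

.state_names <- c("u", "up", "m", "M", "I")

#' Model parameters for the homogeneous amyloid/inflammation system
#'
#' Constructs and validates the 19 named rate constants of the five-species
#' kinetic model. Time is measured in months and concentrations in mol/l
#' throughout; no internal rescaling is performed.
#'
#' @param preset Optional preset name. `"table2"` loads the published
#'   benchmark parameter set (the monomer degradation rate `d` is declared
#'   "variable" there and must be supplied explicitly).
#' @param ... Named parameter overrides, e.g. `d = 0.15`, `sigma = 1e-3`.
#'   Explicit values win over preset values.
#'
#' @details The fields are:
#' \describe{
#'   \item{r1}{bi-monomeric polymerization rate (l/mol/month)}
#'   \item{r2}{monomer-to-oligomer attachment rate (l/mol/month)}
#'   \item{d}{monomer degradation rate (1/month); the bifurcation parameter}
#'   \item{gamma0}{oligomer recruitment rate to plaques (1/month)}
#'   \item{gamma1, gamma2}{Michaelis-Menten coefficients of the optional
#'     microglia-dependent recruitment rate [gamma_of_M()]; unused by the
#'     homogeneous right-hand side}
#'   \item{tau0}{free-oligomer degradation rate (1/month); default 0}
#'   \item{taup}{plaque-oligomer degradation rate (1/month)}
#'   \item{tauS}{neural stress coefficient (1/month)}
#'   \item{tau1, tau2}{interleukin growth coefficients}
#'   \item{tau3}{interleukin degradation rate (1/month)}
#'   \item{C, n}{stress-function coefficient (l^n mol^-n) and power (n >= 1)}
#'   \item{alpha1, alpha2}{microglial growth coefficients}
#'   \item{lambdaM}{microglial proliferation source (mol/l/month)}
#'   \item{Mhat}{microglial carrying capacity (mol/l)}
#'   \item{sigma}{microglial degradation rate (1/month)}
#' }
#'
#' Invariants enforced: all fields non-negative and finite; `d`, `gamma0`,
#' `taup`, `tau3`, `sigma` strictly positive; `n >= 1`.
#'
#' @return An object of class `ad_params`: a named numeric vector of length 19.
#' @examples
#' p <- ad_params("table2", d = 0.15)
#' p["gamma0"]
#' @export
ad_params <- function(preset = NULL, ...) {
  vals <- setNames(rep(NA_real_, length(.param_names)), .param_names)
  if (!is.null(preset)) {
    preset <- match.arg(preset, "table2")
    vals[] <- .preset_table2[.param_names]
  }
  over <- list(...)
  if (length(over)) {
    if (is.null(names(over)) || any(names(over) == ""))
      stop("parameter overrides must be named")
    bad <- setdiff(names(over), .param_names)
    if (length(bad))
      stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    vals[names(over)] <- vapply(over, as.numeric, numeric(1))
  }
  validate_ad_params(structure(vals, class = "ad_params"))
}

# Published benchmark values. gamma1, gamma2 are not listed in the source
# table (unused by the homogeneous system); they default to 1 so that
# gamma_of_M() is well defined. tau0 = 0 is stated (negligible free-oligomer
# degradation). d is "variable" and left NA until set by the caller.
.preset_table2 <- c(
  r1 = 1e-1, r2 = 1e-1, d = NA_real_, gamma0 = 5e-2,
  gamma1 = 1, gamma2 = 1, tau0 = 0, taup = 3e-2,
  tauS = 1, tau1 = 1, tau2 = 1, tau3 = 1,
  C = 1, n = 2, alpha1 = 1, alpha2 = 1,
  lambdaM = 1e-3, Mhat = 1, sigma = 1e-3
)

#' @rdname ad_params
#' @param p An `ad_params` object to validate.
#' @export
validate_ad_params <- function(p) {
  if (!inherits(p, "ad_params")) stop("not an 'ad_params' object")
  v <- unclass(p)
  miss <- names(v)[is.na(v)]
  if (length(miss))
    stop("parameter(s) not set: ", paste(miss, collapse = ", "),
         " (the preset leaves 'd' variable; pass e.g. d = 0.15)")
  if (any(!is.finite(v))) stop("all parameters must be finite")
  if (any(v < 0)) stop("all parameters must be non-negative")
  strict <- c("d", "gamma0", "taup", "tau3", "sigma")
  zero <- strict[v[strict] <= 0]
  if (length(zero))
    stop("parameter(s) must be strictly positive: ", paste(zero, collapse = ", "))
  if (v["n"] < 1) stop("stress power n must be >= 1")
  rho <- v["r1"] / v["gamma0"]
  if (!is.finite(rho) || rho < 0) stop("derived ratio rho = r1/gamma0 invalid")
  p
}

#' @export
print.ad_params <- function(x, ...) {
  cat("Amyloid/inflammation model parameters (1/month, mol/l units):\n")
  print(unclass(x))
  invisible(x)
}

#' Model state: concentrations of the five species
#'
#' A state is the vector (u, up, m, M, I) of concentrations (mol/l): free
#' oligomers, plaque-bound oligomers, monomers, microglia, interleukins.
#'
#' @param preset Optional initial-condition preset. `"table3"` (small monomer
#'   and oligomer seed, developed microglia, `I0` variable) or `"table4"`
#'   (monomer load only, `m0` variable). The variable field must be supplied.
#' @param u,up,m,M,I Component values; explicit values win over the preset.
#'
#' @return An object of class `ad_state`: a named numeric vector of length 5.
#' @examples
#' ad_state("table3", I = 0.4)
#' ad_state(u = 0, up = 0, m = 0, M = 1, I = 0)
#' @export
ad_state <- function(preset = NULL, u = NULL, up = NULL, m = NULL,
                     M = NULL, I = NULL) {
  vals <- setNames(rep(NA_real_, 5L), .state_names)
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("table3", "table4"))
    vals[] <- if (preset == "table3") {
      c(1e-4, 0, 1e-3, 1, NA_real_)   # I0 variable
    } else {
      c(0, 0, NA_real_, 1, 0)         # m0 variable
    }
  }
  over <- list(u = u, up = up, m = m, M = M, I = I)
  for (nm in names(over)) if (!is.null(over[[nm]])) vals[nm] <- as.numeric(over[[nm]])
  miss <- names(vals)[is.na(vals)]
  if (length(miss))
    stop("state component(s) not set: ", paste(miss, collapse = ", "),
         if (!is.null(preset)) " (the preset leaves this field variable)" else "")
  if (any(!is.finite(vals))) stop("state components must be finite")
  if (any(vals < 0)) stop("state components must be non-negative")
  structure(vals, class = "ad_state")
}

#' @export
print.ad_state <- function(x, ...) {
  cat("Model state (mol/l):\n")
  print(unclass(x))
  invisible(x)
}

#' Disease-free equilibrium state
#'
#' The steady state (0, 0, 0, lambdaM/sigma, 0): no amyloid species, no
#' inflammation, microglia at their source/degradation balance.
#'
#' @param p An [ad_params()] object.
#' @return An `ad_state`.
#' @export
disease_free_state <- function(p) {
  p <- validate_ad_params(p)
  ad_state(u = 0, up = 0, m = 0, M = p[["lambdaM"]] / p[["sigma"]], I = 0)
}

# Coerce a state-like input (ad_state or bare numeric 5-vector) to numeric.
.as_state_vec <- function(s) {
  if (inherits(s, "ad_state")) return(as.numeric(unclass(s)))
  s <- as.numeric(s)
  if (length(s) != 5L) stop("a state must have 5 components (u, up, m, M, I)")
  if (any(!is.finite(s))) stop("state components must be finite")
  s
}
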