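# Shared fixtures: the benchmark parameter set and random generators.

table2 <- function(d = 0.15, ...) ad_params("table2", d = d, ...)

# Random strictly positive parameter set; rates kept in [1e-3, ~3] so that
# genuine eigenvalues stay far from the stability dead band of 1e-8.
random_params <- function() {
  draw <- function() 10^runif(1, -3, 0.5)
  ad_params(r1 = draw(), r2 = draw(), d = draw(), gamma0 = draw(),
            gamma1 = draw(), gamma2 = draw(), tau0 = 0, taup = draw(),
            tauS = draw(), tau1 = draw(), tau2 = draw(), tau3 = draw(),
            C = draw(), n = sample(1:3, 1), alpha1 = draw(), alpha2 = draw(),
            lambdaM = draw(), Mhat = draw(), sigma = draw())
}

random_state <- function(min = 0, max = 2) {
  ad_state(u = runif(1, min, max), up = runif(1, min, max),
           m = runif(1, min, max), M = runif(1, min, max),
           I = runif(1, min, max))
}

# Direct quadratic-formula root of the microglial stationary equation
# (oracle for the rationalized form used by M_of_u); valid for u > 0.
quad_M <- function(u, p) {
  a1 <- p[["alpha1"]]; a2 <- p[["alpha2"]]
  lM <- p[["lambdaM"]]; Mh <- p[["Mhat"]]; sg <- p[["sigma"]]
  b <- sg * a2 - Mh * a1
  disc <- (sg + b * u)^2 + 4 * lM * a1 * u * (1 + a2 * u)
  (sqrt(disc) - sg - b * u) / (2 * a1 * u)
}

# Central finite-difference Jacobian of ad_rhs (independent oracle);
# evaluate at states with components > h so y - e stays admissible.
fd_jacobian <- function(s, p, h = 1e-6) {
  y <- as.numeric(unclass(s))
  J <- matrix(0, 5, 5)
  for (j in 1:5) {
    e <- numeric(5); e[j] <- h
    J[, j] <- (ad_rhs(y + e, p) - ad_rhs(y - e, p)) / (2 * h)
  }
  J
}
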