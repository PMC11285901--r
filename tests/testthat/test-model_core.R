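# Stress function, recruitment rate and the vector field.

test_that("stress function matches its closed form and limits", {
  p <- table2(tauS = 1, C = 1, n = 2)
  expect_identical(stress_S(0, 1, p), 1)         # denominator is 1 at u = 0
  expect_identical(stress_S(1, 1, p), 0.5)       # 1 / (1 + 1)
  expect_equal(stress_S(2, 3, p), 0.6)           # 3 / (1 + 4)
  # monotone non-increasing in u, linear in I, vanishing at large u
  u <- seq(0, 50, length.out = 200)
  expect_true(all(diff(stress_S(u, 1, p)) <= 0))
  expect_equal(stress_S(u, 3, p), 3 * stress_S(u, 1, p))
  expect_lt(stress_S(1e6, 1, p), 1e-11)
  expect_error(stress_S(-1, 1, p), "non-negative")
  expect_error(stress_S(1, -1, p), "non-negative")
})

test_that("microglia-dependent recruitment rate gamma(M)", {
  p <- table2(gamma0 = 0.05, gamma1 = 1, gamma2 = 1)
  expect_identical(gamma_of_M(0, p), 0.05)
  expect_equal(gamma_of_M(1, p), 0.55)           # 0.05 + 1/2
  expect_equal(gamma_of_M(1e12, p), 0.05 + 1, tolerance = 1e-9)  # saturation
  expect_true(all(gamma_of_M(10^(0:10), p) <= 0.05 + 1))
  expect_error(gamma_of_M(-0.1, p), "non-negative")
})

test_that("vector field vanishes at the disease-free state and matches hand arithmetic", {
  p <- table2(d = 0.15)
  expect_identical(unname(ad_rhs(disease_free_state(p), p)), rep(0, 5))
  # term-by-term arithmetic at (1, 1, 1, 1, 1), benchmark parameters
  expect_equal(unname(ad_rhs(c(1, 1, 1, 1, 1), p)),
               c(0.1 - 0.05,            # r1 m^2 - gamma0 u
                 0.05 - 0.03,           # gamma0 u - taup up
                 0.5 - 0.15 - 0.1 - 0.1,  # S - d m - r2 u m - r1 m^2
                 0 - 1e-3 + 1e-3,       # logistic term zero at M = Mhat
                 0.5 - 1))              # tau1 u/(1+tau2 u) M - tau3 I
  expect_error(ad_rhs(c(1, NA, 1, 1, 1), p), "finite")
})

test_that("disease-free state annihilates the field for random positive parameters", {
  set.seed(421)
  for (i in 1:25) {
    p <- random_params()
    expect_equal(unname(ad_rhs(disease_free_state(p), p)), rep(0, 5),
                 tolerance = 1e-12)
  }
})

test_that("vector field is quasi-positive on the non-negative orthant", {
  set.seed(7)
  for (i in 1:50) {
    p <- if (i <= 25) table2(d = 0.15) else random_params()
    s <- as.numeric(unclass(random_state()))
    for (j in 1:5) {
      sj <- s
      sj[j] <- 0
      expect_gte(ad_rhs(sj, p)[j], 0)
    }
  }
})

test_that("parameter and state validation enforce the invariants", {
  expect_error(ad_params("table2"), "d")            # preset leaves d variable
  expect_error(table2(sigma = 0), "strictly positive")
  expect_error(table2(n = 0.5), "n must be >= 1")
  expect_error(table2(r1 = -1), "non-negative")
  expect_error(ad_params("table2", d = 0.1, bogus = 2), "unknown parameter")
  expect_error(ad_state("table3"), "I")             # variable field required
  expect_error(ad_state("table4"), "m")
  expect_error(ad_state(u = 1, up = 0, m = -1, M = 1, I = 0), "non-negative")
})
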