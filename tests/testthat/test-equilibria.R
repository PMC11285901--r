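# Steady-state reduction, the scalar equation P + d = F, enumeration and
# the critical degradation rate.

test_that("M_of_u solves the microglial quadratic and is continuous at 0", {
  p <- table2()
  expect_equal(M_of_u(0, p), 1)  # lambdaM / sigma
  for (u in 10^seq(-6, 3, length.out = 40)) {
    M <- M_of_u(u, p)
    resid <- p[["alpha1"]] * u / (1 + p[["alpha2"]] * u) *
      (p[["Mhat"]] - M) * M - p[["sigma"]] * M + p[["lambdaM"]]
    expect_lt(abs(resid), 1e-10)
  }
  for (u in c(1e-6, 1, 1e3))
    expect_equal(M_of_u(u, p), quad_M(u, p), tolerance = 1e-8)
  # continuity at the removable singularity
  expect_equal(M_of_u(1e-12, p), M_of_u(0, p), tolerance = 1e-8)
  set.seed(11)
  for (i in 1:10) {
    p <- random_params()
    u <- 10^runif(1, -4, 2)
    expect_equal(M_of_u(u, p), quad_M(u, p), tolerance = 1e-8)
  }
})

test_that("reduce_from_m reconstructs the full state from the monomer value", {
  p <- table2()
  expect_equal(unname(unclass(reduce_from_m(0, p))), c(0, 0, 0, 1, 0))
  # u = rho m^2 with rho = r1/gamma0 = 2
  expect_equal(reduce_from_m(0.1, p)[["u"]], 2 * 0.1^2)
  # at any root of the scalar equation the full field vanishes
  for (e in find_steady_states(p))
    expect_lt(max(abs(ad_rhs(e$state, p))), 1e-10 * max(1, unclass(e$state)))
})

test_that("F and P have the proven shape and slopes", {
  p <- table2()
  expect_identical(F_of_m(0, p), 0)
  expect_identical(P_of_m(0, p), 0)
  m <- 10^seq(-4, 3, length.out = 100)
  expect_true(all(F_of_m(m, p) > 0))
  expect_lt(F_of_m(1e6, p), 1e-10)           # F -> 0 at infinity
  expect_true(all(diff(P_of_m(m, p)) > 0))   # P strictly increasing
  # F'(0) = r1 tau1 tauS lambdaM / (sigma gamma0 tau3) = 2 for the benchmark
  # set, via Richardson-extrapolated forward differences (F undefined < 0)
  h <- 1e-6
  fd <- (4 * F_of_m(h, p) - F_of_m(2 * h, p)) / (2 * h)
  expect_equal(fd, 2, tolerance = 1e-6)
})

test_that("F agrees with the independent stress-chain composition", {
  # oracle: F(m) = S(u(m), I(m)) / m with the state from reduce_from_m
  for (p in list(table2(), table2(tau0 = 0.02), table2(n = 1))) {
    for (m in c(0.01, 0.1, 1)) {
      s <- reduce_from_m(m, p)
      expect_equal(F_of_m(m, p), stress_S(s[["u"]], s[["I"]], p) / m,
                   tolerance = 1e-12)
    }
  }
})

test_that("persistence condition is the printed strict inequality", {
  expect_true(persistence_condition(table2()))          # 5e-5 < 1e-3
  expect_false(persistence_condition(table2(sigma = 0.1)))  # 5e-3 > 1e-3
  # equality case: sigma gamma0 tau3 = tau1 tauS lambdaM = 1e-3
  expect_false(persistence_condition(table2(sigma = 0.02)))
})

test_that("steady-state enumeration returns residual-exact, sorted equilibria", {
  for (d in c(0.05, 0.15, 0.35, 0.55)) {
    eqs <- find_steady_states(table2(d = d))
    kinds <- vapply(eqs, `[[`, character(1), "kind")
    expect_identical(kinds[1], "disease-free")
    ms <- vapply(eqs, function(e) e$state[["m"]], numeric(1))
    expect_true(!is.unsorted(ms))
    for (e in eqs) {
      expect_lt(max(abs(ad_rhs(e$state, table2(d = d)))), 1e-8)
      if (e$kind == "positive")
        expect_true(all(unclass(e$state) > 0))
    }
  }
})

test_that("critical degradation rate brackets the fold", {
  p <- table2()
  dc <- critical_d(p)
  n_pos <- function(d)
    sum(vapply(find_steady_states(table2(d = d)), `[[`, character(1),
               "kind") == "positive")
  expect_gte(n_pos(dc - 1e-3), 2)
  expect_identical(n_pos(dc + 1e-3), 0L)
  # no persistence, no positive maximum
  expect_identical(critical_d(table2(lambdaM = 0)), 0)
  expect_identical(critical_d(table2(sigma = 0.1)), 0)
})
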