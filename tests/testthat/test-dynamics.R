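# Time integration and asymptotic-outcome classification.

test_that("equilibria are invariant under the flow", {
  p <- table2(d = 0.15)
  tr <- simulate_model(disease_free_state(p), p, t_end = 500, n_out = 50)
  expect_lt(max(abs(sweep(tr$states, 2, tr$states[1, ]))), 1e-9)
  # the stable positive equilibrium is invariant too
  eqs <- find_steady_states(p)
  stab <- eqs[[which(vapply(eqs, function(e)
    classify_stability(e, p)$label, character(1)) == "stable" &
    vapply(eqs, `[[`, character(1), "kind") == "positive")]]
  tr2 <- simulate_model(stab$state, p, t_end = 500, n_out = 50)
  expect_lt(max(abs(sweep(tr2$states, 2, tr2$states[1, ]))), 1e-6)
})

test_that("trajectories stay non-negative and bounded", {
  set.seed(31)
  cases <- c(list(ad_state("table3", I = 0.4), ad_state("table4", m = 1.5)),
             replicate(4, random_state(max = 3), simplify = FALSE))
  p <- table2(d = 0.15)
  for (init in cases) {
    tr <- simulate_model(init, p, t_end = 3000, n_out = 300)
    expect_true(all(tr$states >= 0))
    expect_true(all(is.finite(tr$states)))
    # no growth after the transient: the tail never exceeds the first half
    expect_lte(max(tr$states[151:300, ]), max(tr$states[1:150, ]) + 1e-6)
    expect_lt(max(tr$states), 1e3)
  }
})

test_that("supercritical inflammation converges to the stable positive state", {
  p <- table2(d = 0.15)
  eqs <- find_steady_states(p)
  stab <- eqs[[3]]$state  # largest-m equilibrium (stable branch)
  tr <- simulate_model(ad_state("table3", I = 0.4), p, t_end = 4000)
  final <- tr$states[nrow(tr$states), ]
  expect_lt(sqrt(sum((final - unclass(stab))^2)), 1e-4)
  # interleukin transient: interior minimum, then recovery to equilibrium
  I <- tr$states[, "I"]
  imin <- which.min(I)
  expect_gt(imin, 1)
  expect_lt(imin, length(I))
  expect_gt(I[length(I)], I[imin])
})

test_that("subcritical monomer runs show the rise-and-fall transient", {
  # monomer concentration increases to an interior maximum then decays
  p <- table2(d = 0.15)
  tr <- simulate_model(ad_state("table3", I = 0.15), p, t_end = 2000)
  m <- tr$states[, "m"]
  imax <- which.max(m)
  expect_gt(imax, 1)
  expect_lt(imax, length(m))
  expect_lt(m[length(m)], 1e-3)
})

test_that("outcome labels are robust to halving solver tolerances", {
  for (case in list(c(0.15, 0.15), c(0.35, 1.2))) {
    p <- table2(d = case[1])
    init <- ad_state("table3", I = case[2])
    base <- classify_outcome(init, p)
    half <- classify_outcome(init, p, rtol = 5e-9, atol = 5e-11)
    expect_identical(base, half)
  }
})

test_that("simulate rejects bad inputs and reports integrator failure times", {
  p <- table2(d = 0.15)
  expect_error(simulate_model(c(-1, 0, 0, 1, 0), p, 10), "non-negative")
  expect_error(simulate_model(ad_state("table3", I = 1), p, t_end = -5),
               "positive")
})
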