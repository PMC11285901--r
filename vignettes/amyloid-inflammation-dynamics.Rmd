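---
title: "Bistability and hysteresis in an amyloid/neuroinflammation kinetic model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bistability and hysteresis in an amyloid/neuroinflammation kinetic model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abetadyn)
```

## The model and its assumptions

`abetadyn` studies a deliberately reduced picture of Alzheimer's disease
kinetics: a single well-mixed tissue compartment, bi-monomeric nucleation
(two amyloid-beta monomers $m$ merge directly into a stable free oligomer
$u$, with no intermediate proto-oligomer ladder), and a constant rate
$\gamma_0$ of oligomer recruitment into inert plaques $u_p$. Microglia $M$
are activated by free oligomers and secrete interleukins $I$, which in turn
stimulate stressed neurons to produce monomers. The governing system is

$$
\begin{aligned}
u'   &= r_1 m^2 - \gamma_0 u - \tau_0 u,\\
u_p' &= \gamma_0 u - \tau_p u_p,\\
m'   &= \frac{\tau_S\, I}{1 + C u^n} - d\, m - r_2 u m - r_1 m^2,\\
M'   &= \frac{\alpha_1 u}{1 + \alpha_2 u}(\hat M - M)M - \sigma M + \lambda_M,\\
I'   &= \frac{\tau_1 u}{1 + \tau_2 u} M - \tau_3 I,
\end{aligned}
$$

with time in months and concentrations in mol/l (no internal rescaling).
The stress term $S(u, I) = \tau_S I / (1 + C u^n)$ encodes the
unfolded protein response: interleukins drive production linearly, and a
high oligomer load shuts it down. The typeset source formula for $S$ admits
a second reading, $\tau_S / (1 + C u^n I)$; we adopt the first because it is
the only one consistent with the closed-form steady-state gain $F(m)$ below
(whose denominator carries the factor $1 + C\rho^n m^{2n}$ and whose
numerator is linear in the interleukin chain) and with the $\tau_S$ entry of
the disease-free Jacobian.

The vector field is quasi-positive, so the non-negative orthant is forward
invariant and solutions are global and bounded; the test suite asserts both
properties on randomized states and trajectories. A microglia-dependent
recruitment rate $\gamma(M) = \gamma_0 + \gamma_1 M / (1 + \gamma_2 M)$ is
provided (`gamma_of_M()`) for completeness, but the homogeneous system uses
the constant $\gamma_0$. The free-oligomer degradation rate $\tau_0$ is kept
as a parameter with default 0 ("highly stable oligomers") so that the claim
that the qualitative picture survives $\tau_0 > 0$ is testable; the
oracle test of $F$ against the stress-chain composition runs with
$\tau_0 > 0$ as well.

## Steady states by scalar reduction

At a stationary point every component is an explicit function of $m$:

$$
u = \rho m^2,\qquad u_p = \tfrac{\gamma_0}{\tau_p} u,\qquad
I = \tfrac{\tau_1}{\tau_3}\tfrac{u}{1+\tau_2 u} M,
$$

and $M$ is the positive root of a quadratic in $u$. We generalize
$\rho = r_1/\gamma_0$ to $\rho = r_1/(\gamma_0 + \tau_0)$ so the reduction
stays exact when $\tau_0 > 0$; at the default $\tau_0 = 0$ they coincide.
Substituting into the monomer equation leaves the scalar problem

$$
P(m) + d = F(m),\qquad P(m) = r_2\rho m^2 + r_1 m ,
$$

with $F(0) = 0$, $F > 0$ on $m > 0$, $F(m)\to 0$ as $m \to \infty$ and
$F'(0) = r_1\tau_1\tau_S\lambda_M / (\sigma\gamma_0\tau_3)$. Positive
equilibria exist for small $d$ exactly when the persistence condition
$\sigma\gamma_0\tau_3 < \tau_1\tau_S\lambda_M$ holds (strict, following the
theorem hypothesis; `persistence_condition()` returns `FALSE` at equality).
The critical degradation rate is the height of the gain over the loss,

$$
d_c = \max_{m > 0}\,\bigl(F(m) - P(m)\bigr),
$$

computed by `critical_d()` as a 2000-point log-grid scan refined by bounded
scalar maximization (tolerance $10^{-8}$). For the packaged benchmark
parameter set:

```{r dc}
p <- ad_params("table2", d = 0.15)
critical_d(p)
```

### Numerical choices

* **Division-safe microglia root.** The textbook quadratic-formula root of
  the microglial equation is $0/0$ at $u = 0$ and cancels catastrophically
  at small $u$. `M_of_u()` multiplies through by the conjugate:
  $M = 2\lambda_M(1+\alpha_2 u) / (\sqrt{\Delta} + \sigma + b u)$ with
  $b = \sigma\alpha_2 - \hat M\alpha_1$, which is finite at $u = 0$
  (value $\lambda_M/\sigma$). Equivalence with the direct quadratic root is
  oracle-tested on a log grid of $u$.
* **Root scan domain.** The scalar equation is scanned on 2000 log-spaced
  points on $[10^{-8}, m_{\max}]$, where $m_{\max}$ is the smallest power of
  10 at which $P > 2\max F$ over the grid; beyond it $F - P - d < 0$ is
  guaranteed because $F \to 0$ while $P \to \infty$. Each sign change is
  refined by Brent's method to $10^{-10}$ relative tolerance.
* **Tangency.** At $d = d_c$ the two positive roots merge; a grid point
  where the residual vanishes without a sign change is reported as a single
  equilibrium flagged `marginal` rather than crashing or double-counting.

## Linear stability

`ad_jacobian()` is the hand-derived analytic Jacobian (finite differences
are kept to the test suite as an oracle; eigenvalues near the fold need
better than finite-difference accuracy). At the disease-free point the
matrix is triangular up to the single stress entry $\tau_S$, so its spectrum
is $\{-\gamma_0, -\tau_p, -d, -\sigma, -\tau_3\}$: the healthy state is
locally stable for *every* positive parameter set — the disease cannot start
from infinitesimal seeds; it needs a finite push. `classify_stability()`
labels an equilibrium by the largest eigenvalue real part with a dead band
of $10^{-8}$, far below the smallest benchmark rate ($10^{-3}$ per month).

```{r stab}
steady_state_table(p)
```

For every $d < d_c$ the positive pair splits as in the bifurcation diagram:
the larger-$I^*$ equilibrium is stable, the smaller is a saddle whose stable
manifold is the basin boundary.

## Time integration

No ODE solver package is available in the target environment, so the
integrator is part of the package: a compiled Dormand–Prince 5(4) embedded
pair with PI-free standard step control, relative tolerance $10^{-8}$,
absolute tolerance $10^{-10}$, and at least 500 output samples
(`simulate_model()`). The system's rates span $10^{-3}$ to $1$ per month —
a stiffness ratio of order $10^3$, mild enough that the explicit adaptive
method resolves it exactly rather than merely stably; the outcome labels are
tested to be invariant under halving both tolerances. Components that dip
below zero by round-off (magnitude under $10^{-9}$) are clipped to exactly
zero, so trajectories respect the positivity invariant; a genuinely negative
excursion aborts with the failure time in the error.

## Outcome classification and hysteresis maps

`classify_outcome()` integrates on doubling horizons (2000, 4000, 8000
months, each continuing from the last state) until the state is within
Euclidean distance $10^{-4}$ of a known equilibrium, returning
`"disease-free"`, `"persistent"`, or `"undecided"` — a value, not an error,
because transients near the basin boundary are arbitrarily long. The
horizons resolve the slowest benchmark rate ($\sigma = 10^{-3}$ per month,
time scale $10^3$ months) several-fold; the distance is unweighted because
all benchmark equilibria are $O(1)$ or smaller.

One honest corner case: starting from the all-zero state, the microglial
component approaches $\lambda_M/\sigma$ as $1 - e^{-\sigma t}$, leaving a
residual of $3.35\times 10^{-4}$ at 8000 months — larger than the match
distance. The default schedule therefore reports `"undecided"` there, and
the `horizons` argument exists for callers who want the longer answer. We
kept the default schedule rather than silently extending it.

`critical_initial()` locates the threshold value of the varied initial
component ($I_0$ over the inflammation preset, $m_0$ over the monomer
preset) by doubling from 1 until persistent (capped at $2^{10}$), then
bisecting to $10^{-3}$ mol/l. Bisection assumes the outcome is monotone in
the varied component along each column; this is asserted, not proven, in the
source analysis — `basin_map()` classifies a full grid and serves as the
cross-check that flags non-monotone columns. `threshold_curve()` returns the
sentinel `NA` ("none" in CSV) for $d \ge d_c$, which is CSV-safe where
infinity is not.

```{r thresh}
critical_initial(0.15, "I0", p)
```

Three independent estimates of $d_c$ — the scalar maximization, the $d$ at
which positive rows vanish from `sweep_bifurcation()`, and the termination
of the threshold curve — agree within grid resolution (asserted in the
acceptance tests).

## What a green test establishes — and what it does not

All quantitative checks run against the packaged benchmark parameter set
and published initial-condition presets; the model itself is an
acknowledged caricature (the source discussion stresses that only the
*ratios* of rates are biologically meaningful). Passing tests establish the
internal mathematical story — fold location, bistability window, threshold
monotonicity — not tissue realism. Known limitations, out of scope by
design: the spatial PDE variant (diffusion, chemotaxis, proto-oligomer size
ladder), oligomer-load-dependent degradation $d(u)$, impulsive dosing /
treatment schedules, global (as opposed to linear) stability, and any
fitting to clinical data. Figure-level trajectory shapes are matched
qualitatively (interior extrema of $I(t)$ and $m(t)$), not pointwise, since
the source does not specify its integrator.
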