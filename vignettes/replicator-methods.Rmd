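---
title: "Methods: replicator dynamics of information sharing and disclosure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: replicator dynamics of information sharing and disclosure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sharegame)
```

## The game and its assumptions

Two bounded-rational populations interact: online users, a fraction `x` of
whom share personal pandemic-related information with the government, and
the government, which discloses its collected information with probability
`y`. Neither player computes an equilibrium outright; both adjust their
mixed strategies gradually in the direction of higher-than-average payoff,
which is exactly what the replicator equation models.

The economics is carried by six dimensionless parameters. Without sharing
or disclosure the information is worth `V` to society. Sharing multiplies
value by `α > 1` (shared data is more precise than what the government can
collect on its own); disclosure adds `L` of planning value but costs `C`
in privacy disputes, a cost that inflates to `γC` (`γ > 1`) when the
disclosed data was user-shared, because more precise data leaks more
privacy. Every realised total is split in a fixed ratio `β : 1−β` between
users and government. The fixed split is a deliberate simplification: it
makes the welfare of each pure profile independent of `β`, and it makes
`β` a pure time-rescaling of the dynamics (it multiplies `dx/dt` and
scales `dy/dt` by `(1−β)`), so regime labels, rest points and stability
classes cannot depend on it. The test suite asserts this `β`-invariance.

Strategies live on the closed unit square, boundaries included — the
corners are precisely the long-run outcomes of interest, so validation
accepts them.

## Rest points and the interior-point sign convention

The four corners are rest points for every admissible parameter set. The
interior candidate solves the two bracketed factors of the replicator
system for zero:

$$a = \frac{L-C}{(\gamma-1)C-(\alpha-1)L}, \qquad
  b = \frac{(\alpha-1)V}{(\gamma-1)C-(\alpha-1)L}.$$

Some presentations of this model print these formulas with the denominator
negated. The two conventions matter: under the bistable benchmark
parameter set (`V=1, L=0.2, C=0.1, α=1.1, β=0.5, γ=2.5`) the negated-denominator
forms give `(-10/13, -10/13)`, outside the square, while direct
substitution into the vector field confirms the rest point at
`(10/13, 10/13)`. The package therefore derives `(a, b)` from the factors
(the form above), and keeps the other convention inspectable via
`interior_rest_point(params, printed = TRUE)`. The candidate is reported
as an equilibrium only when both coordinates are strictly inside `(0, 1)`;
a vanishing denominator (`(γ−1)C = (α−1)L`) is reported as a degenerate
diagnostic rather than a point.

The claim that the candidate is genuine is never taken on faith: tests
check `replicator_rhs` vanishes there, and that the closed-form Jacobian
matches a central finite-difference Jacobian of the vector field (absolute
tolerance `1e-6`, the square root of the `1e-12` relative accuracy of the
difference quotient) across hundreds of random parameter sets.

## Stability classification and its tolerances

Each rest point is classified from the eigenvalues of the 2×2 Jacobian:
`stable` when both real parts are negative, `unstable` when both are
positive, `saddle` for real eigenvalues of opposite sign. Real parts
within `eps_hyperbolic = 1e-9` of zero yield `non_hyperbolic`: linear
stability analysis is silent there, and pretending otherwise would
misclassify boundary cases. The threshold is far above the `~1e-16`
round-off of the closed-form entries and far below any eigenvalue the
admissible parameter ranges actually produce, so it only fires for
genuinely degenerate configurations. Complex eigenvalues are classified
by real part for robustness under arbitrary user parameters, although the
corner Jacobians are triangular (off-diagonal entries vanish identically
there) and thus always have real spectrum.

Regime classification uses the strict inequalities among
`(α−1)(V+L)` vs `(γ−1)C`, `L` vs `C`, and `αL` vs `γC`. Differences within
`eps_boundary = 1e-12` of zero are labelled `degenerate_or_other` instead
of being forced into a regime: a parameter set sitting on a bifurcation
boundary has no regime-predicted stable set, and silently assigning one
would be wrong in either direction.

## Integrating the flow

`integrate_trajectory()` uses the adaptive `lsodar` solver (deSolve) with
`rtol = 1e-9`, `atol = 1e-12`, and a root function that stops integration
once the sup-norm of the vector field falls below `conv_tol = 1e-10`.
Convergence to a boundary attractor is asymptotic, so a horizon and a
threshold are unavoidable choices; `t_max = 1e4` covers the benchmark
scenarios (whose slowest corner eigenvalue is `-0.015`) with an order of
magnitude to spare. States are projected back onto the unit square after
integration, but only cosmetically: a projection larger than `10·rtol`
raises an error, because overshoot of that size would mean the integrator,
not round-off, is wrong. A fixed-step forward-Euler integrator written
independently in the test helpers cross-checks the adaptive solution at
`t = 10` to `1e-4`.

`long_run_state()` snaps the final state to the nearest enumerated rest
point within `snap_tol = 1e-4`. The snap is deliberately conservative: an
unconverged trajectory, or a final state not within reach of any rest
point, is reported `undecided` rather than silently attributed. Interior
starts exactly on the separatrix of the bistable regime converge to the
saddle slowly (its eigenvalues are `±0.0115` on the benchmark set), which
is where the undecided diagnostics come from in practice.

## Basin probabilities

In the bistable regime the saddle `(a, b)` anchors the straight-line
approximation of the separatrix, giving the quadrilateral area
`P_C = a/2 + (1−b)/2` for the basin of (not share, disclose), and
`P_B = 1 − P_C`. A simplified single-fraction expression for `P_C`,
`1/2 + (L−C−(α−1)V)/((α−1)V−(γ−1)C)`, circulates alongside the area form;
the two are *not* algebraically equal for general parameters (they
coincide on the benchmark set only because `L−C = (α−1)V` there), and the
simplified form can leave `[0, 1]`. Both are therefore computed and
reported side by side, with the area form — the geometrically meaningful
one — as the primary quantity.

The Monte Carlo estimator draws uniform starts on the square and runs the
actual flow, so it measures the true, curved separatrix rather than the
straight-line approximation; discrepancy between it and `P_C` is
information, not failure. Uniform random sampling (not a lattice) keeps
the binomial error bar honest, and the seed is a required, reported part
of the estimate. On the benchmark bistable set, `β = 1/2` makes the flow
symmetric under swapping `x` and `y`, the separatrix is exactly the
diagonal, and the true fraction is exactly `1/2` — the one case where the
Monte Carlo run validates the area form against a known truth.

For sensitivity in `α`, the closed form `V(γC−L)/[(α−1)V−(γ−1)C]²` was
confirmed symbolically to be the exact derivative of the simplified
fraction (differentiate the fraction's numerator and denominator in `α`
and simplify: the quotient-rule numerator collapses to `−V(L−γC)`). The
report therefore shows three numbers — the closed form, a central
difference of the simplified fraction (these two must agree), and a
central difference of the area form (which may differ in sign, since the
area form is a different function of `α`) — and evaluates the qualitative
rule "`∂P_C/∂α > 0` iff `γC > L`" against each separately.

## Welfare and alignment

Welfare is the unweighted sum of both players' payoffs per profile; no
social-welfare weights are introduced because the model defines none. The
totals are computed twice, from the closed forms and as payoff-matrix cell
sums, and the two routes must agree to `1e-12` — a transcription-drift
guard, not a numerical necessity. Exact ties in the argmax are reported as
ties; the benchmark bistable set is itself tied (`αV = (V+L)−C = 1.1`), so
breaking ties silently would misreport the package's own flagship example.

A structural result emerged while implementing the alignment check:
within each of the three regimes the welfare optimum is always reachable
by the dynamics. Regime 1's defining inequalities
(`(α−1)(V+L) < (γ−1)C` and `αL > γC`) jointly imply `(α−1)V < L−C`, which
is exactly the condition for (not share, disclose) to be the optimum — so
a regime-1 game with a misaligned optimum cannot exist. In regime 2 the
two welfare contenders are the two stable corners, and in regime 3 the
conditions make (share, disclose) dominate all four profiles. Individual
and collective rationality can still diverge *probabilistically* in
regime 2: only one stable corner is optimal (outside the tied benchmark
set), and the game reaches it only from that corner's basin — which is why
`alignment_report()` attaches per-corner optimality and basin
probabilities there instead of a single flag.

## The scenario generator

`printed_scenarios()` fixes the three benchmark assignments
(`V = 1, L = 0.2, C = 0.1, β = 0.5` throughout; `α = 1.05, γ = 2`;
`α = 1.1, γ = 2.5`; `α = 1.1, γ = 1.1`) — one per regime, used as the
package's reference conditions everywhere. `sample_regime_parameters()`
rejection-samples uniform draws within default bounds
(`V ∈ (0.5, 2)`, `L ∈ (0.05, 0.5)`, `C ∈ (0.02, 0.4)`, `α ∈ (1.01, 1.5)`,
`β ∈ (0.2, 0.8)`, `γ ∈ (1.01, 3)`) until the requested regime's strict
inequalities hold. The bounds bracket the benchmark assignments with
acceptance rates comfortably above the `1e-4` floor below which the
sampler refuses and advises wider bounds; rejection sampling was chosen
over constraint-aware construction because it is simple and exactly
uniform on the feasible region.

What the generator emulates is the model's parameter space, nothing more.
It does not calibrate to empirical COVID-19 data, does not model network
topology among individuals, finite populations, strategy-dependent `β`,
or noisy strategy updating. Passing tests therefore demonstrate that the
deterministic replicator analysis is implemented correctly across the
admissible parameter space — not that the model describes any particular
real population.

## Problem sizes and limitations

The test suite runs the oracle-agreement checks at 200 parameter sets × 5
states (Jacobian), 100 sets (bimatrix/replicator consistency and the
welfare equivalence), 50 random trajectories (forward invariance), and
8–20 regime-constrained sets for the flow/classifier and saddle
properties; the Monte Carlo basin check in the acceptance tests uses
2,000 trajectories, and the unit tests 300. These sizes give the
properties enough room to fail while keeping a full run in tens of
seconds on one core.

Known limitations: no global bifurcation analysis beyond the three
regimes, no center-manifold treatment of non-hyperbolic points, no exact
computation of the curved separatrix (the Monte Carlo estimator stands in
for it), and 2×2 games only.
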