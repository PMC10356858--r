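---
title: "Planning reliable laser thermal pain stimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning reliable laser thermal pain stimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The planning problem

Laser-evoked potential studies stimulate cutaneous nociceptors by heating
the skin with a short laser pulse. The stimulus window is narrow: tissue at
the receptor depth must exceed roughly 43 °C to fire the receptors, while
the skin surface must stay below 52 °C to avoid damage (above ~60 °C
proteins denature). Two scalar indicators summarize a pulse:

* **HPM** (thermal penetration, efficacy): the maximum over time of the
  on-axis temperature 20 µm below the surface — the shallow end of the
  nociceptor band.
* **ST** (surface temperature, safety): the on-axis surface temperature at
  the end of irradiation, constrained below the damage threshold
  b = 52 °C.

Four operating parameters drive both indicators: laser power (5–10 W),
Gaussian spot radius (1–2 mm), irradiation time (0.2–0.6 s) and ambient
temperature (10–35 °C). None of them is perfectly repeatable across
sessions; the package treats each as an interval ⟨midpoint, radius⟩ with
radii 0.25 W, 0.05 mm, 0.02 s and 1.25 °C, and looks for the midpoint
vector that maximizes efficacy while the *whole* ST interval respects the
threshold with a prescribed reliability.

## The bioheat model

Heat transport in perfused tissue follows the Pennes equation

ρc ∂T/∂t = ∇·(k ∇T) + ω_b C_b (T_b − T) + q_m + q_r ,

solved in axisymmetric (r, z) coordinates over a five-layer model of
hair-bearing skin: stratum corneum (10 µm), epidermis (80 µm), upper dermis
(260 µm), a blood-rich layer (150 µm) and subdermal tissue (1500 µm), each
carrying its own ρ, c, k and optical coefficients. The stratum corneum is
assigned epidermis properties — no separate measurement exists for a 10 µm
keratin film — and both dermis layers share the dermis optics.

The laser source is a separable Gaussian/Beer–Lambert deposition

Q(r, z) = P µ_a(z) e^(−τ(z)) · e^(−r²/(2σ²)) / (2πσ²),

with τ(z) the cumulative optical depth ∫µ_a dz across the layers and σ the
spot radius. Two radial normalizations are implemented. The
`"cylindrical"` default divides by 2πσ², so the power deposited in an
infinitely deep domain is exactly P(1 − e^(−τ_total)); this is the only
normalization consistent with watt-scale powers heating millimetre-scale
spots by tens of kelvin. A `"literal"` mode dividing by σ√(2π) (the
one-dimensional Gaussian normalization that sometimes appears in print) is
retained behind a flag for comparison; in cylindrical geometry it
under-deposits by about three orders of magnitude at these parameters.
Scattering coefficients are carried in the data model but do not attenuate
the default source (absorption-only Beer–Lambert); an optional
`"effective"` mode attenuates with µ_a + µ_s and scales each cell's
absorption by µ_a/(µ_a + µ_s). With the tabulated epidermis scattering
(450 cm⁻¹) that mode absorbs well under 1 % of the beam and is far too
cold, which is why it is off by default — neither extreme is a full
radiative-transfer model, a known limitation discussed below.

### Boundary conditions and unreported constants

The published description of this class of experiments leaves several
constants unstated, and the package makes them explicit, documented
defaults rather than hidden assumptions:

* **Surface**: Robin exchange −k ∂T/∂z = h(T − T_ambient) with
  h = 10 W m⁻² K⁻¹, a standard free-convection-plus-radiation lump for
  still indoor air. This choice gives the pre-pulse field its ambient
  sensitivity; larger h would deepen it.
* **Bottom** (2 mm): Dirichlet at the 37 °C core temperature.
* **Lateral** (≥ 5 spot radii, default 10 mm): zero flux; doubling the
  extent moves the indicators by < 0.05 °C (tested).
* **Perfusion and metabolism**: ω_b = q_m = 0 by default. Over sub-second
  pulses the perfusion sink removes of order 0.1 % of the stored heat even
  at strongly hyperaemic rates, so zero is both simpler and honest; both
  terms are fully implemented and configurable for longer exposures.
* **Initial condition**: the conductive steady state of the same boundary
  problem (computed, not assumed uniform), so ambient temperature affects
  the result the way it does in practice.

Because these constants are not recoverable from published summaries, the
solver's absolute temperatures cannot be expected to match any particular
published table to fractions of a degree. The package therefore validates
itself differently: against an independent 1-D Crank–Nicolson reference in
the radially uniform limit (< 0.05 °C agreement), by exact energy
conservation on an insulated domain, by grid/time-step convergence, and by
the monotone parameter trends (hotter with power, duration and ambient;
cooler with spot radius) that any correct implementation must show. In our
runs the low-energy operating points agree with published 20 µm
temperatures to well under 2 °C while the hottest points run hotter,
a discrepancy consistent with unreported source or boundary settings in
the reference finite-element model rather than with discretization error
(the solver is converged to < 0.03 °C at those points).

### Discretization

Conservative finite volumes on a graded tensor grid: depth spacing is a
uniform 2 µm down to 40 µm — so the 10 µm corneum boundary and the 20 µm
probe depth are exact nodes — then grows geometrically within each layer to
at most 100 µm; radially, twelve cells per spot radius across the beam,
growing outward to the lateral boundary. Every layer interface is a node,
so each z-segment lies in a single layer and face conductances need no
cross-layer averaging; the r = 0 axis is natural (the innermost control
volume has zero inner face area). The source is integrated *exactly* over
each control volume (closed-form Gaussian annulus fractions × Beer–Lambert
cell absorption), which makes the discrete energy input independent of
resolution and was necessary for clean second-order convergence — with
point-sampled sources the indicator still drifted by ~0.1–0.5 °C under
refinement.

Time stepping is implicit (backward Euler default, Crank–Nicolson option),
unconditionally stable, with the sparse symmetric system factorized once
per run (Cholesky) and back-solved each step; dt = 1 ms during the pulse
and the horizon equals the pulse, since on-axis heating is monotone and
both indicators peak at pulse end. Halving all spacings and the step moves
HPM by 0.007 °C at the centre of the design space. A `coarse_grid_spec()`
(4 µm / 5 ms) exists for smoke tests; reported numbers use the default.

## Design of experiments

* `orthogonal_l9()` returns the standard L9(3⁴) array with the study's
  factor-level assignment. `range_analysis()` reports level sums K, level
  means K/3, the level sums ÷ 9 convention that some summary tables print,
  the range R per factor, the factor ranking by R, and the optimal
  combination as the argmax of the level means per factor — the
  self-consistent definition, applied uniformly even where a printed
  summary row disagrees with its own level means.
* `variance_analysis()` computes the textbook saturated-design
  decomposition SS_f = 3 Σ(level mean − grand mean)², df = 2. A saturated
  L9 leaves no error degrees of freedom, so F ratios require pooling; the
  default pools the smallest-SS factor (a conventional, conservative
  choice), and `pooling = "none"` reports the decomposition alone. The SS
  identity Σ SS_f = SS_total is asserted in the tests, and the
  decomposition is cross-checked against `stats::aov`.
* `optimal_lhs()` wraps seeded maximin Latin hypercube sampling: exactly
  one point per 1/n quantile band per dimension, with the minimum
  inter-point distance improved by random swaps. "Optimal" is read as
  maximin — the common choice when no criterion is stated.
* `single_factor_sweep()` holds three factors at the centre of the design
  ranges (7.5 W, 1.5 mm, 0.4 s, 25 °C) — the natural base point absent any
  other specification — and returns rise curves for plotting.

## The surrogate

A Gaussian RBF network with centers at all design points. Inputs are
affinely mapped to [0, 1] per dimension using the design domain (so the
kernel treats a 5 W power range and a 25 °C ambient range equally);
outputs are standardized. The shared kernel width is the median pairwise
distance between normalized centers (a robust default; configurable
multiplier), and the output weights solve (Φ + ridge·I) W = Y with
ridge = 10⁻⁸ — numerically conditioned interpolation, automatically
escalated with a warning if the kernel matrix is degenerate. On the
50-point design the training-sample R² is 1 − O(10⁻¹²) for both
indicators; since near-interpolation makes training-sample R² nearly
tautological, `error_metrics()` works equally on held-out points, and the
test suite checks generalization on held-out samples of a known smooth
surface (< 0.5 °C). The relative-error sign convention is
RE = (y − ŷ)/y: positive means the surrogate under-predicts.

## Interval uncertainty and the RPDI

An uncertain parameter is an interval d ∈ [d_c − d_ω, d_c + d_ω]. Pushing
a box of four such intervals through the surrogate gives response
intervals [F_L, F_R] = [min F, max F] over the box (the *inner* problem).
The reliability-based possibility degree of interval orders an interval
against the threshold:

p(F ≤ b) = (b − F_L) / (2 F_ω),

with the properties (i) p is unbounded in (−∞, ∞); (ii) p ≥ 1 exactly when
F_R ≤ b (the whole interval is safe — simple algebra, asserted in tests);
(iii) p ≥ 0.5 exactly when the midpoint is safe; (iv) the complement
identity p(A ≤ B) = 1 − p(B ≤ A) for the two-interval form. Degenerate
zero-width cases use the documented convention (±∞ for the scalar form;
1/0/0.5 for two scalars). Requiring p ≥ λ turns the uncertain constraint
into a deterministic one; λ is the reliability dial, with λ ≥ 1 a hard
guarantee and λ < 1 admitting some overshoot.

### The nested optimizer

The outer real-coded genetic algorithm (population 60, 100 generations,
tournament selection, SBX crossover η = 15, polynomial mutation η = 20 at
rate 1/d, elitist merge, fixed seed) searches interval *midpoints* inside
the radius-shrunk domain [d_l + d_ω, d_u − d_ω]; the radii stay fixed at
the stated operating uncertainties — the planner chooses set-points, not
the hardware's repeatability. Fitness is the objective-interval midpoint
(the standard scalarization when no weighting is prescribed; a
conservative lower-bound mode exists) minus a large penalty times the RPDI
shortfall.

The inner problem is solved at two fidelities. During the GA each
candidate box is bounded on a fixed 3-level tensor grid (3⁴ = 81 surrogate
evaluations in one vectorized call) — the boxes are small (radii are 2–5 %
of the ranges) and the surface is smooth, so this is accurate to well
under 0.01 °C. The returned optimum is then re-certified with the full
multi-start bound search (vertex + centre + grid seeds polished by
bound-constrained quasi-Newton descent/ascent); if refinement reveals a
constraint violation the best refined-feasible member of the final
population is returned instead, and a dense-grid fallback guards against
local-search failure. Tests assert that the returned interval contains a
17⁴ brute-force grid of the box, that a linear response attains its bounds
at opposite vertices, that the optimizer recovers a closed-form constrained
optimum within 1 %, and that the optimized ST interval at λ = 1 tops out
at exactly b.

Raising λ over {0.9, 1.0, 1.1} monotonically lowers the achievable thermal
penetration — reliability is bought with efficacy — and the package's
λ = 1 solution keeps the HPM interval above the ~43 °C activation
threshold, so the guaranteed-safe stimulus remains effective. An optional
second constraint HPM_L ≥ 43 °C can be switched on by treating `hpm` as
the constrained response; it is off by default because the canonical
formulation carries only the safety constraint.

## The synthetic response generator

`fixture_response_table()` produces a deterministic design with smooth
closed-form indicator surfaces that mimic the solver's monotone structure
(rise ∝ P · t^0.45 / σ^1.7, weak ambient slope, ST slightly above HPM).
It exists so the surrogate and interval modules can be exercised in
milliseconds and is labelled synthetic throughout: it reproduces the
solver's trends and smoothness, not its values, curvature near the domain
corners, or any noise — so tests that pass on it demonstrate algorithmic
correctness, not solver fidelity (the solver-backed tests do that).

## Problem sizes and budgets

Reported numbers use the default resolution: a ~44 × 77 node grid, 1 ms
steps, the 50-point maximin design, and GA 60 × 100. One irradiation takes
about a second on one core; the full pipeline (9 orthogonal runs, 50
design runs, surrogate, sweep, three λ levels) a few minutes. These sizes
were chosen as the point where the discretization error (< 0.01 °C) and
the GA's run-to-run spread (< 0.01 °C in the optimized bounds across
seeds) are far below the 0.1–1 °C scale that matters clinically.

## Known limitations

* Light transport is absorption-only Beer–Lambert; strong epidermal
  scattering is not modelled as transport (no diffusion approximation or
  Monte Carlo), so absolute heating of scattering-dominated layers carries
  systematic uncertainty.
* The surface heat-exchange coefficient, perfusion and the initial state
  are documented defaults, not measurements; absolute temperatures shift
  by a few degrees across their plausible ranges, although rankings,
  trends and the optimization structure are robust to them.
* No tissue-damage kinetics (Arrhenius integrals) — the 52 °C threshold is
  a temperature cap, not a dose model.
* Axisymmetric beams only; no pulse trains; no 3-D anatomy.
* The RBF surrogate is least accurate near domain corners (a few °C there,
  versus < 0.2 °C near the centre); the optimizer's solutions sit in the
  interior, and the acceptance path re-confirms extrema with direct solver
  runs.
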