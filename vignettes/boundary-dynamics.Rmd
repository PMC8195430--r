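---
title: "Models and methods: bistable expression boundaries over dynamic morphogen gradients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: bistable expression boundaries over dynamic morphogen gradients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
library(bistablefronts)
```

## The problem

During tissue patterning, a diffusible morphogen forms a spatial
concentration profile that downstream gene networks convert into sharp
expression boundaries. When the interpreting network is bistable — the
canonical example being a two-gene toggle switch — the morphogen acts as a
spatially varying bifurcation parameter: at some positions only one
expression state exists, at others two coexist and a cell's fate depends on
where its initial chemical state sits relative to the basins of attraction.
This package simulates and analyses that process in one spatial dimension,
in two regimes:

1. **No protein diffusion.** Every position `x` evolves independently under
   its local morphogen concentration; boundary precision is governed by the
   interplay of initial conditions, basins of attraction, and the *temporal*
   evolution of the gradient.
2. **With protein diffusion.** The boundary becomes a propagating front
   whose local velocity is set by the frozen-parameter travelling-wave speed
   at each position; its motion can be reduced to a single ordinary
   differential equation.

## Model families

All reaction terms are assembled by `build_model()`:

* **`toggle1`** — mutual repression with morphogen-activated species 1:
  `du1/dt = a1 h_a(alpha(t, x)) h_r(u2) - beta u1`,
  `du2/dt = a2 h_r(u1) - beta u2`, with activating/repressing Hill
  functions `h_a(y) = (y/K)^n / (1 + (y/K)^n)`, `h_r(y) = 1 / (1 + (y/K)^n)`.
  Transcription and translation are lumped into one production step, and
  there are no delays or stochastic kinetics.
* **`toggle2`** — both species driven by their own (typically antiparallel)
  gradients, with per-species diffusivities; used for front localization.
* **`hb`** — Hunchback dynamics over a Bicoid-style gradient:
  `dh/dt = f(b, h) - beta h + D d2h/dx2` with the saturating regulatory
  function `f(b, h) = (alpha_b (b/b0)^nb + alpha_h (h/h0)^nh) /
  (1 + (b/b0)^nb + (h/h0)^nh)`. The published parameter values for the
  quantitative Hb example are deliberately **not** bundled; the `hb_yang`
  scenario requires a user-supplied parameter file (a blank template ships
  in `inst/extdata/hb_yang_template.toml`).
* **`scalar`** — the cubic bistable reaction `du/dt = u (1 - u)(u - alpha(x))`
  with diffusivity `D`. This one-species stand-in was chosen for its
  closed-form travelling-wave speed `c = (1 - 2 alpha) sqrt(D / 2)`, which
  serves as an analytic oracle for the numerical front-speed machinery; it
  is a generic representative of one-dimensional bistable reactions, not a
  claim about any particular published variant.

Gradient families (`gradient_*()`): a static exponential `b exp(-x/lambda)`;
an *emerging* profile `b exp(-x/lambda) (1 - exp(-gamma t))`; a *decaying*
profile `b exp(-x/lambda - gamma t)`; a Bicoid-style profile whose temporal
decay at rate `omega0` starts at onset time `t0`; and tabulated profiles
with linear interpolation and flat extrapolation at the table ends (the
rule that preserves monotonicity with no invented curvature). Coordinates
run anterior (`x = 0`, high morphogen) to posterior (`x = L`); positions are
reported both in model length units and as fractions of `L`.

## Instantaneous portraits, scans, and timescales

`find_fixed_points()` solves the frozen local dynamics. For one-species
families the attainable interval `[0, umax]` is decomposed into monotone
segments (critical points located from sign changes of the derivative) with
one bracketed root per segment — robust arbitrarily close to saddle-node
collisions. Two-species families use a multi-start damped Newton iteration
on an 8 x 8 log-spaced seed grid spanning `[0, a_max/beta]` per species; a
root is accepted only when both the residual and the Newton correction are
negligible, which rejects the pseudo-roots that a residual test alone admits
near saddle-node collisions. Roots outside the attainable box are discarded
(production is bounded, so admissible steady states cannot exceed
`a_max/beta`). Stability comes from the analytic Jacobian's eigenvalues; a
leading rate below `1e-8` in magnitude is flagged marginal and classified
unstable with a warning rather than silently, since that situation occurs
exactly at bifurcations.

`scan_axis()` classifies every grid position as `mono_high`, `mono_low` or
`bistable` (high/low refer to species 1) and refines the interval endpoints
`x_a`, `x_p` and the monostable-to-bistable transition `x_crit` by bisection
to `1e-4 L` — finer than any position the analyses report.

`sigma_and_kappa()` measures the slowest network timescale `sigma`: the
minimum over bistable grid positions and over both stable states of the
magnitude of the leading Jacobian eigenvalue, evaluated at the gradient's
*reference static profile*. For an emerging gradient that reference is its
`t -> infinity` limit. For a decaying (or Bicoid-style) gradient the formal
long-time limit is zero morphogen everywhere — monostable by construction —
so the reference is instead the established profile at `t = 0` (resp. the
onset time), the profile whose bistable region is being swept. `kappa =
gamma / sigma` then compares gradient and network rates; `kappa << 1` means
the network tracks the gradient quasi-statically.

Two caveats are worth stating plainly. First, the local convergence rate
genuinely tends to zero at the fold points bounding the bistable interval,
so `sigma` depends on how close the scan grid happens to sit to those
folds; it is a property of the *discretised* axis, and `kappa` values are
implementation-defined up to that choice (all experiment protocols compute
`sigma` on their own grid, so a given scenario is internally consistent).
Second, `sigma` defined through Jacobian eigenvalues is a linearisation
statement; the trajectory-fit test in the suite confirms it matches the
fitted late-time decay exponent of simulated trajectories at the slowest
bistable position.

## The irregularity metric R

Given an ensemble of initial states whose spatial arrangement is unknown,
`tight_bounds()` finds the tightest guarantees available: `x_tilde_a`, the
largest position at which *every* member converges to the high state, and
`x_tilde_p`, the smallest position at which *none* does.
`irregularity_R()` reports `R = (x_tilde_p - x_tilde_a) / (x_p - x_a)`, the
fraction of the bistable region over which fate is not guaranteed: `R = 0`
is a perfectly precise boundary, `R = 1` a fully irregular bistable region.
Read with cell-to-cell initial variation the metric is *precision*; read
with embryo-to-embryo variation in uniform starts it is *reproducibility* —
the computation is identical, only the interpretation label on the ensemble
differs. `irregularity_at_time()` rescales `R` to the bistable width at an
earlier time.

Because the basins are nested along a monotone gradient (any state reaching
the high state at a posterior position also reaches it anterior of there),
both defining predicates are monotone in `x` and are located by bisection
with the full ensemble — the two-species basins are not totally ordered
member-wise, so no member-pruning shortcut is attempted. Basin membership
itself (`basin_label()`) is decided by integrating the frozen dynamics until
the state is within a relative max-norm radius `1e-4` of a stable fixed
point, with a time cap of 50 (protocols: 100) times the slowest local
timescale. A trajectory that exhausts the cap is labelled *indeterminate*
and widens the bounds conservatively: it counts as not-high for `x_tilde_a`
and as high for `x_tilde_p`, so indeterminacy can only enlarge the reported
irregular region, never shrink it. When every probed position is unanimous
the two bounds are collapsed to a common value so that `R` is exactly zero,
matching the defining property "R = 0 iff every member shares a label at
every bistable position".

## Experiment protocols

**Gradient emergence** (`emergence_experiment()`, scenario
`fig2_emergence`). The gradient grows from zero — the whole axis initially
monostable for low species 1 — while every ensemble member at every grid
position evolves under the non-autonomous dynamics. For each target
`kappa`, `gamma = kappa sigma`; emergence is integrated until the profile is
within `1e-8` of its limit (`18.4 / gamma` time units), followed by
frozen-profile relaxation, and `R` is computed against the final-profile
scan. `kappa = Inf` is the static-gradient control. The defaults — 50
initial conditions drawn uniformly from the box `[0, 0.2 a_max/beta]^2`
near the origin, 100 grid positions, seed 1 — are the package's standard
emergence conditions. Slow emergence (`kappa <= 0.01`) washes out initial
variation completely (`R = 0`); fast emergence approaches the static
control's irregularity.

**Decay sweep** (`sweep_experiment()`, scenario `fig3_sweep`). An
established gradient decays for a readout time `t_f`, chosen by
`readout_time_for_shift()` so the bifurcation points shift anteriorly by a
fixed distance (level sets of the decaying exponential move at speed
`lambda gamma`; default shift `0.05 L`, a configurable choice). The profile
is then frozen, cells relax, and `R` is computed against the frozen-profile
scan. Anterior cells that converged to the high state while monostable stay
high as bistability sweeps over them; the initially bistable region is
swept into monostable-low territory. The scenario's ensembles are drawn
from the same near-origin box as the emergence protocol (the distribution
is an open choice; a box spanning the full concentration range pins every
cell to its initial basin under quasi-static decay and hides the
preinduction effect the protocol is designed to expose). With ten seeded
ensembles the mean `R` decreases as `kappa` drops from 10 to 1 to 0.1 — and
does so seed by seed, not just on average.

## Reaction–diffusion solver and boundary extraction

`integrate_rd()` uses the method of lines: node-centred grid, second-order
central Laplacian, no-flux boundaries via mirrored ghost nodes, and lsoda
time integration with a banded Jacobian (species interleaved per node, so
reaction and nearest-neighbour diffusion fit in bandwidth `n_species`).
Zero-diffusivity species reduce exactly to per-node reaction equations —
verified against independent per-node integration to `1e-6` max-norm.
Time-varying gradients are evaluated inside the right-hand side at solver
time rather than pre-tabulated, so adaptive steps see the exact profile.
Negative undershoots are diagnosed (warning below `-1e-9`), never clipped;
clipping would mask solver error. The default grid is 401 nodes with 201
outputs, i.e. quarter-percent spatial resolution at desk cost.

`extract_boundary()` defines the boundary as the crossing of the species
profile with the *local unstable steady state* interpolated along the
bistable interval. In monostable stretches no unstable state exists and no
convention is universal; the fallback is the midpoint of the bistable
region's stable branches (clamped interpolation), a documented choice.
Multiple crossings resolve by continuity (nearest to the previous time's
position); formation time `t_form` is the first time a crossing lies inside
the bistable interval; boundary width is the distance between the 10% and
90% levels of the local high–low span.

## Front velocities and the boundary-position ODE

`frozen_front_speed()` builds the homogeneous companion system at one
position's frozen parameter values and measures its travelling-front speed:
a step between the two stable states on an auxiliary domain 40 front widths
long (front width estimated as `sqrt(D_max / beta_eff)` with `beta_eff` the
slowest stable-state rate; 24 nodes per width), positions extracted at the
unstable-state crossing, the first quarter of the usable window discarded
as transient, and the speed taken as the least-squares slope. The fit's
`R^2` must exceed 0.999 whenever the displacement is resolvable on the
grid, else a convergence warning is raised. An optional refinement doubles
the domain until the speed changes by under 1%. Sign convention: `c > 0`
means the high-species-1 domain expands posteriorly. The scalar family
bypasses simulation via its closed form unless simulation is requested;
the numerical route reproduces the closed form to about 0.01%.

`velocity_map()` evaluates the speed once per distinct morphogen value and
maps it to positions; entries within 1% of `L` of the bistable endpoints
are linearly extrapolated instead of simulated (speeds near the fold are
expensive to converge) and flagged. `ode_boundary()` integrates
`dw/dt = c(w + eps)` over the map's linear interpolant, halting cleanly at
the domain edge. `eps` corrects for the finite boundary straddling a range
of local velocities: it defaults to 0, which is accurate for equal
diffusivities, and `eps_from_width()` offers the quarter-boundary-width
magnitude convention for unequal-diffusivity work; `eps` is treated as an
absolute length (its scale is otherwise unstated in the conventions this
follows). `localization_points()` returns the sign-change roots of the map
— attracting where `c` passes from positive to negative — which is where
opposing fronts meet and the boundary parks.

## Scenario defaults and what the synthetic conditions do (and do not) show

The single-gradient toggle parameters used throughout
(`a1 = 1.5, a2 = 1, beta = 1, K_a = 0.5, n_a = 2, K_r = 0.3, n_r = 2`;
gradient `b = 2, lambda = 0.35` on `x in [0, 1]`) are not printed in the
literature this models; they were chosen once so that the final profile
yields the canonical class sequence mono_high -> bistable -> mono_low
(bistable for morphogen concentrations roughly in `[0.62, 1.13]`, i.e.
`x in [0.20, 0.41]`); they are representative defaults rather than fitted
values, so runs with them illustrate the mechanisms, not any particular
measured system. The antiparallel-gradient scenario uses the printed switch
parameters (`a = 1.7, beta = 0.35, n = 2, K_a = 0.75, K_r = 1,
D1 = D2 = 1`) with opposing exponentials `b = 4, lambda = 40` on
`L = 100`, chosen so the gradients cross mid-domain at concentration
`~1.15`, comfortably inside the bistable band, with the bistable interval
(`x` roughly 44–56) several front widths wide. The stripe scenario's
threshold field oscillates about the cubic's balance level with amplitude
0.1 (`alpha(x) = 0.5 + 0.1 sin(6 pi x / L)`, `D = 0.1`); a published 2-D
version of this pattern varies only along one axis, so the 1-D solve here
equals its midline cross-sections and no 2-D solver is provided.

Ensembles are uniform draws in an axis-aligned box, seeded and reproducible
(`make_ic_ensemble()`); they emulate unstructured variation in initial
chemical state. Real embryos add features deliberately outside this model:
spatially correlated initial conditions, gene-expression noise during (not
just before) patterning, mRNA/protein two-stage kinetics, delays, growth,
and gradient variability between individuals. Passing tests therefore
certify the deterministic interpretation machinery, not those sources of
biological variability; stochastic boundary-sharpening mechanisms in
particular are explicitly out of scope.

Problem sizes used by the shipped analyses: emergence precision at 100 axis
positions x 50 initial conditions; sweep trend at 30–40 positions, 10–20
initial conditions, 10 seeds; localization runs on 401-node grids; velocity
maps from 13–33 frozen-front simulations. These sizes resolve every
reported quantity well inside its stated tolerance (endpoint bisection at
`1e-4 L`, boundary extraction at sub-quarter-percent resolution).

## Known limitations

* `kappa` inherits `sigma`'s dependence on the scan grid near fold points
  (see above); compare `kappa` values only within a fixed grid.
* The boundary-position ODE is an engineering approximation with no formal
  error bound; `eps` is a convention, not a derived quantity. Accuracy
  degrades near bifurcation points, where the front straddles the
  monostable/bistable transition, and for strongly unequal diffusivities.
* Front-speed measurement assumes the companion system's front settles
  within the auxiliary window; exotic parameter sets with extremely slow
  fronts may need the `refine` option or a larger `n_widths`.
* The quantitative Hunchback analyses require externally supplied published
  parameter values; without them the package exposes only the structural
  machinery (and refuses to invent defaults).
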