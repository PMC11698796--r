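---
title: "Methods: the symmetric two-cell ellipse alignment model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the symmetric two-cell ellipse alignment model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellign)
```

## The model

`cellign` implements a minimal mechanical model of how two crawling,
ellipse-shaped cells align with each other through *overlap avoidance*: a
soft (penalised, not hard) exclusion interaction in which overlapping
configurations are allowed but drive restoring motion.  Each cell is an
ellipse of fixed area with centre $\mathbf{X}$, orientation $\alpha$ and
aspect ratio $r$; it self-propels along its orientation and changes
position, orientation and shape to reduce overlap with its partner.  All
quantities are non-dimensional: lengths are scaled by the radius of the
equal-area circle and time by the overlap-avoidance response time.

The analysis becomes tractable under a mirror symmetry: cell 1 at
$(x, y)$ with orientation $\alpha$, cell 2 at $(x, -y)$ with orientation
$-\alpha$, equal aspect ratios.  Velocity alignment then corresponds to
$\alpha \to 0$ (cells side by side, moving in the same direction).  The
symmetric configuration admits *analytic* boundary intersection points,
so the governing equations can be written in closed form.  Three
non-dimensional parameters remain ([`model_params()`]):

| parameter | meaning | typical values here |
|---|---|---|
| `nu` | self-propulsion speed relative to overlap-avoidance strength (with substrate friction) | 0–8 |
| `gamma` | overlap-avoidance strength relative to shape restoration; `0` = rigid cells | 0–1 |
| `r_bar` | preferred aspect ratio; `> 1` "long" cells, `< 1` "wide" cells | 1.2–8 |

`r_bar = 1` (circular cells) is a structural degeneracy: circular cells
exert no torque and several formulas divide by $r^2 - 1$, so operations
that need it refuse with an explicit error.

## Overlap geometry: regions A, B, C

Depending on $(\alpha, y, r)$, the two ellipse boundaries intersect in 0,
2 or 4 points (regions A, B, C).  With
$\gamma_1^2 = r\sin^2\alpha + \cos^2\alpha/r$ and
$\gamma_2^2 = \sin^2\alpha/r + r\cos^2\alpha$, the region boundaries are
$\Gamma_{AB} = \gamma_1$ and
$\Gamma_{BC} = (r^2-1)\sin\alpha\cos\alpha/(r\gamma_2)$, and the regions
are classified by comparing $y^2$ against $\Gamma_{AB}^2$ and
$\Gamma_{BC}^2$ (`classify_region()`).  The identity
$\gamma_1^2 - \Gamma_{BC}^2 = 1/\gamma_2^2$ holds exactly and is used both
in the classifier and as a closed-form test.

The intersection points themselves (`intersection_points()`) are
validated two independent ways: every returned point must satisfy the
implicit equation of both ellipses (`implicit_residual()`, residuals
below $10^{-9}$), and a brute-force scan of one boundary against the
other's implicit equation (`count_intersections_scan()`) must find the
same number of crossings as the classifier.

Numerical choices at the region boundaries:

* Ties within $10^{-12}$ of a boundary are classified as the region with
  *more* intersection points, so vanishing square roots evaluate to 0
  rather than NaN.  The vector field is continuous across both
  boundaries, so the tie rule cannot alter trajectories.
* Square-root radicands in $(-10^{-12}, 10^{-12})$ are clamped to 0;
  anything more negative while the state is classified as overlapping
  raises an internal-consistency error, distinguishing float noise from
  logic bugs.

## Governing equations and their continuity

`rhs_full()` implements the piecewise equations of motion: horizontal
drift $\dot x = \nu\cos\alpha$ decouples; $\dot y$, $\dot\alpha$ and
$\dot r$ switch branches across A/B/C, and $\dot r$ always carries the
restoration term $-(16/\gamma)\,(1 + \bar r r^3)/(\bar r(r^2+1))\,(r-\bar r)$.
In region C the shape equation is assembled from the already-computed
$\dot\alpha$ and the overlap part of $\dot y$; the sign of its
$(\cos^2\alpha - \sin^2\alpha)$ factor is fixed by requiring the B and C
branches to agree identically at the B–C boundary, where the inner
intersection pair merges and its contribution must vanish.  (With that
factor the agreement is exact in closed form; it also gives the
physically expected behaviour that deeply overlapping head-to-head cells
shorten.)  Continuity of $(\dot y, \dot\alpha)$ across both boundaries is
asserted at thousands of sampled boundary states in the test suite.

Two reduced systems are provided: `rhs_rigid()` ($\gamma \to 0$, aspect
ratio locked at $\bar r$, a two-variable phase plane) and `rhs_nu0()`
(rigid with $\nu = 0$, where overlap avoidance is the only driver and the
A–B boundary is a line of stationary points).

## Event-aware integration

`integrate_trajectory()` drives `deSolve::lsodar` (adaptive,
stiff-capable, with root finding) and restarts the integration at every
resolved region-boundary crossing, so branch switches never occur
mid-step.  Defaults `rtol = 1e-9`, `atol = 1e-11`.  Three details matter
and are easy to get wrong:

* **Linear region-A motion is advanced in closed form** for the rigid
  modes ($\alpha$ frozen, $y$ linear in $t$).  An adaptive integrator
  grows its steps without bound in this linear regime and can then step
  across the entire overlap window — the boundary root function dips
  below zero and returns within a single internal step, and the cell
  "flies through" its partner undetected.  The closed-form advance is
  exact and immune to this.
* **A deadband of $10^{-8}$ on the A–B root function.**  Trajectories
  attracted to the slow slide along the A–B boundary graze it at the
  integration-noise level; without the deadband the root fires at every
  step and the integration stalls.
* **Tangential arrival at $\nu = 0$.**  The stationary boundary is
  approached with $\sqrt{\gamma_1^2 - y^2} \to 0$, a quadratic tangency
  the root finder cannot bracket.  The stop is therefore root-resolved on
  $\gamma_1^2 - y^2 = 10^{-12}$ and the analytically known remainder of
  the arrival time (the radicand decays linearly in its square root) is
  added, giving arrival times accurate to $\sim 10^{-6}$ relative.

Termination policy (configurable; `terminate = FALSE` records the full
horizon): for $\nu = 0$, stop on the stationary A–B boundary; for
$\nu > 0$, stop when the state is in region A with
$\mathrm{sign}(y)\sin\alpha > 0$ (cell 1 past its partner and heading
away — by straight-line region-A motion it can never re-enter overlap),
or when the orientation has converged to the half-stable aligned state.
Exact alignment is reached only in infinite time, so convergence is
declared at `tol_align` ($10^{-4}$ by default).

## Zero-propulsion closed forms

For rigid cells without propulsion the region-B orbits follow an explicit
curve $y(\alpha)$ (`trajectory_curve_nu0()`), whose first integral is
conserved along numerically integrated arcs to $10^{-8}$.  Three derived
results are implemented as monotone root problems and a singular
quadrature:

* `final_angle_nu0()`: the terminal orientation solves a strictly
  increasing arrival equation in $s = \sin\alpha$.  Re-deriving this
  equation from the orbit curve gives a right-hand side containing
  $r\,y_0^2$; the validity check is the trivial case (a start on the A–B
  boundary must return itself) plus agreement with the integrated
  terminal angle to $10^{-6}$.
* `bc_no_reentry_root()`: a launch on the B–C boundary satisfies a second
  monotone equation whose unique root is the initial condition itself —
  the closed-form statement that region B is forward-invariant.
* `interaction_time_nu0()`: separating variables along the orbit gives
  the arrival time as $T = (r^2+1)/(8(r^2-1)) \cdot J$ with an integrable
  inverse-square-root endpoint singularity, removed by the substitution
  $\alpha = \alpha_T + u^2$ before adaptive quadrature (tolerance
  $10^{-10}$).  The prefactor was fixed by re-deriving the separable form
  from the orientation equation and validating against the integrator's
  arrival event ($10^{-4}$ relative agreement over random region-B
  starts); an inconsistent prefactor variant was rejected by the same
  cross-check.

The closed forms hold on region-B arcs.  Region-C starts are first
advanced numerically to the B–C crossing (region B is forward-invariant,
so the crossing point begins the closed-form arc).

## Perturbations of the perfect-alignment state

The states $(\alpha, y, r) = (0, \pm 1/\sqrt{\bar r}, \bar r)$ — cells at
preferred shape, side by side, just touching — are steady
(`steady_states()` verifies residuals below $10^{-12}$).  Their stability
is degenerate: linearisation is uninformative, and the correct picture
comes from the scalings $\alpha = \varepsilon A$,
$y = -1/\sqrt{\bar r} + \varepsilon^2 B$,
$r = \bar r + \varepsilon^2 C$ in the distinguished limit
$\gamma = \varepsilon\Gamma$.

* **Early time** $t = O(\varepsilon)$ (`early_time_rhs()`,
  `solve_early_time()`): the orientation is frozen while overlap
  avoidance and shape restoration balance.  The overlap indicator
  $D = (\bar r^2 - 1)A^2 + 2\sqrt{\bar r}\,B - C/\bar r$ decides whether
  the cells interact; its own evolution equation is recovered by the
  chain rule on the $(A, B, C)$ system (the test asserts exactly this
  self-consistency).  For $a > 0$ the solution approaches closed-form
  far-field constants (`far_field_limits()`); for $a < 0$ overlap ceases
  and the perturbation escapes.
* **Late time** $t = O(1/\varepsilon)$ (`late_time_solution()`): the
  orientation decays *algebraically*,
  $A(T) = a/(kT + 1)$ with
  $k = 4a\nu\sqrt{\bar r}(\bar r^2-1)/(\bar r^2+1)$, so
  $t\,\alpha(t) \to (\bar r^2+1)/(4\nu\sqrt{\bar r}(\bar r^2-1))$.  For
  wide cells ($\bar r < 1$) the denominator vanishes at a finite positive
  time and the perturbation blows up; evaluation past the pole is an
  error carrying the pole location.
* **Composite** (`composite_solution()`): the additive early + late
  combination minus the common matching part, uniformly valid in $t$.
  The early-time functions have no closed form and are integrated
  numerically to a configurable horizon (default $10^3$ in early time)
  with a convergence check against the far field.  No sharp error
  constant is available for a composite of this kind, so the test
  contract is *self-convergence*:
  halving $\varepsilon$ must contract the sup-error against the full
  system by at least 1.8 (measured: 6–7.5).  The orientation composite
  carries no shape-parameter dependence, and the tests assert it is
  bit-identical across $\gamma$.

Together these give half-stability for long cells: $a > 0$ decays
algebraically, $a < 0$ escapes; for wide cells the orientation grows
toward the head-to-head configuration.  `stability_probe()` classifies
these routes numerically ("decays" / "escapes" / "turns") and, for the
decaying route, fits the tail twice — algebraic $\alpha \sim K/t$ versus
exponential — and reports the residual ratio (the algebraic fit wins by
three orders of magnitude in the reference configuration).

## The small-propulsion slow manifold

For $0 < \nu \ll 1$ the fast ($\nu = 0$) dynamics deposit the state on
the A–B boundary in finite time $T$; propulsion then drives a slow drift
along the constraint $\gamma_1^2(\alpha) = y^2$ over $\tau = \nu(t - T)$.
`slow_manifold_rhs()` and `slow_manifold_single_ode()` implement the
reduced flow (strictly toward alignment), and `slow_manifold_time()`
integrates the separable drift time.  The offset $T$ is estimated with
the zero-propulsion interaction time, which is what the slow-time
construction prescribes.  As the target orientation goes to zero the
drift time diverges like
$(r^2+1)/(4\sqrt{r}(r^2-1)\,s)$ — perfect alignment is an infinite-time
limit.  At $\nu = 0.1$, $r = 2$ the full trajectory stays within
$O(\nu)$ of the constraint (measured $2\times10^{-4}$) and its
$\sin\alpha$ projection tracks the reduced ODE within $0.15\,\nu$.

## Alignment strength and the separatrix

`final_angle()` integrates a rigid-cell initial condition
$(\alpha_0, y_0) \in (0, \pi/2) \times (-\sqrt r, 0)$ to its
post-interaction orientation; `alignment_strength()` averages
$(\pi/2 - \alpha_{\text{final}})/(\pi/2)$ over a uniform midpoint grid
(default $20 \times 20$; the integral normalisation makes the statistic
the plain grid mean, in $[0, 1]$).  The defensible discretisation
contract is convergence under refinement, which the tests check by
comparing successive grid doublings.  Never-interacting nodes keep
$\alpha_{\text{final}} = \alpha_0$ and are included (the literal
integration domain); a switch excludes them.

Two outcomes exist for $\nu > 0$: convergence to the half-stable point,
or crawling over the partner and separating with $y > 0$.  The dividing
curve (`separatrix()`) is computed by bisection on the forward outcome at
orientation slices — the aligned side lies below in $y$ — after a
backward-integration trace (the separatrix is transversally attracting in
reverse time) used as a diagnostic.  Verification integrates forward from
$\pm 0.01$ offsets normal to the polyline and checks the outcomes flip.

One classification shortcut matters for cost: once a trajectory's
orientation has fallen below `align_cutoff` (default 0.02 rad) while on
the region-B side of the B–C boundary, it is inside the attracting cone
of the half-stable point — throughout region B at such small angles the
overlap term dominates propulsion for every propulsion strength used
here — so the infinite-time limit $\alpha \to 0$ is already decided and
the run stops without riding the $1/t$ tail (which is also where the
stiff integrator degrades).  Equivalence with the full
`tol_align = 10^{-4}` slide was validated on random nodes, including the
thinnest-sliver case $r = 1.2$.  Setting `align_cutoff = tol_align`
disables the shortcut.

### What the parameter sweeps show — and a known definitional caveat

Across $\nu \in \{0, 1, 2, 4, 8\}$ at $r = 2$ the statistic is
non-monotone exactly as the mechanism suggests: with no propulsion the
cells stop interacting at the first stationary contact
($S \approx 0.61$), moderate propulsion sustains the interaction long
enough to align ($S \approx 0.94$ at $\nu = 1$), and strong propulsion
pushes cells past each other ($S$ decreasing to $\approx 0.62$ at
$\nu = 8$).

Across $r \in \{1.2, 2, 4, 8\}$ at $\nu = 2$ this implementation finds
$S$ *maximal at the smallest aspect ratio* and decreasing thereafter.
The driver is the region-C push-apart rate, which scales like
$1/(r^2-1)$: as $r \to 1^+$ deep overlap is expelled ever more
violently, the crawl-over basin shrinks, and almost every initial
condition falls below the separatrix — and every such node's *limiting*
orientation is exactly zero.  An interior optimum ("both too round and
too elongated cells align less") emerges only under a finite measurement
horizon, because near-circular cells rotate at a rate $\propto (r^2-1)$
and a finite-time snapshot still shows $\alpha \approx \alpha_0$.  This
package reports the infinite-time limit (with the `tol_align` mapping and
a $t_{\text{end}}$ cap of $10^4$, capped nodes flagged rather than
silently included), and documents the discrepancy rather than tuning the
horizon to reproduce it.

## Synthetic fixtures, problem sizes, limitations

All test inputs are generated in code: uniform or region-stratified
initial conditions on $(0, \pi/2) \times (-\sqrt r, 0)$ under fixed seeds
(`fixture_initial_conditions()`), random states over
$r \in (1.1, 5)$ for geometry audits, and exact boundary states for
continuity checks.  These emulate the *configuration space* of the
symmetric two-cell model only — no measurement noise, no cell-to-cell
variability, no third cell, no adhesion — so passing tests certify the
mathematics of this model, not agreement with real cell-imaging data.

Reference problem sizes, chosen to exercise each result at scale while
keeping a default test run in minutes: $10^3$ states for the geometry and
continuity audits, $10^2$ region-B and $10^2$ boundary starts for the
zero-propulsion checks, $20\times20$ (refined to $40\times40$) alignment
grids, 10 separatrix slices, and full-system comparisons over
$t \in [0, 100]$ at $\varepsilon \in \{0.1, 0.05\}$.

Beyond scope by design: more than two cells, cell–cell adhesion,
stochastic forcing, nematic (orientation-only) alignment — the imposed
mirror symmetry can only represent velocity alignment — and the
"squishy" regime in which shape change is punished very weakly.
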