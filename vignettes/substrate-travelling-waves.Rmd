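---
title: "Travelling waves in substrate-mediated tissue growth: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Travelling waves in substrate-mediated tissue growth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

Thin tissues grown on 3D-printed scaffolds close square pores behind a
well-defined moving front. A minimal continuum description couples the cell
density $\hat u$ to the density $\hat s$ of an immobile substrate that the
cells deposit and which decays in time:

$$\frac{\partial \hat u}{\partial \hat t} = \hat D \, \nabla \cdot \Big(
\frac{\hat s}{\hat K_s} \nabla \hat u \Big) + \hat\lambda\, \hat u \Big(1 -
\frac{\hat u}{\hat K_u}\Big), \qquad
\frac{\partial \hat s}{\partial \hat t} = \hat r_1 \hat u - \hat r_2 \hat s .$$

The defining feature is that the diffusive flux of cells is proportional to
the substrate density, so the flux vanishes where no substrate has been
laid down. This degeneracy is what produces sharp fronts: cells cannot
spread into substrate-free territory faster than they can pave it.

Scaling $u = \hat u/\hat K_u$, $s = \hat s/\hat K_s$,
$x = \hat x \sqrt{\hat\lambda/\hat D}$, $t = \hat\lambda \hat t$ leaves a
two-parameter model,

$$u_t = (s\,u_x)_x + u(1-u), \qquad s_t = r_1 u - r_2 s,$$

with $r_1 = \hat r_1 \hat K_u/(\hat\lambda \hat K_s)$ (dimensionless
substrate production) and $r_2 = \hat r_2/\hat\lambda$ (dimensionless
decay). The ratio $R = r_1/r_2$ sets the substrate level behind the wave
($s \to R$) and indexes the fast-kinetics limit: for $r_1, r_2 \to \infty$
at fixed $R$ the substrate slaves to the cells ($s \to R u$) and the model
collapses to the Porous-Fisher equation with diffusivity $R u$, whose sharp
wave and minimum speed $\sqrt{R/2}$ are known exactly
(`porous_fisher_wave()`).

Two families of initial data are built in (`initial_condition()`): a
compactly supported Heaviside block of length $\beta$ (the biologically
realistic seeding), which selects the *sharp-fronted* wave moving at the
minimum speed $c_{\min}(r_1, r_2)$, and an exponentially decaying profile
$u \sim e^{-a(x-\beta)}$, which selects a *smooth-fronted* wave whose speed
follows the dispersion relation $c = 1/a$ as long as $a$ stays below a
critical decay rate; beyond it the measured speed plateaus near $c_{\min}$.
We use $\beta = 10$ throughout; the long-time wave is independent of this
choice, which the test suite checks.

## Time-dependent solver

`solve_1d()` integrates the nondimensional system with backward Euler in
time and Picard linearisation: within each step the degenerate flux
coefficient and the logistic factor are frozen at the previous iterate,
the (pointwise, linear) substrate equation is updated implicitly from the
current cell-density iterate, and the resulting tridiagonal systems are
solved directly. Iteration stops when the max-norm update falls below
`picard_tol` ($10^{-10}$ by default; this plays the role usually given to
an iteration tolerance $\epsilon$ in schemes of this type). A
linear-extrapolation predictor seeds each step, and the solve is
restricted to the active region (nodes at exact zero ahead of the support
are invariant), which matters for long compact-support runs.

Boundary conditions are no-flux at $x = 0$ and $u = 0$ at the truncation
boundary $x = X$; the substrate equation has no spatial derivatives and
needs none. $X$ is chosen per run so the tracked front stays at least 20
space units clear of the boundary (150 for slowly decaying initial data,
50–100 otherwise). Negative round-off undershoot in $(-10^{-9}, 0)$ is
clipped to zero; anything below $-10^{-6}$ raises an error.

Two spatial discretisations of $(s u_x)_x$ are provided
(`solver_settings(scheme = ...)`):

* `"central"` (default): the expanded form $s u_{xx} + s_x u_x$ with
  central differences;
* `"conservative"`: the finite-volume form with arithmetic-mean face
  coefficients, which conserves mass up to the reaction terms.

Both converge to the same solution under refinement. We default to the
central form because its front-speed error on under-resolved sharp fronts
is about half that of the arithmetic-mean flux: any scheme must regularise
the degenerate front, where the discrete flux into the first
substrate-free cell controls the measured invasion speed, and the central
form leaks less. Smooth sub-critical waves are insensitive to this choice.

### Resolution and the two-stage front protocol

Smooth waves on the dispersion branch ($a \le 2$ here) are broad on the
scale of $\Delta x = 10^{-2}$ and their measured speeds change by well
under 0.01 upon refinement, so single runs at $\Delta x = 10^{-2}$,
$\Delta t = 10^{-3}$ to $t = 60$ suffice. Sharp and near-critical fronts
are steep on that scale and their measured speed carries a first-order
front-leak bias; refining the whole domain to convergence is wasteful
because all the structure sits within a few units of the front.
`measure_wave_speed(refine = TRUE)` therefore runs a coarse
$\Delta x = 10^{-2}$ simulation to $t = 40$, interpolates a window from 12
units behind to 16 units ahead of the front onto $\Delta x = 10^{-3}$, and
continues to $t = 60$, measuring the speed on the fine stage (the
post-refinement transient dies within about two time units; the fit uses
the final third). For the reference sharp wave ($r_1 = r_2 = 1$) this
reproduces the single-stage fine-grid speed to four decimals at roughly a
tenth of the cost, and further refinement to $\Delta x = 2\times10^{-4}$
moves the estimate by well under 0.005 — the two-decimal reporting
precision used throughout.

One consequence of measuring at converged resolution is worth stating
plainly: for $r_1 = r_2 = 1$ the minimum speed measures 0.29, and the
plateau speed for fast-decaying initial data ($a = 5$) also measures 0.29,
but for $a = 10/3$ — which lies just below the critical decay rate
$1/c_{\min} \approx 3.5$ — the converged speed is 0.30, in agreement with
the dispersion relation $c = 1/a$ rather than with the plateau. On coarse
grids this run is easily mistaken for a plateau wave because the
discretisation steepens its (already steep) tail. `scripts/acceptance.R`
reports the converged value.

## Wave-speed measurement

`front_position()` defines the front as the largest $x$ where $u$ crosses
a level (0.5 by default), by linear interpolation between nodes; the model
never defines a front coordinate, and for a rigidly translating wave the
choice of level is immaterial, which we assert by comparing estimates at
levels 0.5 and 0.05. `estimate_wave_speed()` fits a least-squares line to
the front position over the final third of the stored snapshots and flags
the estimate as converged when the slopes over the two halves of that
window differ by less than 0.005 (half the two-decimal reporting
precision). Non-convergence is a warning, not an error, so parameter
sweeps (`cmin_heatmap()`, `dispersion_sweep()`) can report it per cell.

## Phase space, slow manifold and front classification

In the wave frame $z = x - ct$ the profiles satisfy a three-dimensional
system in $(U, S, W = \mathrm{d}U/\mathrm{d}z)$ that is singular where
$S = 0$ (`tw_rhs_smooth()`). Rescaling the independent variable by
$\mathrm{d}\zeta = \mathrm{d}z/S$ gives a desingularised system
(`tw_rhs_desing()`) that is regular everywhere and valid for both front
types. Both systems share the invaded equilibrium $(1, R, 0)$ and the
uninvaded origin. `equilibrium_eigenvalues()` returns the closed-form
eigenvalues alongside a numerical eigendecomposition of the Jacobian; the
two agree to $10^{-10}$ over randomised parameters in the tests. The
origin is non-hyperbolic (eigenvalues $-c, 0, 0$), so the local dynamics
live on a slow manifold, computed to quadratic order by centre-manifold
reduction:

$$W(U, S) = \frac{1}{c^3}\left[(c^2 - r_1)U^2 - (1 - r_2)US - c^2 U\right].$$

The geometric dichotomy is then: smooth-fronted waves enter the origin
*along* this surface, sharp-fronted waves enter *directly*, off it.
`classify_front()` makes that operational: it reads the orbit at 24
log-spaced density levels across the tail window
$U \in (10^{-3}, 10^{-2})$ (linear interpolation on the monotone leading
tail) and computes the relative deviation of the measured $W$ from the
manifold graph at each level, reporting `smooth` below a median of 0.1,
`sharp` above 0.5, and `indeterminate` between — the distinction itself
is geometric and the thresholds are reporting conventions, so borderline
cases are surfaced rather than forced. In practice the two classes are
separated by orders of magnitude (medians near $10^{-3}$ versus $10^{3}$).
The orbit is extracted from the final PDE snapshot (`extract_orbit()`),
with $W$ from centred spatial differences — one snapshot suffices and
avoids time-interpolation error.

Levels, rather than raw samples, matter for the sharp case: unlike the
Porous-Fisher corner, whose density crosses the window over
$\sim 2c \ln 10 \approx 0.4$ space units, the substrate model's sharp
leading edge steepens toward a genuine density jump as the grid is
refined (window-crossing widths of $10^{-4}$ and below, still shrinking),
so no resolution ever places many nodes *inside* the window. The
classifier therefore anchors its resolution requirement on the front body
instead — at least 20 samples with $U$ between $10^{-2}$ and $1/2$ —
which any front-resolving grid satisfies; both front types classify
correctly straight from the study-resolution solutions.

`probe_subminimal_speed()` gives the phase-space view of why $c_{\min}$ is
minimal. For any $c$ the candidate connecting orbit leaves the invaded
saddle tangent to its *weak* unstable eigendirection (the strong one is a
pure substrate mode along which $S$ collapses or diverges with the cells
untouched; note that backward integration from the origin is not an
option here — the origin's stable eigenvector spans the invariant
$W$-axis, so backward orbits never unfold into the octant). The probe
traces the orbit by shooting: it starts a fixed displacement
$\varepsilon = 0.02$ from the saddle at a mixing angle between the two
oriented unstable eigenvectors, bisects the angle on the
substrate-collapse/substrate-divergence dichotomy, and truncates the best
shot at its closest approach to the origin (beyond which strong-mode
contamination, amplified like $e^{(\lambda_1-\lambda_2)\zeta}$, takes
over — which also bounds how small $\varepsilon$ can usefully be). For
admissible speeds the traced orbit stays in the physical octant; for
$c < c_{\min}$ part of it has $U < 0$, on arcs away from the equilibria.
That is also why no closed form for $c_{\min}(r_1, r_2)$ follows from
linearisation, and the package does not attempt one.

## Reference solutions

`substrate_from_profile()` evaluates the exact substrate integral implied
by a given travelling cell-density profile by adaptive quadrature with an
analytic exponential-tail correction. `perturbation_solution()` builds
the large-speed expansion in $1/c^2$ on the stretched coordinate
$\hat z = z/c$: the leading front is the logistic $U_0 = 1/(1+e^{\hat z})$
(normalised so $U_0(0) = 1/2$), $S_0$ integrates the linear substrate
equation driven by $U_0$, and the first correction $U_1$ follows from an
integrating factor. For positive integer $r_2$ the package evaluates
$S_0$ in closed form; ahead of the front the closed form is a difference
of near-equal terms, so it is evaluated there through the exactly
equivalent alternating series
$r_1 \sum_{j\ge1} (-1)^{j+1} e^{-j\hat z}/(r_2+j)$, which keeps it within
$10^{-8}$ of the quadrature over $\hat z \in [-10, 10]$. $U_1$ is always
evaluated by quadrature with analytic derivatives of the integrand
($S_0' = r_2 S_0 - r_1 U_0$, $U_0'' = -U_0'(1-2U_0)$), which stays
determinate at large $\hat z$ where naive closed forms become
indeterminate. When comparing the composite $U_0 + U_1/c^2$ against a
simulated wave, both profiles are aligned to cross $1/2$ at $z = 0$ —
the expansion fixes its integration constant through $U_0$ alone, so the
composite's own midpoint shifts by $O(c^{-2})$ and aligning on $U_0$
would contaminate the comparison with a pure translation. At $c = 4$ the
aligned composite matches the simulated wave to a few times $10^{-4}$ in
the tests (the acceptance threshold is 0.02), and the wave-equation
residual of the composite falls by a factor of about 16 when $c$ doubles
from 2 to 4, as the $O(c^{-4})$ truncation error dictates.

## The two-dimensional pore simulation

`solve_2d()` integrates the dimensional model on the square pore with the
cell density held at carrying capacity on the boundary (cells seeded on
the scaffold walls) and an empty interior. The initial data are
inconsistent with the boundary values; the implicit scheme regularises
the discontinuity in the first step, and the tests check
grid-symmetric, monotone filling rather than any pointwise value — the
published account of this geometry is qualitative. The inner linear
solves use damped Jacobi rather than Gauss–Seidel so the discrete
solution retains all eight symmetries of the square to round-off.

## Synthetic fixtures: what they do and do not show

`generate_fixture()` provides inputs with known ground truth: a rigidly
translating profile (the speed estimator must recover its speed to
$10^{-10}$), an orbit integrated on the slow-manifold flow itself (the
classifier must call it smooth with near-zero deviation), and a spatially
uniform state (the solver must track the logistic/driven-linear closed
forms to $10^{-6}$). These validate the measurement machinery
independently of the PDE solver, and the solver against exact dynamics in
regimes without spatial structure. They do not exercise
experimental realities — noisy density estimates, finite imaging windows,
non-uniform seeding — so passing them says the mathematics is implemented
correctly, not that the model fits any particular dataset.

## Problem sizes

The study-resolution runs behind the reported speeds use
$\Delta x = 10^{-2}$ ($n$ up to 15\,001 nodes) for sub-critical smooth
waves and the two-stage protocol (fine stage $\Delta x = 10^{-3}$ over a
28-unit window, about 28\,001 nodes) for sharp and near-critical fronts,
all with $\Delta t = 10^{-3}$ to $t = 60$. Parameter sweeps in the test
suite run at deliberately coarser resolution ($\Delta x = 0.02$,
$\Delta t = 0.01$, $t \le 40$) because they assert qualitative structure
(monotonicity, bounds, independence properties) rather than two-decimal
speeds. The 2D pore simulation uses the $101 \times 101$ mesh and
$\Delta \hat t = 10^{-2}$ day of the motivating experiments.

## Known limitations

* The minimum wave speed is measured, never derived; no analytic
  $c_{\min}(r_1, r_2)$ or critical decay rate is available.
* The small-$r_1$ square-root scaling of $c_{\min}$ is visible but
  expensive to verify to tight tolerance: slow fronts are extremely steep
  and converge slowly in time, so the suite does not assert the exponent.
* Perturbation terms beyond $U_1$ are not implemented (no closed forms
  exist), and the generalised diffusivity model $D(s)$ is out of scope.
* Sharp-front speeds on coarse grids are biased upward by the front
  regularisation in either spatial scheme; quantitative speeds should
  always come from `measure_wave_speed(refine = TRUE)` or an equivalent
  refinement study.
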