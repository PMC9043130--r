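---
title: "Computing single-channel permeability three ways: methods and design notes"
author: "permeakit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computing single-channel permeability three ways}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(permeakit)
```

## The problem

Single-channel permeability $P$ (cm$^3$/s) is the intrinsic,
concentration-independent measure of how readily an ion or small solute
crosses a channel. It is related to the equilibrium crossing rate $k$ and
mean first passage time (MFPT) $\langle t\rangle$ at symmetric concentration
$c$ by $P = k/c = 1/(c\,\langle t\rangle)$, and to the unitary conductance
$\gamma$ of a charged permeant by the Goldman–Hodgkin–Katz (GHK) relation.
Because $k$, $\langle t\rangle$ and $\gamma$ all depend on $c$ while $P$
does not, $P$ is the right quantity for comparing independent computational
routes against each other.

permeakit implements three such routes over one-dimensional
collective-variable trajectories $z(t)$ (the permeant's position along the
pore axis, in Å, sampled at a fixed stride in ps):

1. **ISD (solubility–diffusion)**: from a potential of mean force $w(z)$ and
   a position-dependent diffusion profile $D(z)$,
   $$P = \pi r^2\Big(\int_{z_1}^{z_2}\frac{e^{\beta w(z)}}{D(z)}\,dz\Big)^{-1},$$
   where $[z_1, z_2]$ is the pore interval beyond which $w$ is at its bulk
   value and $r$ is the radius of the lateral flat-bottom restraint that
   confines the tagged particle in the bulk. The $\pi r^2$ factor is what
   ties the restrained single-particle simulation to a bulk concentration:
   one particle per cylinder of radius $r$ *defines* the effective
   concentration, and offsetting $w$ to zero over that bulk region makes $P$
   independent of it.
2. **Milestoning MFPT**: Voronoi cells partition the axis, the shared edges
   are milestones, and confined (soft-wall) sampling in each cell yields a
   Markov rate matrix over milestones whose absorbing solves give MFPT
   profiles in both directions. $P$ follows either from
   $1/(c\,\langle t\rangle)$ with the effective bulk concentration, or from
   $$P = \frac{\pi r^2 \int_{z_1}^{z_2} e^{-\beta w(z)}dz}{2\,\langle t\rangle},$$
   whose factor 2 reflects that at equilibrium half of the first-passage
   flux crosses in each direction.
3. **Steady-state flux**: permeation events (or charge displacement) under a
   uniform field give currents, a linear I–V fit gives $\gamma$, and
   $P = \gamma k_BT/(q^2 C)$ converts it.

On top of these the package ships an overdamped Langevin (Brownian
dynamics, BD) simulator, so every estimator can be validated against
trajectories whose generating $w(z)$ and $D(z)$ are known exactly.

## The estimators

### PMF by self-consistent reweighting

`estimate_pmf()` implements binned WHAM: histograms of each harmonically
biased window are combined through the self-consistent equations for the
unbiased bin probabilities and per-window free-energy offsets, iterated to a
tolerance on the offsets (default $10^{-7}$ kcal/mol). The bin width
defaults to 0.2 Å — fine enough that bin-discretization error is far below
sampling noise for kcal/mol-scale barriers sampled at 2 Å window spacing.
For one-dimensional binned data this estimator agrees with
multistate-reweighting (MBAR-style) estimators to within bin-discretization
error, which is why no external reweighting dependency is used. Error bars,
when requested, come from a two-block analysis (re-estimating the PMF from
each half of every window and taking half the absolute difference); this is
estimator-agnostic, directly mirrors the standard block-comparison
convergence check, and costs two extra WHAM solves.

Degenerate inputs are rejected loudly: windows whose sampled ranges do not
overlap raise a coverage error naming the gap, as do interior empty bins;
non-convergence at `max_iter` raises an error carrying the residual.

### Position-dependent diffusion

For each restrained window $i$, $D(z_i) = \langle\delta z^2\rangle_i/\tau_i$:
the sampled variance divided by the integrated autocorrelation time.
For an overdamped harmonic well this is the exact Ornstein–Uhlenbeck
identity, and notably it is independent of the restraint stiffness —
doubling $k$ halves both the variance and $\tau$ — which the tests assert.

$\tau$ is the lag-sum of the normalized autocovariance (trapezoid in lag
time, so the lag-0 term enters with weight $\tfrac12$), truncated at the
first lag where the normalized autocovariance drops below 0.01 or crosses
zero, whichever comes first. A truncation rule is necessary: integrating
the full noisy tail of an empirical autocorrelation diverges. The 0.01
cutoff trades a $\sim$1% truncation bias against tail noise; it is a
declared choice, scanned up to 10% of the series length. The lag sums are
evaluated by FFT, which computes exactly the same sums as direct summation
at $O(n\log n)$. The estimate is stride-robust while the stride resolves
$\tau$ (stride $\lesssim \tau/10$); beyond that the variance is still right
but $\tau$ loses resolution, and a heuristic warning fires when the series
is shorter than 100 decorrelation times.

### Quadratures

ISD permeability, the resistance profile and the Smoluchowski MFPT
$$\langle t\rangle = \int_{z_1}^{z_2}\frac{e^{\beta w(z)}}{D(z)}
  \int_{z_1}^{z}e^{-\beta w(z')}\,dz'\,dz$$
use trapezoidal quadrature on the PMF grid with $D$ interpolated linearly
onto it. The tests hold the trapezoid result to within 0.1% of a 100×-finer
Riemann oracle on a 0.05 Å grid; on flat profiles all three routes coincide
to machine precision, which pins down the constants. Exponentials of
$\beta w$ are computed with the grid extremum subtracted and restored, so
large barriers cannot overflow. The inner integral starts at $z_1$
(reflecting at $z_1$, absorbing at $z_2$), matching the outward
first-passage construction; the inward MFPT is the same quadrature on the
mirrored profile.

### Milestoning

Cell-confined trajectories are scanned with a sample-based crossing rule: a
milestone hit is logged at a sample lying at or beyond a cell edge when the
previous sample was not in that edge region. No interpolation of exact
crossing times is attempted — fixed-stride output cannot support it, and
the stride-sensitivity tool (`stride_sensitivity()`) quantifies the bias
this induces instead of hiding it. Consequences of the rule, all
deliberate: a sample landing exactly on an edge is a hit (deterministic
tie-break); a trajectory that starts beyond an edge logs nothing until it
re-enters and crosses again; and all time before the first hit is discarded
as burn-in (the estimator needs a defined last-hit milestone, and the
pre-first-hit segment has none).

Equilibrium cell weights $\pi$ solve the attempted-escape balance equation,
with one escape counted per contiguous excursion past an edge — counting
frames instead would overweight stiff restraints, since a single physical
escape attempt spans several frames of excursion. Rates between milestones
$S_{ij}\to S_{ik}$ are
$\pi_i n^i_{jk} / (\pi_i r^i_{ij} + \pi_j r^j_{ij})$: transition counts from
the shared cell over the $\pi$-weighted residence on the starting milestone
from both adjacent cells. MFPT profiles solve the absorbing linear system
once per target milestone, restricted to the milestones preceding the
target — exact for a chain ordered along a scalar coordinate, where a
walker cannot pass the target unseen, and robust when milestones beyond
the target are themselves absorbing; the inward profile reverses the
milestone indices. On a symmetric system the two profiles must be mirror images —
that, not a fit statistic, is the convergence criterion, and the tests
enforce it within two combined block standard errors (4 contiguous blocks
per cell). Diagnostics report per-cell minimum/maximum waiting times
between transitions and the positional decorrelation time; the Markov
assumption is comfortable when decorrelation is faster than the shortest
waiting time.

### Flux under voltage

Event counting uses a strict lower→inner→upper state machine on region
labels (boundary samples are inner, by the open-interval convention):
returns to the starting side emit nothing, and periodic wrap jumps can
never register because they skip the inner region. Charge displacement sums
per-step displacements clipped to the pore interval and normalized by the
pore length; wrap events recorded by the simulator are unfolded so a
re-entry contributes its true path. The two estimators converge on the same
driven trajectories (the tests require 5%), which is the standard internal
consistency check for flux runs. The I–V fit is ordinary least squares
*with* an intercept: forcing the line through the origin would silently
absorb any asymmetry, whereas reporting the intercept exposes it.

## The synthetic-data generator

`simulate_bd()` integrates the overdamped Langevin equation with the
Euler–Maruyama scheme,
$$z \leftarrow z + \big[\beta D(z)F(z) + D'(z)\big]\,dt
  + \sqrt{2D(z)\,dt}\;\xi,$$
with $F = -\,d(w+\text{biases})/dz$. The $D'(z)$ term is the Itô
spurious-drift correction; it is exactly what makes the stationary law
Boltzmann when $D$ varies with position, and the test suite asserts this
(Kolmogorov–Smirnov distance to the analytic Boltzmann CDF below 0.05 at
$10^6$ steps, for both constant and strongly varying tabulated $D$).
Potentials and diffusion profiles are tabulated with forces on a fine
uniform grid (0.01 Å) and interpolated linearly in the compiled core;
harmonic and constant forces are linear in $z$, so their interpolation is
exact. Reflecting boundaries mirror the position at the domain edges —
the simplest scheme whose stationary law is correct at these time steps.
Replicas draw sequentially from a single RNG stream seeded once by the
master seed, so any ensemble is reproducible from one integer.

The generator emulates the statistical structure of restrained
molecular-dynamics output of a tagged permeant: a single particle on a 1-D
free-energy surface with position-dependent diffusion, under harmonic
(umbrella), flat-bottom (cell-confining, lateral-bulk) or constant-force
(voltage) biases, recorded at a fixed output stride. It does *not* emulate
inertial dynamics, orthogonal degrees of freedom, memory effects, explicit
solvent or ion–ion interactions. Passing tests on these fixtures therefore
demonstrate that the estimators recover the truth of the assumed
overdamped 1-D model — the same model the ISD and Smoluchowski formulas
assume — not that the model describes any particular real channel.

### Study conditions baked into the fixtures

The fixture parameters mirror the conditions the estimators are designed
for: a symmetric Gaussian barrier of 4 kcal/mol (half-width 3 Å) on a
±12 Å pore — a physiologically relevant barrier that makes crossings rare
events; umbrella windows every 2 Å with $k = 2.5$ kcal/mol/Å$^2$ and 40 ns
of 0.5 ps-stride sampling per window; soft-wall cells of 2 Å with
$k = 100$ kcal/mol/Å$^2$; diffusion coefficients of 0.01–0.02 Å$^2$/ps, in
the range typical for an ion in a narrow pore; 300 K; and voltages of
±0.4 V across a 24 Å box. The milestoning fixture is sampled for 600 ns
per cell at 0.1 ps output so that integer subsampling reproduces the 0.2,
0.5 and 5 ps strides whose comparison drives the stride-sensitivity
analysis; its diffusion coefficient of 0.01 Å$^2$/ps keeps the
missed-recrossing bias of the 0.5 ps stride within the few-percent regime
in which the 0.2/0.5 ps pair is expected to agree. The BD time step is
0.01–0.02 ps for biased fixtures (the rms Brownian step stays an order of
magnitude below the narrowest potential feature) and up to 0.05 ps for
flat-potential field runs.

## Effective bulk concentrations and geometry

One tagged particle restrained to a bulk volume $V$ has effective
concentration $1/(N_A V)$; `single_particle_molarity()` evaluates this for
cylinders, hemispheres and hemispherical shells. A cylinder of $r = 6$ Å
and $L = 28$ Å gives 0.52 M. Direct volume computation gives 0.79 M for a
hemisphere of 10 Å and 1.47 M for a cylinder of $r=6$ Å, $L=10$ Å, a ratio
of 1.85 — the "factor of ~2" by which MFPTs from different bulk boundary
shapes must be rescaled before they can be compared. The package always
computes concentrations from the geometry rather than accepting printed
values, and the milestoning tests verify the scaling directly: widening
the bulk buffer cell lengthens the end-to-end MFPT by exactly the
quadrature-predicted bulk-volume factor.

## Numerical and design choices

* Internal units are Å, ps, kcal/mol and elementary charges; conversions to
  SI, eV, pA and pS happen only at API boundaries. This keeps
  $e^{\beta w}$ well-scaled for kcal/mol barriers. Constants are CODATA
  2018, frozen in `phys_constants` and exported via `constants_table()`.
* $1\ \text{Å}^3/\text{ps} \equiv 10^{-12}\ \text{cm}^3/\text{s}$ exactly;
  permeabilities are converted with that single factor.
* Trapezoid-vs-oracle, flat-limit identities and round-trip unit
  conversions are pinned at machine precision in the tests, so any future
  change to grids or constants that moves physics will fail loudly.
* Trajectory files are Colvars-style whitespace tables (`#` comments,
  scientific notation accepted, time in column 1); values are written at 10
  significant digits so read∘write round-trips bit-identically. Stride
  uniformity is enforced at 1e-9 ps absolute — files are written at fixed
  print precision, so a looser tolerance would mask real gaps.
* Block splitting drops the tail remainder rather than padding, preserving
  stationarity within blocks for error bars.
* Eq.-4-style MFPT-to-permeability conversion assumes a symmetric dominant
  barrier; the package encodes this as a cross-method *consistency
  property* (ISD and MFPT routes within 25% on a 4 kcal/mol symmetric
  barrier) rather than an identity, because the factor-2 derivation is not
  exact for arbitrary profiles.

## Known limitations

* Hit detection is sample-based; MFPTs carry a stride-dependent bias that
  `stride_sensitivity()` measures but does not correct. At 10× coarser
  stride the fixture MFPT inflates by tens of percent — the intended
  demonstration, not a defect to be calibrated away.
* The milestoning engine treats any scalar collective variable (axial $z$,
  radial shell index); it does not compute 2-D/3-D Voronoi tessellations or
  continuous-time (exact-crossing) milestoning.
* WHAM assumes uncorrelated samples within bins; error bars come from
  blocks, not from an analytic covariance model.
* The GHK conversion covers symmetric concentrations and constant field
  only; concentration-gradient and reversal-potential analyses are out of
  scope.
* All dynamics are memoryless and overdamped; none of the estimators can
  detect a violation of those assumptions from a single fixture — that is
  what the three-way cross-method comparison is for.
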