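# permeakit

Single-channel permeability from one-dimensional collective-variable
trajectories, by three independent routes that must agree when the sampling
is converged:

1. **Solubility–diffusion (ISD)** — from a potential of mean force `w(z)`
   (estimated here by self-consistent WHAM reweighting of umbrella-sampling
   windows) and a position-dependent diffusion profile `D(z)` (variance over
   integrated autocorrelation time per restrained window):

   `P = πr² ( ∫_{z1}^{z2} exp(βw(z)) / D(z) dz )⁻¹`

   where `r` is the radius of the lateral flat-bottom restraint that defines
   the effective bulk concentration, and `[z1, z2]` is the pore.

2. **Markovian milestoning** — Voronoi cells along the pore axis, soft-wall
   confined sampling per cell, a rate matrix over the shared cell edges
   (milestones), and mean-first-passage-time (MFPT) profiles in both
   directions from its absorbing solves:

   `P = πr² ∫ exp(−βw(z)) dz / (2 ⟨t⟩)`  or  `P = 1 / (c ⟨t⟩)`.

3. **Steady-state flux** — permeation-event counting (lower→inner→upper
   state machine) and charge-displacement currents under a uniform field, a
   linear I–V fit for the unitary conductance γ, and the
   Goldman–Hodgkin–Katz conversion `P = γ·kBT / (q²·C)`.

A compiled overdamped Langevin (Brownian dynamics) simulator with
position-dependent `D(z)` and umbrella / soft-wall / constant-force biases
generates ground-truth trajectories, so every estimator in the package is
validated against fixtures whose generating `w(z)` and `D(z)` are known
exactly — no molecular-dynamics engine required.

Intended users: simulators of ion channels and membrane transport who want
the three permeability routes, and their consistency checks, in one place
with an audited unit chain (Å/ps/kcal·mol⁻¹ internally; cm³/s, pS, pA, M at
the interfaces).

## Worked example

A symmetric 4 kcal/mol Gaussian barrier (half-width 3 Å) on a ±10 Å pore
with `D = 0.02 Å²/ps` and a 6 Å lateral bulk restraint:

```r
library(permeakit)

pot <- potential_gaussian_barrier(4, center = 0, width = 3)
z   <- seq(-10, 10, by = 0.05)
pmf <- pmf_profile(z, potential_eval(pot, z),
                   bulk_region = list(c(-10, -9), c(9, 10)))
d   <- diffusion_constant(0.02)
b   <- channel_bounds(-10, 10)

isd_permeability(pmf, d, r = 6, b)
#> <permeability_result> P = 9.237e-16 cm^3/s [ISD]

t_cross <- smoluchowski_mfpt(pmf, d, b)   # 456741.1 ps
mfpt_permeability(pmf, t_cross, r = 6, b)
#> <permeability_result> P = 9.237e-16 cm^3/s [MFPT]
```

The two equilibrium routes agree (for this symmetric single barrier, almost
exactly: the MFPT relation is derived from the ISD and Smoluchowski
expressions). The flux route on the worked two-point I–V example, with the
effective concentration of one ion in a 6 Å × 28 Å cylindrical bulk:

```r
fit  <- conductance_fit(c(-0.4, 0.4), c(-0.92, 0.92))
fit$conductance_pS                       # 2.3 pS
conc <- single_particle_molarity(bulk_geometry("cylinder", radius = 6, length = 28))
round(conc, 2)                           # 0.52 M
ghk_permeability(fit$conductance_pS, conc)
#> <permeability_result> P = 1.175e-15 cm^3/s [GHK]
```

To run the estimators on trajectory data instead of analytic profiles:
`read_cv_series()` parses Colvars-style time/value tables,
`estimate_pmf()` / `estimate_diffusion()` consume lists of
`umbrella_window()` objects, and `milestoning_model()` consumes
`cell_sampling()` objects over a `cell_partition()`; see the package
vignette for the estimator details and `?permeakit_cli` (plus
`inst/scripts/permeakit`) for the command-line interface
(`simulate | pmf | diffusion | isd | milestone | flux | report`).

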