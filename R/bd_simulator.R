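#' Potential specifications
#'
#' A 1-D free-energy surface w(z) in kcal/mol on which the Brownian-dynamics
#' simulator runs. Three forms: `potential_flat()` (w = 0 everywhere),
#' `potential_gaussian_barrier()` (a Gaussian bump of given height, centre and
#' width sigma), and `potential_tabulated()` (natural cubic-spline
#' interpolation through supplied knots; the interpolant reproduces the knots
#' exactly).
#'
#' @param height Barrier height, kcal/mol.
#' @param center Barrier centre, angstrom.
#' @param width Gaussian sigma, angstrom (> 0).
#' @param z,w Knot positions (strictly increasing, angstrom) and values
#'   (kcal/mol) for the tabulated form.
#' @return An object of class `potential_spec`.
#' @name potential_spec
NULL

#' @rdname potential_spec
#' @export
potential_flat <- function() {
  structure(list(form = "flat"), class = "potential_spec")
}

#' @rdname potential_spec
#' @export
potential_gaussian_barrier <- function(height, center = 0, width = 1) {
  stopifnot(is.finite(height), is.finite(center), is.finite(width), width > 0)
  structure(list(form = "gaussian_barrier", height = height, center = center,
                 width = width), class = "potential_spec")
}

#' @rdname potential_spec
#' @export
potential_tabulated <- function(z, w) {
  stopifnot(length(z) == length(w), length(z) >= 4L, all(is.finite(z)),
            all(is.finite(w)))
  if (any(diff(z) <= 0)) stop("tabulated grid must be strictly increasing")
  sf <- stats::splinefun(z, w, method = "natural")
  structure(list(form = "tabulated", z = z, w = w, spline = sf),
            class = "potential_spec")
}

#' Evaluate a potential or its force
#' @param p A `potential_spec`.
#' @param z Positions, angstrom.
#' @return `potential_eval`: w(z) in kcal/mol. `potential_force`: -dw/dz in
#'   kcal/mol/angstrom.
#' @export
potential_eval <- function(p, z) {
  stopifnot(inherits(p, "potential_spec"))
  switch(p$form,
    flat = rep(0, length(z)),
    gaussian_barrier = p$height * exp(-(z - p$center)^2 / (2 * p$width^2)),
    tabulated = p$spline(z))
}

#' @rdname potential_eval
#' @export
potential_force <- function(p, z) {
  stopifnot(inherits(p, "potential_spec"))
  switch(p$form,
    flat = rep(0, length(z)),
    gaussian_barrier = p$height * (z - p$center) / p$width^2 *
      exp(-(z - p$center)^2 / (2 * p$width^2)),
    tabulated = -p$spline(z, deriv = 1))
}

#' Diffusion specifications
#'
#' Position-dependent diffusion coefficient D(z) in \eqn{\mathrm{\AA^2/ps}},
#' either constant or a natural cubic spline through knots. Must be strictly
#' positive on its domain.
#'
#' @param D Constant diffusion coefficient (> 0).
#' @param z,values Knots for the tabulated form.
#' @return An object of class `diffusion_spec`.
#' @name diffusion_spec
NULL

#' @rdname diffusion_spec
#' @export
diffusion_constant <- function(D) {
  stopifnot(is.finite(D), D > 0)
  structure(list(form = "constant", D = D), class = "diffusion_spec")
}

#' @rdname diffusion_spec
#' @export
diffusion_tabulated <- function(z, values) {
  stopifnot(length(z) == length(values), length(z) >= 4L)
  if (any(diff(z) <= 0)) stop("tabulated grid must be strictly increasing")
  if (any(values <= 0)) stop("D must be positive everywhere")
  sf <- stats::splinefun(z, values, method = "natural")
  structure(list(form = "tabulated", z = z, values = values, spline = sf),
            class = "diffusion_spec")
}

#' @rdname diffusion_spec
#' @param d A `diffusion_spec`.
#' @export
diffusion_eval <- function(d, z) {
  stopifnot(inherits(d, "diffusion_spec"))
  switch(d$form,
    constant = rep(d$D, length(z)),
    tabulated = d$spline(z))
}

diffusion_deriv <- function(d, z) {
  switch(d$form,
    constant = rep(0, length(z)),
    tabulated = d$spline(z, deriv = 1))
}

#' Bias specifications
#'
#' Restraining or driving potentials added to w(z): a harmonic restraint
#' (umbrella window), a flat-bottom harmonic restraint (soft-wall cell
#' confinement), or a constant force (uniform field along z).
#'
#' @param k Force constant, kcal/mol/A^2 (>= 0).
#' @param center Harmonic centre, angstrom.
#' @param lower,upper Flat-bottom edges (`lower < upper`), angstrom.
#' @param f Constant force, kcal/mol/A (positive pushes toward +z).
#' @return An object of class `bias_spec`.
#' @name bias_spec
NULL

#' @rdname bias_spec
#' @export
bias_harmonic <- function(k, center) {
  stopifnot(is.finite(k), k >= 0, is.finite(center))
  structure(list(kind = "harmonic", k = k, center = center), class = "bias_spec")
}

#' @rdname bias_spec
#' @export
bias_flat_bottom <- function(k, lower, upper) {
  stopifnot(is.finite(k), k >= 0, is.finite(lower), is.finite(upper))
  if (lower >= upper) stop("flat-bottom bias requires lower < upper")
  structure(list(kind = "flat_bottom", k = k, lower = lower, upper = upper),
            class = "bias_spec")
}

#' @rdname bias_spec
#' @export
bias_constant_force <- function(f) {
  stopifnot(is.finite(f))
  structure(list(kind = "constant_force", f = f), class = "bias_spec")
}

bias_potential <- function(b, z) {
  switch(b$kind,
    harmonic = 0.5 * b$k * (z - b$center)^2,
    flat_bottom = 0.5 * b$k * (pmax(z - b$upper, 0)^2 + pmin(z - b$lower, 0)^2),
    constant_force = -b$f * z)
}

bias_force <- function(b, z) {
  switch(b$kind,
    harmonic = -b$k * (z - b$center),
    flat_bottom = -b$k * (pmax(z - b$upper, 0) + pmin(z - b$lower, 0)),
    constant_force = rep(b$f, length(z)))
}

#' Simulation configuration
#'
#' @param dt Integration time step, ps (default 0.01; chosen so the rms
#'   Brownian step stays well below the narrowest potential feature of the
#'   shipped fixtures).
#' @param n_steps Number of integration steps.
#' @param temperature Temperature, K.
#' @param seed Integer RNG seed, or `NULL` to use the current RNG state.
#' @param output_stride Record every this many steps (>= 1).
#' @param initial_z Starting position, angstrom.
#' @param domain Simulation domain `c(lo, hi)`, angstrom.
#' @param boundary `"reflect"` (mirror reflection at the domain edges) or
#'   `"error"` (a step escaping the domain aborts, naming the step).
#' @param absorbing_bounds Optional `c(z_lo, z_hi)` for first-passage mode;
#'   use `-Inf`/`Inf` to disable one side (that side is then reflecting at
#'   the domain edge). `initial_z` must lie strictly inside.
#' @param max_steps Step budget per first-passage replica (default 1e8).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(dt = 0.01, n_steps = 1e5, temperature = 300,
                       seed = NULL, output_stride = 1L, initial_z = 0,
                       domain = c(-20, 20), boundary = c("reflect", "error"),
                       absorbing_bounds = NULL, max_steps = 1e8) {
  boundary <- match.arg(boundary)
  stopifnot(dt > 0, n_steps >= 1, temperature > 0, output_stride >= 1,
            length(domain) == 2L, domain[1] < domain[2])
  if (!is.null(absorbing_bounds)) {
    stopifnot(length(absorbing_bounds) == 2L)
    lo <- absorbing_bounds[1]; hi <- absorbing_bounds[2]
    if (is.finite(lo) && initial_z <= lo || is.finite(hi) && initial_z >= hi)
      stop("initial_z must lie strictly inside the absorbing bounds")
  }
  structure(list(dt = dt, n_steps = n_steps, temperature = temperature,
                 seed = seed, output_stride = as.integer(output_stride),
                 initial_z = initial_z, domain = domain, boundary = boundary,
                 absorbing_bounds = absorbing_bounds, max_steps = max_steps),
            class = "sim_config")
}

# Tabulate total force, D and D' on a uniform fine grid over the domain.
# Harmonic and constant forces are linear in z, so linear interpolation is
# exact; flat-bottom kinks and smooth potentials incur O(dz^2) local error.
build_force_grids <- function(p, d, biases, domain, extra_force = 0,
                              dz = 0.01) {
  n <- max(16L, ceiling(diff(domain) / dz) + 1L)
  zg <- seq(domain[1], domain[2], length.out = n)
  Fg <- potential_force(p, zg) + extra_force
  for (b in biases) Fg <- Fg + bias_force(b, zg)
  Dg <- diffusion_eval(d, zg)
  if (any(Dg <= 0)) stop("D must be positive over the simulation domain")
  dDg <- diffusion_deriv(d, zg)
  list(meta = c(zg[1], zg[2] - zg[1], n), Fg = Fg, Dg = Dg, dDg = dDg)
}

#' Simulate overdamped Langevin dynamics on w(z) with D(z)
#'
#' Euler–Maruyama integration of
#' \deqn{z \leftarrow z + [\beta D(z) F(z) + D'(z)]\,dt + \sqrt{2 D(z) dt}\,\xi}
#' with \eqn{F = -d(w + \sum \mathrm{biases})/dz} and \eqn{\xi} standard
#' normal. The Itô spurious-drift term \eqn{D'(z)} keeps the stationary
#' distribution proportional to \eqn{e^{-\beta w_{tot}}} when D varies with
#' position. Deterministic for a fixed seed.
#'
#' @param p A `potential_spec`.
#' @param d A `diffusion_spec`.
#' @param biases List of `bias_spec` objects (may be empty).
#' @param cfg A [sim_config()].
#' @param label Label for the returned series.
#' @return A [cv_series()] sampled every `output_stride` steps (including the
#'   initial position at t = 0).
#' @export
simulate_bd <- function(p, d, biases = list(), cfg = sim_config(),
                        label = "bd") {
  stopifnot(inherits(cfg, "sim_config"))
  if (inherits(biases, "bias_spec")) biases <- list(biases)
  g <- build_force_grids(p, d, biases, cfg$domain)
  beta <- inv_thermal_energy(cfg$temperature)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  res <- bd_run_core(cfg$initial_z, cfg$n_steps, cfg$dt, cfg$output_stride,
                     g$meta, g$Fg, g$Dg, g$dDg, beta,
                     cfg$domain[1], cfg$domain[2],
                     if (cfg$boundary == "reflect") 1L else 0L)
  dt_out <- cfg$dt * cfg$output_stride
  cv_series(seq_along(res$z) * dt_out - dt_out, res$z, label = label,
            metadata = list(seed = cfg$seed, dt = cfg$dt,
                            output_stride = cfg$output_stride,
                            temperature = cfg$temperature))
}

#' First-passage times through absorbing bounds
#'
#' Runs `n_replicas` independent trajectories from `cfg$initial_z` until the
#' first exit through either absorbing bound (continuous-time stepping, no
#' output stride). Replicas are drawn sequentially from one RNG stream seeded
#' by `cfg$seed`, so the whole ensemble is reproducible from the master seed.
#'
#' @inheritParams simulate_bd
#' @param n_replicas Number of independent replicas.
#' @return A data.frame with columns `time` (ps), `side` (-1 lower exit, +1
#'   upper exit), `censored` (TRUE when the step budget was exhausted before
#'   exit; such times are lower bounds, never silently dropped).
#' @export
first_passage_times <- function(p, d, cfg, n_replicas = 100L) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(cfg$absorbing_bounds))
    stop("cfg$absorbing_bounds must be set for first-passage mode")
  g <- build_force_grids(p, d, list(), cfg$domain)
  beta <- inv_thermal_energy(cfg$temperature)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  res <- bd_fpt_core(rep(cfg$initial_z, n_replicas), cfg$dt, g$meta,
                     g$Fg, g$Dg, g$dDg, beta,
                     cfg$domain[1], cfg$domain[2],
                     cfg$absorbing_bounds[1], cfg$absorbing_bounds[2],
                     cfg$max_steps)
  if (any(res$censored))
    warning(sum(res$censored), " replica(s) censored at the step budget")
  data.frame(time = res$time, side = res$side, censored = res$censored)
}

#' Simulate particles under a uniform field with periodic wrapping
#'
#' Adds the electric force q*E to the drift and wraps positions periodically
#' on the simulation domain (a particle leaving one end re-enters at the
#' other; wrap events are recorded so unwrapped displacements can be
#' reconstructed for charge-displacement current accounting).
#'
#' @inheritParams simulate_bd
#' @param charge Permeant charge in units of e.
#' @param field Electric field in V/angstrom (positive drives a positive
#'   charge toward +z).
#' @param n_particles Number of independent particles.
#' @return A list of [cv_series()]; each has `metadata$wraps` (cumulative
#'   wrap count at each record, +1 per exit through the top) and
#'   `metadata$charge`.
#' @export
simulate_field <- function(p, d, charge, field, cfg, n_particles = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  if (diff(cfg$domain) <= 0) stop("zero wrap interval")
  # e * 1 V = 1 eV = 23.0605 kcal/mol, so force in kcal/mol/A is q*E*that
  f_field <- charge * field * convert_energy(1, "eV", "kcal/mol")
  g <- build_force_grids(p, d, list(), cfg$domain, extra_force = f_field)
  beta <- inv_thermal_energy(cfg$temperature)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  dt_out <- cfg$dt * cfg$output_stride
  lapply(seq_len(n_particles), function(i) {
    res <- bd_run_core(cfg$initial_z, cfg$n_steps, cfg$dt, cfg$output_stride,
                       g$meta, g$Fg, g$Dg, g$dDg, beta,
                       cfg$domain[1], cfg$domain[2], 2L)
    cv_series(seq_along(res$z) * dt_out - dt_out, res$z,
              label = sprintf("ion%d", i),
              metadata = list(wraps = res$wraps, charge = charge,
                              field = field, domain = cfg$domain,
                              seed = cfg$seed, particle = i))
  })
}
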