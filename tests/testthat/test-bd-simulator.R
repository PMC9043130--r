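test_that("fixed seed reproduces trajectories bit-identically", {
  cfg <- sim_config(dt = 0.01, n_steps = 5e3, seed = 99, output_stride = 5,
                    domain = c(-5, 5))
  a <- simulate_bd(potential_flat(), diffusion_constant(0.02),
                   list(bias_harmonic(2.5, 0)), cfg)
  b <- simulate_bd(potential_flat(), diffusion_constant(0.02),
                   list(bias_harmonic(2.5, 0)), cfg)
  expect_identical(a$values, b$values)
})

test_that("free diffusion obeys the MSD law and harmonic confinement equipartition", {
  # ensemble MSD at lag tau equals 2*D*tau (200 replicas, flat potential)
  D <- 0.02; tlag <- 10
  set.seed(301)
  disp <- vapply(1:200, function(i) {
    cfg <- sim_config(dt = 0.01, n_steps = 1000, seed = NULL,
                      output_stride = 1000, domain = c(-100, 100))
    ts <- simulate_bd(potential_flat(), diffusion_constant(D), list(), cfg)
    ts$values[2] - ts$values[1]
  }, numeric(1))
  msd <- mean(disp^2)
  se <- sd(disp^2) / sqrt(length(disp))
  expect_lt(abs(msd - 2 * D * tlag), 3 * se)

  # harmonic bias k = 2.5 at 300 K: sample variance -> kBT/k within 5%
  ou <- fx_ou_series()
  expect_equal(var(ou$values), kBT300 / 2.5, tolerance = 0.05)
})

test_that("stationary distribution is Boltzmann, also with position-dependent D", {
  ks_dist <- function(z, pot, domain) {
    zg <- seq(domain[1], domain[2], length.out = 2001)
    dens <- exp(-potential_eval(pot, zg) / kBT300)
    cdf <- cumsum(dens) / sum(dens)
    emp <- ecdf(z)(zg)
    max(abs(emp - cdf))
  }
  # a 1 kcal/mol barrier with D = 0.2 A^2/ps mixes across the wells a few
  # hundred times over the run, enough to pin the well occupancies
  pot <- potential_gaussian_barrier(1, 0, 1)
  cfg <- sim_config(dt = 0.01, n_steps = 5e6, seed = 71, output_stride = 10,
                    domain = c(-4, 4))
  ts <- simulate_bd(pot, diffusion_constant(0.2), list(), cfg)
  expect_lt(ks_dist(ts$values, pot, c(-4, 4)), 0.05)

  # tabulated, varying D: the D'(z) drift keeps the same stationary law
  zk <- seq(-4, 4, by = 0.5)
  dvar <- diffusion_tabulated(zk, 0.2 + 0.1 * sin(pi * zk / 4))
  ts2 <- simulate_bd(pot, dvar, list(),
                     sim_config(dt = 0.01, n_steps = 5e6, seed = 72,
                                output_stride = 10, domain = c(-4, 4)))
  expect_lt(ks_dist(ts2$values, pot, c(-4, 4)), 0.05)
})

test_that("first-passage times match closed form, symmetry and the Smoluchowski oracle", {
  # flat potential, reflecting at 0, absorbing at 20: mean FPT = L^2/2D
  D <- 0.02
  cfg <- sim_config(dt = 0.02, initial_z = 1e-3, domain = c(0, 20), seed = 3,
                    absorbing_bounds = c(-Inf, 20), max_steps = 1e8)
  fpt <- first_passage_times(potential_flat(), diffusion_constant(D), cfg,
                             n_replicas = 300)
  expect_false(any(fpt$censored))
  se <- sd(fpt$time) / sqrt(nrow(fpt))
  expect_lt(abs(mean(fpt$time) - 20^2 / (2 * D)), 3 * se)

  # symmetric start between two absorbing bounds: 50/50 exit sides
  cfg2 <- sim_config(dt = 0.02, initial_z = 0, domain = c(-5, 5), seed = 5,
                     absorbing_bounds = c(-5, 5), max_steps = 1e7)
  fpt2 <- first_passage_times(potential_flat(), diffusion_constant(D), cfg2,
                              n_replicas = 400)
  n_up <- sum(fpt2$side == 1)
  expect_gt(n_up, qbinom(0.0005, 400, 0.5))
  expect_lt(n_up, qbinom(0.9995, 400, 0.5))

  # Gaussian barrier: ensemble mean within 10% of the quadrature
  pot <- potential_gaussian_barrier(2.5, 0, 1)
  zg <- seq(-4, 4, by = 0.02)
  pmf <- pmf_profile(zg, potential_eval(pot, zg), bulk_region = c(-4, -3.5))
  sm <- smoluchowski_mfpt(pmf, diffusion_constant(D), channel_bounds(-4, 4))
  cfg3 <- sim_config(dt = 0.01, initial_z = -3.999, domain = c(-4, 4),
                     seed = 4, absorbing_bounds = c(-Inf, 4), max_steps = 1e9)
  fpt3 <- first_passage_times(pot, diffusion_constant(D), cfg3,
                              n_replicas = 200)
  expect_equal(mean(fpt3$time), sm, tolerance = 0.10)
})

test_that("uniform field produces the Einstein drift with odd symmetry", {
  D <- 0.02; V <- 0.4; Lbox <- 24
  f <- V / Lbox * 23.0605                 # kcal/mol/A on a +1 charge
  v_expect <- D * f / kBT300
  unwrap <- function(ts) ts$values + ts$metadata$wraps * diff(ts$metadata$domain)
  drift <- function(ts) {
    u <- unwrap(ts)
    (u[length(u)] - u[1]) / (ts$times[length(ts$times)] - ts$times[1])
  }
  up <- fx_field()$pos
  dn <- fx_field()$neg
  # s.e. of the mean velocity of one long run: sd of per-ns displacements
  u <- unwrap(up); chunk <- 250                       # 1 ns chunks
  dv <- diff(u[seq(1, length(u), by = chunk)]) / (chunk * up$stride)
  se <- sd(dv) / sqrt(length(dv))
  expect_lt(abs(drift(up) - v_expect), 3 * se)
  expect_lt(abs(drift(dn) + v_expect), 3 * se)

  # zero field: no systematic drift
  z0 <- fx_field_run(0, 23)
  expect_lt(abs(drift(z0)), 3 * se)
})

test_that("domain escapes abort with the step named under the error boundary", {
  cfg <- sim_config(dt = 0.05, n_steps = 1e4, seed = 1, domain = c(-0.5, 0.5),
                    boundary = "error")
  expect_error(simulate_bd(potential_flat(), diffusion_constant(0.5),
                           list(), cfg),
               "domain escape at step")
})

test_that("tabulated potentials reproduce their knots and reject bad grids", {
  z <- seq(-5, 5, by = 0.5)
  w <- 3 * exp(-z^2 / 4)
  p <- potential_tabulated(z, w)
  expect_equal(potential_eval(p, z), w, tolerance = 1e-12)
  expect_error(potential_tabulated(rev(z), w), "increasing")
  expect_error(diffusion_tabulated(z, w - 2), "positive")
  expect_error(diffusion_constant(0), "D > 0")
})
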