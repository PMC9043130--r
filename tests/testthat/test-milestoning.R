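mk_cell_series <- function(z, stride = 1) {
  cv_series(seq_along(z) * stride - stride, z)
}

test_that("hit detection follows the crossing rule on hand-traced paths", {
  part <- cell_partition(c(-3, -1, 1, 3))   # cell 2 spans [-1, 1]
  # starts beyond the left edge: no hit until it crosses +1 at the last step
  s <- cell_sampling(2, mk_cell_series(c(-1.2, -0.4, 0.3, -0.2, 1.1)), part)
  st <- detect_events(s)
  expect_equal(sum(st$counts), 0)               # no transition
  expect_equal(st$first_hit_time, 4)            # the final sample
  expect_equal(unname(st$residence["2"]), 0)    # hit at the last instant

  # crossing left edge then right edge: one left->right transition,
  # residence in between assigned to the left milestone
  s2 <- cell_sampling(2, mk_cell_series(c(0, -1.1, -0.5, 0.4, 1.2, 0.5)), part)
  st2 <- detect_events(s2)
  expect_equal(st2$counts["1", "2"], 1)
  expect_equal(sum(st2$counts), 1)
  expect_equal(unname(st2$residence["1"]), 3)   # samples 2..5 span 3 ps
  expect_equal(sum(st2$residence) , st2$T_assigned)

  # landing exactly on an edge counts as a hit of that milestone
  s3 <- cell_sampling(2, mk_cell_series(c(0, 1.0, 0.2, -1.0, 0)), part)
  st3 <- detect_events(s3)
  expect_equal(st3$counts["2", "1"], 1)
})

test_that("event statistics match a brute-force state-machine re-scan", {
  fx <- fx_milestoning()
  s <- fx$samps[[5]]                     # a steep-PMF cell
  sub <- cell_sampling(5, subsample(s$series, 10L), fx$part)  # keep it light
  st <- detect_events(sub)
  or <- oracle_scan_cell(sub$series$values, sub$series$stride,
                         fx$edges[5], fx$edges[6], 4L, 5L)
  expect_equal(unclass(st$counts), unclass(or$counts))
  expect_equal(st$residence, or$residence)
  expect_equal(st$T_assigned, or$T_assigned)
  # residence fractions over hit milestones sum to one
  expect_equal(sum(st$residence) / st$T_assigned, 1, tolerance = 1e-12)
})

test_that("equilibrium probabilities solve the balance equation", {
  # two cells, equal escape rates -> 50/50
  st2 <- list(fake_stats(1, 2, escapes = c(left = 0, right = 5), T_total = 10),
              fake_stats(2, 2, escapes = c(left = 5, right = 0), T_total = 10))
  expect_equal(solve_equilibrium(st2), c(0.5, 0.5))

  # three cells, k12=2, k21=1, k23=1, k32=2 -> (0.25, 0.5, 0.25)
  st3 <- list(fake_stats(1, 3, escapes = c(left = 0, right = 2), T_total = 1),
              fake_stats(2, 3, escapes = c(left = 1, right = 1), T_total = 1),
              fake_stats(3, 3, escapes = c(left = 2, right = 0), T_total = 1))
  pi3 <- solve_equilibrium(st3)
  expect_equal(pi3, c(0.25, 0.5, 0.25))
  expect_equal(sum(pi3), 1)

  # disconnected graph
  st_bad <- list(fake_stats(1, 3, escapes = c(left = 0, right = 0), T_total = 1),
                 fake_stats(2, 3, escapes = c(left = 0, right = 1), T_total = 1),
                 fake_stats(3, 3, escapes = c(left = 2, right = 0), T_total = 1))
  expect_error(solve_equilibrium(st_bad), "irreducibility")
})

test_that("cell free energies are -kBT ln(pi) with a bulk zero", {
  expect_equal(free_energy(rep(0.2, 5)), rep(0, 5))
  fe <- free_energy(c(0.25, 0.5, 0.25), reference_cells = 2)
  expect_equal(fe, c(0.413, 0, 0.413), tolerance = 1e-3)   # kBT ln 2
  expect_error(free_energy(c(0.5, 0, 0.5)), "zero")
})

test_that("rate matrix entries follow the two-cell residence-weighted formula", {
  # pi_1 = pi_2 = 0.25; n_2(S12->S23) = 0.005/ps; r_2(S12) = 0.5, r_1(S12) = 0.3
  T2 <- 1000
  cnt2 <- matrix(c(0, 0, 5, 0), 2, 2, dimnames = list(c("1", "2"), c("1", "2")))
  st <- list(
    fake_stats(1, 3, T_total = 1000, T_assigned = 1000,
               residence = c("1" = 300), escapes = c(left = 0, right = 1)),
    fake_stats(2, 3, T_total = T2, T_assigned = T2, counts = cnt2,
               residence = c("1" = 500, "2" = 500),
               escapes = c(left = 1, right = 1)),
    fake_stats(3, 3, T_total = 1000, T_assigned = 1000,
               residence = c("2" = 1000), escapes = c(left = 1, right = 0)))
  part <- cell_partition(c(0, 1, 2, 3))
  model <- build_rate_matrix(st, c(0.25, 0.25, 0.5), part)
  expect_equal(model$Q[1, 2], 0.25 * 0.005 / (0.25 * 0.5 + 0.25 * 0.3))
  expect_equal(model$Q[1, 2], 0.00625)
  expect_equal(rowSums(model$Q), rep(0, 2))

  # all-zero counts: zero matrix with a warning
  st0 <- lapply(st, function(s) { s$counts[] <- 0; s })
  expect_warning(m0 <- build_rate_matrix(st0, c(0.25, 0.25, 0.5), part),
                 "zero")
  expect_true(all(m0$Q == 0))
})

test_that("MFPT solves match 1/q and the birth-death closed form", {
  # two milestones, one-way rate 0.01/ps -> 100 ps
  Q <- matrix(c(0, 0.01, 0, 0), 2, 2, byrow = TRUE)
  m <- model_from_Q(Q)
  expect_equal(mfpt_end_to_end(m, "outward"), 100)

  # birth-death chain with uneven rates vs the summation formula
  a <- c(0.020, 0.050, 0.010, 0.040, 0.030)
  b <- c(0.030, 0.020, 0.050, 0.010)
  N <- 6
  Q <- matrix(0, N, N)
  for (i in 1:5) Q[i, i + 1] <- a[i]
  for (i in 1:4) Q[i + 1, i] <- b[i]
  m2 <- model_from_Q(Q)
  expect_equal(mfpt_end_to_end(m2, "outward"), oracle_birth_death_mfpt(a, b),
               tolerance = 1e-10)
})

test_that("milestoning recovers the Smoluchowski MFPT with mirror-symmetric profiles", {
  model <- fx_milestoning_model()
  sm <- fx_milestoning_oracle_mfpt()
  mf_out <- mfpt_end_to_end(model, "outward")
  mf_in <- mfpt_end_to_end(model, "inward")
  expect_lt(abs(mf_out - sm) / sm, 0.15)
  expect_lt(abs(mf_in - sm) / sm, 0.15)
  # inward/outward mirror symmetry within 2 combined standard errors
  se <- sqrt(mfpt_block_se(model, "outward")^2 +
             mfpt_block_se(model, "inward")^2)
  expect_lt(abs(mf_out - mf_in), 2 * se)
  # symmetric generating system: Q approximately equals its index-reversed
  # transpose (compare the dominant nearest-neighbour rates)
  K <- nrow(model$Q)
  Qr <- t(model$Q[K:1, K:1])
  offd <- row(model$Q) != col(model$Q) & abs(row(model$Q) - col(model$Q)) == 1
  expect_equal(model$Q[offd], Qr[offd], tolerance = 0.25)
  # free-energy barrier from pi matches the cell-averaged generating barrier
  fx <- fx_milestoning()
  fe <- free_energy(model$pi, reference_cells = c(1, 12))
  beta <- 1 / kBT300
  cell_avg <- vapply(seq_len(12), function(i) {
    zz <- seq(fx$edges[i], fx$edges[i + 1], length.out = 200)
    -kBT300 * log(mean(exp(-beta * potential_eval(fx$pot, zz))))
  }, numeric(1))
  cell_avg <- cell_avg - mean(cell_avg[c(1, 12)])
  expect_equal(max(fe), max(cell_avg), tolerance = 0.15)
})

test_that("waiting-time and decorrelation diagnostics behave as sampling allows", {
  fx <- fx_milestoning()
  model <- fx_milestoning_model()
  sub <- lapply(fx$samps[5:7], function(s)
    cell_sampling(s$cell_index, subsample(s$series, 5L), fx$part))
  d <- milestoning_diagnostics(sub, n_checkpoints = 4L)
  # min waiting time is at least one stride by construction
  expect_true(all(d$waiting$min_waiting >= sub[[1]]$series$stride - 1e-9))
  expect_true(all(d$waiting$max_waiting >= d$waiting$min_waiting))
  expect_true(all(d$waiting$decorrelation_time > 0))
  # convergence traces: final-checkpoint rates close to the full-data rates
  expect_true(all(c("n_rate", "r_from") %in% names(d$convergence)))
  expect_true(nrow(d$convergence) > 0)
})

test_that("coarse output strides inflate the MFPT by missing transitions", {
  fx <- fx_milestoning()
  tab <- stride_sensitivity(fx$samps, fx$part, factors = c(2L, 5L, 50L))
  # 0.2 ps and 0.5 ps (a 2.5x pair) agree within 5%
  expect_lt(abs(tab$mfpt[2] / tab$mfpt[1] - 1), 0.05)
  # 5 ps (10x the 0.5 ps baseline) inflates the MFPT by > 20%
  expect_gt(tab$mfpt[3] / tab$mfpt[2], 1.20)
  # and loses transition events
  expect_lt(tab$total_transitions[3], tab$total_transitions[2])
  # factor 1 reproduces the direct pipeline on the raw series
  one <- stride_sensitivity(fx$samps[1:12], fx$part, factors = 1L)
  direct <- milestoning_model(fx$samps, fx$part)
  expect_equal(one$mfpt, mfpt_end_to_end(direct, "outward"))
})

test_that("a wider bulk cell rescales the MFPT by the effective-concentration ratio", {
  pot <- potential_gaussian_barrier(2.5, 0, 2)
  D <- diffusion_constant(0.02)
  # narrow bulk: first cell [-8,-6]; wide bulk: first cell [-12,-6]
  edges_n <- seq(-8, 8, by = 2)
  edges_w <- c(-12, seq(-6, 8, by = 2))
  run_cells <- function(edges, dom_lo) {
    part <- cell_partition(edges)
    samps <- lapply(seq_len(part$n_cells), function(i) {
      lo <- edges[i]; hi <- edges[i + 1]
      cfg <- sim_config(dt = 0.02, n_steps = 1e7, seed = 900L + i,
                        output_stride = 10, initial_z = (lo + hi) / 2,
                        domain = c(dom_lo, 10))
      cell_sampling(i, simulate_bd(pot, D,
                                   list(bias_flat_bottom(100, lo, hi)), cfg),
                    part)
    })
    mfpt_end_to_end(milestoning_model(samps, part), "outward")
  }
  mf_n <- run_cells(edges_n, -10)
  mf_w <- run_cells(edges_w, -14)
  # quadrature prediction of the same ratio (reflecting at the bulk edge)
  pred <- local({
    mk <- function(lo) {
      zg <- seq(lo, 6, by = 0.05)
      pmf <- pmf_profile(zg, potential_eval(pot, zg),
                         bulk_region = c(lo, lo + 1))
      smoluchowski_mfpt(pmf, D, channel_bounds(lo, 6))
    }
    mk(-12) / mk(-8)
  })
  expect_gt(mf_w / mf_n, 1.1)            # more bulk volume, longer MFPT
  expect_equal(mf_w / mf_n, pred, tolerance = 0.15)
})

test_that("cell samplings reject series that sit in the wrong cell", {
  part <- cell_partition(c(-3, -1, 1, 3))
  bad <- mk_cell_series(rep(2.5, 10))
  expect_error(cell_sampling(1, bad, part), "outside")
  expect_warning(detect_events(cell_sampling(2, mk_cell_series(rep(0, 10)),
                                             part)),
                 "no milestone")
})
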