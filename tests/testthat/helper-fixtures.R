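# Shared fixtures (generated once per test run) and independent oracles.

kBT300 <- 0.0019872043 * 300   # kcal/mol at 300 K

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- make()
  .fixtures[[name]]
}

# Overdamped harmonic (OU) window: k = 2.5 kcal/mol/A^2, D = 0.02 A^2/ps,
# 40 ns at 0.5 ps output. Exact targets: var = kBT/k, tau = var/D.
fx_ou_series <- function() fixture("ou", function() {
  cfg <- sim_config(dt = 0.01, n_steps = 4e6, seed = 11, output_stride = 50,
                    domain = c(-10, 10))
  simulate_bd(potential_flat(), diffusion_constant(0.02),
              list(bias_harmonic(2.5, 0)), cfg, label = "ou")
})

# Umbrella-sampling fixture: 11 windows (k = 2.5, centres -10..10) over a
# 4 kcal/mol Gaussian barrier (sigma 3 A), D = 0.02, 40 ns per window at
# 0.5 ps output.
fx_pmf_potential <- function() potential_gaussian_barrier(4, 0, 3)

fx_pmf_windows <- function() fixture("pmf_windows", function() {
  pot <- fx_pmf_potential()
  lapply(seq(-10, 10, by = 2), function(c0) {
    cfg <- sim_config(dt = 0.01, n_steps = 4e6, seed = 1000L + c0,
                      output_stride = 50, initial_z = c0, domain = c(-14, 14))
    umbrella_window(c0, 2.5,
                    simulate_bd(pot, diffusion_constant(0.02),
                                list(bias_harmonic(2.5, c0)), cfg))
  })
})

# Milestoning fixture: 12 Voronoi cells of 2 A on [-12, 12] over the same
# 4 kcal/mol barrier, D = 0.01, soft walls k = 100, 600 ns per cell at
# 0.1 ps output (so integer subsampling reaches 0.2, 0.5 and 5 ps strides).
fx_milestoning <- function() fixture("milestoning", function() {
  pot <- fx_pmf_potential()
  D <- diffusion_constant(0.01)
  edges <- seq(-12, 12, by = 2)
  part <- cell_partition(edges)
  samps <- lapply(seq_len(part$n_cells), function(i) {
    lo <- edges[i]; hi <- edges[i + 1]
    cfg <- sim_config(dt = 0.02, n_steps = 3e7, seed = 500L + i,
                      output_stride = 5, initial_z = (lo + hi) / 2,
                      domain = c(-14, 14))
    cell_sampling(i, simulate_bd(pot, D, list(bias_flat_bottom(100, lo, hi)),
                                 cfg), part)
  })
  list(samps = samps, part = part, pot = pot, D = D, edges = edges)
})

# The same fixture analyzed at 0.2 ps stride, with 4-block models attached.
fx_milestoning_model <- function() fixture("milestoning_model", function() {
  fx <- fx_milestoning()
  s02 <- lapply(fx$samps, function(s)
    cell_sampling(s$cell_index, subsample(s$series, 2L), fx$part))
  milestoning_model(s02, fx$part, n_blocks = 4L)
})

# Smoluchowski oracle for the milestoning fixture: reflecting at the outer
# edge of the bulk buffer cell (-12), absorbing at the last milestone (+10).
fx_milestoning_oracle_mfpt <- function() {
  fx <- fx_milestoning()
  zg <- seq(-12, 10, by = 0.05)
  pmf <- pmf_profile(zg, potential_eval(fx$pot, zg), bulk_region = c(-12, -11))
  smoluchowski_mfpt(pmf, fx$D, channel_bounds(-12, 10))
}

# Field fixture: flat channel of periodic length 24 A, D = 0.02, one +1 ion,
# +/-0.4 V across the box, 100 ns.
fx_field_run <- function(voltage, seed) {
  cfg <- sim_config(dt = 0.05, n_steps = 2e6, seed = seed, output_stride = 4,
                    initial_z = 0, domain = c(-12, 12))
  simulate_field(potential_flat(), diffusion_constant(0.02), charge = 1,
                 field = voltage / 24, cfg)[[1]]
}

fx_field <- function() fixture("field", function() {
  list(pos = fx_field_run(0.4, 21), neg = fx_field_run(-0.4, 22))
})

# ---- independent oracles ----------------------------------------------------

# Brute-force re-scan of a cell trajectory with an explicit state machine,
# independent of detect_events' vectorized implementation.
oracle_scan_cell <- function(z, stride, e_l, e_r, ml, mr) {
  region <- function(zz) {
    if (!is.na(ml) && zz <= e_l) return(ml)
    if (!is.na(mr) && zz >= e_r) return(mr)
    0L
  }
  ids <- sort(c(ml, mr)[!is.na(c(ml, mr))])
  cnt <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  res <- setNames(rep(0, length(ids)), ids)
  last_hit <- NA_integer_; last_hit_t <- NA_real_; first_hit_t <- NA_real_
  prev_r <- region(z[1])
  for (t in 2:length(z)) {
    r <- region(z[t])
    tt <- (t - 1) * stride
    if (r != 0L && r != prev_r) {       # crossing onto/past an edge
      if (!is.na(last_hit)) {
        res[as.character(last_hit)] <- res[as.character(last_hit)] +
          (tt - last_hit_t)
        if (r != last_hit)
          cnt[as.character(last_hit), as.character(r)] <-
            cnt[as.character(last_hit), as.character(r)] + 1
      } else first_hit_t <- tt
      last_hit <- r; last_hit_t <- tt
    }
    prev_r <- r
  }
  t_end <- (length(z) - 1) * stride
  if (!is.na(last_hit))
    res[as.character(last_hit)] <- res[as.character(last_hit)] +
      (t_end - last_hit_t)
  list(counts = cnt, residence = res,
       T_assigned = if (is.na(first_hit_t)) 0 else t_end - first_hit_t)
}

# Closed-form MFPT (state 1 -> state N) of a birth-death CTMC with up-rates
# a[i] (i -> i+1) and down-rates b[i] (i+1 -> i), by the standard summation.
oracle_birth_death_mfpt <- function(a, b) {
  N <- length(a) + 1L
  total <- 0
  for (k in seq_len(N - 1L)) {
    for (j in seq_len(k)) {
      term <- 1 / a[j]
      if (j < k) for (m in (j + 1L):k) term <- term * (b[m - 1L] / a[m])
      total <- total + term
    }
  }
  total
}

# Build a milestoning model directly from a rate matrix (for oracle tests).
model_from_Q <- function(Q, z = seq_len(nrow(Q))) {
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  structure(list(Q = Q, pi = rep(1 / (nrow(Q) + 1), nrow(Q) + 1),
                 milestone_z = z, partition = NULL, stats = NULL),
            class = "milestoning_model")
}

# Minimal hand-built transition_stats for analytic examples.
fake_stats <- function(cell, M, escapes = c(left = 0, right = 0),
                       T_total = 1, T_assigned = T_total,
                       counts = NULL, residence = NULL) {
  ml <- if (cell > 1L) cell - 1L else NA_integer_
  mr <- if (cell < M) cell else NA_integer_
  ids <- sort(c(ml, mr)[!is.na(c(ml, mr))])
  if (is.null(counts))
    counts <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  if (is.null(residence)) residence <- setNames(rep(0, length(ids)), ids)
  structure(list(cell = as.integer(cell),
                 milestones = c(left = ml, right = mr),
                 T_total = T_total, T_assigned = T_assigned, stride = NA_real_,
                 escapes = escapes, counts = counts, residence = residence,
                 waiting = numeric(0), n_samples = NA_integer_),
            class = "transition_stats")
}
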