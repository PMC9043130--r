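#' Voronoi cell partition of the collective variable
#'
#' M cells are defined by M+1 strictly increasing edges. Milestones are the
#' M-1 interior edges shared by adjacent cells: milestone m sits at
#' `edges[m+1]`, between cells m and m+1. The outermost edges are domain
#' boundaries, not milestones.
#'
#' @param edges Strictly increasing numeric vector of cell edges (angstrom,
#'   or any scalar collective variable such as a radial distance).
#' @param labels Optional per-cell display labels (defaults to cell centres).
#' @return An object of class `cell_partition`.
#' @export
cell_partition <- function(edges, labels = NULL) {
  stopifnot(is.numeric(edges), length(edges) >= 3L)
  if (any(diff(edges) <= 0)) stop("edges must be strictly increasing")
  M <- length(edges) - 1L
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  structure(list(edges = edges, n_cells = M,
                 centers = centers,
                 labels = labels %||% format(centers),
                 milestone_z = edges[2:M]),
            class = "cell_partition")
}

#' @export
print.cell_partition <- function(x, ...) {
  cat(sprintf("<cell_partition> %d cells on [%g, %g], %d milestones\n",
              x$n_cells, x$edges[1], x$edges[length(x$edges)], x$n_cells - 1L))
  invisible(x)
}

#' Cell-confined trajectory
#'
#' A collective-variable series sampled under soft-wall (flat-bottom
#' harmonic) confinement to one Voronoi cell. Brief excursions past the cell
#' edges are expected (they are the milestone hits); a large outside
#' fraction indicates a mis-assigned trajectory.
#'
#' @param cell_index Cell number (1-based).
#' @param series A [cv_series()].
#' @param partition The [cell_partition()].
#' @param max_outside_fraction Error threshold on the fraction of samples
#'   outside the cell.
#' @return An object of class `cell_sampling`.
#' @export
cell_sampling <- function(cell_index, series, partition,
                          max_outside_fraction = 0.5) {
  stopifnot(inherits(series, "cv_series"), inherits(partition, "cell_partition"))
  i <- as.integer(cell_index)
  if (i < 1L || i > partition$n_cells) stop("cell_index out of range")
  lo <- partition$edges[i]; hi <- partition$edges[i + 1L]
  frac <- mean(series$values < lo | series$values > hi)
  if (frac > max_outside_fraction)
    stop(sprintf("cell %d: %.0f%% of samples outside [%g, %g]; wrong cell?",
                 i, 100 * frac, lo, hi))
  structure(list(cell_index = i, series = series, partition = partition),
            class = "cell_sampling")
}

#' Detect milestone hits and transitions in one cell trajectory
#'
#' Sample-based hit detection (no interpolation of exact crossing times): a
#' milestone hit is logged at a sample that lies at or beyond a cell edge
#' when the previous sample did not lie in that same edge region — i.e. on
#' crossing onto (or past) the edge. A trajectory that starts beyond an edge
#' logs no hit until it re-enters and crosses again, and all time before the
#' first hit is discarded as burn-in. Between hits, residence time accrues
#' to the last-hit milestone; a transition j -> k is logged whenever a
#' different milestone is hit. Attempted escapes toward each neighbouring
#' cell are counted as one per contiguous excursion beyond the
#' corresponding edge.
#'
#' @param s A [cell_sampling()].
#' @return An object of class `transition_stats` with fields:
#'   `cell`, `milestones` (named ids, NA where the cell has no milestone on
#'   that side), `T_assigned` (ps, post-burn-in), `T_total` (ps),
#'   `counts` (matrix of transition counts, milestone id by milestone id),
#'   `residence` (named ps per milestone), `escapes` (named counts toward
#'   left/right neighbours), `waiting` (ps between successive hits of
#'   different milestones), `first_hit_time`, `stride`.
#' @export
detect_events <- function(s) {
  stopifnot(inherits(s, "cell_sampling"))
  p <- s$partition
  i <- s$cell_index
  M <- p$n_cells
  z <- s$series$values
  stride <- s$series$stride
  n <- length(z)
  e_l <- p$edges[i]; e_r <- p$edges[i + 1L]
  ml <- if (i > 1L) i - 1L else NA_integer_      # milestone id at left edge
  mr <- if (i < M) i else NA_integer_            # milestone id at right edge
  mids <- c(left = ml, right = mr)
  lab <- integer(n)
  if (!is.na(ml)) lab[z <= e_l] <- ml
  if (!is.na(mr)) lab[z >= e_r] <- mr
  # escapes: one per contiguous excursion beyond an edge with a neighbour
  esc <- c(left = 0L, right = 0L)
  if (i > 1L) {
    r <- rle(z <= e_l); esc["left"] <- sum(r$values)
  }
  if (i < M) {
    r <- rle(z >= e_r); esc["right"] <- sum(r$values)
  }
  out <- list(cell = i, milestones = mids,
              T_total = (n - 1) * stride, stride = stride,
              escapes = esc, n_samples = n)
  # crossing rule: hit at sample t >= 2 entering an edge region it was not
  # already in; the first sample never hits (no predecessor crossing)
  hit_idx <- which(lab[-1L] != 0L & lab[-n] != lab[-1L]) + 1L
  mil_ids <- sort(stats::na.omit(unique(c(ml, mr))))
  cnt <- matrix(0, length(mil_ids), length(mil_ids),
                dimnames = list(mil_ids, mil_ids))
  if (!length(hit_idx)) {
    warning(sprintf("cell %d: no milestone ever hit; zero contribution", i))
    out <- c(out, list(T_assigned = 0, counts = cnt,
                       residence = setNames(rep(0, length(mil_ids)),
                                            rownames(cnt)),
                       waiting = numeric(0), first_hit_time = NA_real_))
    class(out) <- "transition_stats"
    return(out)
  }
  h <- lab[hit_idx]
  t_hit <- (hit_idx - 1L) * stride
  t_end <- (n - 1L) * stride
  # residence: interval to next hit (or to end) belongs to the current hit
  dt_seg <- c(diff(t_hit), t_end - t_hit[length(t_hit)])
  res <- tapply(dt_seg, factor(h, levels = mil_ids), sum, default = 0)
  chg <- which(diff(h) != 0L)
  if (length(chg)) {
    from <- as.character(h[chg]); to <- as.character(h[chg + 1L])
    for (k in seq_along(chg)) cnt[from[k], to[k]] <- cnt[from[k], to[k]] + 1
  }
  out <- c(out, list(T_assigned = t_end - t_hit[1L],
                     counts = cnt,
                     residence = setNames(as.numeric(res), mil_ids),
                     waiting = if (length(chg)) t_hit[chg + 1L] - t_hit[chg]
                               else numeric(0),
                     first_hit_time = t_hit[1L]))
  class(out) <- "transition_stats"
  out
}

#' Equilibrium cell probabilities from attempted-escape rates
#'
#' Solves the statistical-equilibrium balance over cells,
#' \deqn{\sum_{j\ne i}\pi_j k_{j\to i} = \sum_{j\ne i}\pi_i k_{i\to j},
#'       \qquad \sum_i \pi_i = 1,}
#' with \eqn{k_{i\to j}} the attempted-escape rate from cell i toward
#' neighbour j (escape count over total cell time), via the null space of
#' the escape-rate generator.
#'
#' @param stats_list List of [detect_events()] results, one per cell,
#'   covering cells 1..M.
#' @return Numeric vector pi of length M (non-negative, sums to 1).
#' @export
solve_equilibrium <- function(stats_list) {
  M <- length(stats_list)
  stopifnot(M >= 2L,
            all(vapply(stats_list, inherits, logical(1), "transition_stats")))
  cells <- vapply(stats_list, `[[`, integer(1), "cell")
  stats_list <- stats_list[order(cells)]
  if (!identical(vapply(stats_list, `[[`, integer(1), "cell"), seq_len(M)))
    stop("stats_list must cover cells 1..M exactly once")
  K <- matrix(0, M, M)
  for (st in stats_list) {
    i <- st$cell
    if (i > 1L) K[i, i - 1L] <- st$escapes[["left"]] / st$T_total
    if (i < M)  K[i, i + 1L] <- st$escapes[["right"]] / st$T_total
  }
  # irreducibility: every adjacent pair must communicate
  up <- K[cbind(1:(M - 1), 2:M)]; dn <- K[cbind(2:M, 1:(M - 1))]
  if (any(up == 0) || any(dn == 0)) {
    brk <- which(up == 0 | dn == 0)[1L]
    stop(sprintf("irreducibility error: cells 1..%d and %d..%d are disconnected (no escapes across their shared edge)",
                 brk, brk + 1L, M))
  }
  G <- K; diag(G) <- -rowSums(K)
  A <- t(G); A[M, ] <- 1
  pi_ <- solve(A, c(rep(0, M - 1L), 1))
  pi_[pi_ < 0 & pi_ > -1e-12] <- 0
  if (any(pi_ < 0)) stop("negative equilibrium probability; inconsistent escape rates")
  pi_ / sum(pi_)
}

#' Per-cell free energy from equilibrium probabilities
#'
#' \eqn{F_i = -k_BT \ln \pi_i}, offset so the mean over the reference (bulk)
#' cells is zero.
#'
#' @param pi_ Equilibrium cell probabilities (> 0).
#' @param reference_cells Indices of the bulk cells used for the zero.
#' @param temperature Temperature, K.
#' @return Numeric vector of free energies in kcal/mol.
#' @export
free_energy <- function(pi_, reference_cells = seq_along(pi_),
                        temperature = 300) {
  if (any(pi_ <= 0)) stop("infinite free energy: zero equilibrium probability")
  f <- -thermal_energy(temperature) * log(pi_)
  f - mean(f[reference_cells])
}

#' Build the milestone rate matrix
#'
#' Implements the Voronoi-milestoning rate estimator
#' \deqn{q_{ij,ik} = \frac{\pi_i\, n^i_{ij,ik}}
#'   {\pi_i\, r^i_{ij} + \pi_j\, r^j_{ij}}}
#' where \eqn{n^i_{ij,ik}} is the number of transitions from milestone
#' \eqn{S_{ij}} to \eqn{S_{ik}} observed in cell i per unit assigned time,
#' and \eqn{r^i_{ij}} is the fraction of cell-i time spent having last hit
#' \eqn{S_{ij}}; the denominator collects the residence weight on
#' \eqn{S_{ij}} from both adjacent cells.
#'
#' @param stats_list List of [detect_events()] results covering cells 1..M.
#' @param pi_ Equilibrium cell probabilities from [solve_equilibrium()].
#' @param partition The [cell_partition()].
#' @return An object of class `milestoning_model` with fields `Q` (rate
#'   matrix over milestones, 1/ps; rows sum to zero), `pi`, `milestone_z`,
#'   `partition`, `stats`.
#' @export
build_rate_matrix <- function(stats_list, pi_, partition) {
  stopifnot(inherits(partition, "cell_partition"))
  M <- partition$n_cells
  stopifnot(length(stats_list) == M, length(pi_) == M)
  cells <- vapply(stats_list, `[[`, integer(1), "cell")
  stats_list <- stats_list[order(cells)]
  nm <- M - 1L
  res_frac <- function(st, m) {
    # residence fraction of this cell on milestone m (0 when never hit)
    key <- as.character(m)
    if (st$T_assigned <= 0 || !key %in% names(st$residence)) return(0)
    st$residence[[key]] / st$T_assigned
  }
  n_rate <- function(st, a, b) {
    ka <- as.character(a); kb <- as.character(b)
    if (st$T_assigned <= 0 || !ka %in% rownames(st$counts) ||
        !kb %in% rownames(st$counts)) return(0)
    st$counts[ka, kb] / st$T_assigned
  }
  Q <- matrix(0, nm, nm)
  for (i in seq_len(M)) {
    st <- stats_list[[i]]
    a <- st$milestones[["left"]]; b <- st$milestones[["right"]]
    if (is.na(a) || is.na(b)) next      # end cells host one milestone only
    for (pr in list(c(a, b), c(b, a))) {
      from <- pr[1]; to <- pr[2]
      num <- pi_[i] * n_rate(st, from, to)
      j <- if (from == i - 1L) i - 1L else i + 1L   # other cell at 'from'
      den <- pi_[i] * res_frac(st, from) + pi_[j] * res_frac(stats_list[[j]], from)
      if (num > 0 && den == 0)
        stop(sprintf("inconsistent stats: transitions %d->%d observed but no residence on milestone %d",
                     from, to, from))
      if (den > 0) Q[from, to] <- Q[from, to] + num / den
    }
  }
  if (all(Q == 0)) warning("all transition counts are zero; rate matrix is zero")
  hit <- rowSums(Q) + colSums(Q) > 0
  if (!all(hit) && any(Q > 0))
    warning("milestone(s) never hit: ", paste(which(!hit), collapse = ", "))
  diag(Q) <- -rowSums(Q)
  m <- structure(list(Q = Q, pi = pi_, milestone_z = partition$milestone_z,
                      partition = partition, stats = stats_list),
                 class = "milestoning_model")
  validate_milestoning_model(m)
  m
}

validate_milestoning_model <- function(m) {
  stopifnot(abs(sum(m$pi) - 1) < 1e-9, all(m$pi >= 0))
  offd <- m$Q; diag(offd) <- 0
  stopifnot(all(offd >= 0), all(abs(rowSums(m$Q)) < 1e-9))
  invisible(m)
}

#' @export
print.milestoning_model <- function(x, ...) {
  cat(sprintf("<milestoning_model> %d cells, %d milestones; max |Q| = %.4g /ps\n",
              x$partition$n_cells, nrow(x$Q), max(abs(x$Q))))
  invisible(x)
}

#' MFPT profile over milestones
#'
#' For each target milestone, solves the linear system
#' \eqn{Q_{\mathrm{sub}}\, t = -1} (rate matrix restricted to non-absorbing
#' milestones) and reports the committed time at the source milestone.
#' `direction = "outward"` starts from the first milestone and targets each
#' later one; `"inward"` reverses the milestone indices, starting from the
#' last. On a symmetric system the two profiles are mirror images — the
#' convergence check used in practice.
#'
#' @param model A `milestoning_model`.
#' @param direction `"outward"` or `"inward"`.
#' @return A data.frame with columns `milestone`, `z`, `mfpt` (ps). The
#'   source milestone has mfpt 0.
#' @export
mfpt_profile <- function(model, direction = c("outward", "inward")) {
  direction <- match.arg(direction)
  stopifnot(inherits(model, "milestoning_model"))
  K <- nrow(model$Q)
  ord <- if (direction == "outward") seq_len(K) else rev(seq_len(K))
  Q <- model$Q[ord, ord, drop = FALSE]
  if (K < 2L) stop("need at least 2 milestones for an MFPT profile")
  mf <- numeric(K)
  for (tgt in 2:K) {
    # the milestone chain is ordered along the collective variable, so a
    # walker from milestone 1 cannot pass the target: restrict the absorbing
    # solve to the milestones before it
    keep <- seq_len(tgt - 1L)
    Qs <- Q[keep, keep, drop = FALSE]
    t_ <- tryCatch(solve(Qs, rep(-1, length(keep))),
                   error = function(e)
                     stop(sprintf("absorbing milestone %d unreachable: %s",
                                  ord[tgt], conditionMessage(e))))
    mf[tgt] <- t_[1L]
  }
  data.frame(milestone = ord, z = model$milestone_z[ord], mfpt = mf)
}

#' End-to-end milestoning pipeline for one direction
#' @param model A `milestoning_model`.
#' @param direction `"outward"` or `"inward"`.
#' @return MFPT (ps) from the first to the last milestone (or reverse).
#' @export
mfpt_end_to_end <- function(model, direction = "outward") {
  pr <- mfpt_profile(model, direction)
  pr$mfpt[nrow(pr)]
}

#' Fit a milestoning model from cell trajectories
#'
#' Runs [detect_events()] on every cell, solves the equilibrium balance and
#' builds the milestone rate matrix. With `n_blocks > 1`, additionally fits
#' one model per contiguous trajectory block and attaches them for
#' uncertainty estimation (`$block_models`).
#'
#' @param samplings List of [cell_sampling()] objects covering cells 1..M.
#' @param partition The [cell_partition()].
#' @param n_blocks Optional number of blocks for block-resampled models.
#' @return A `milestoning_model`.
#' @export
milestoning_model <- function(samplings, partition, n_blocks = 1L) {
  stopifnot(all(vapply(samplings, inherits, logical(1), "cell_sampling")))
  stats_list <- lapply(samplings, detect_events)
  pi_ <- solve_equilibrium(stats_list)
  model <- build_rate_matrix(stats_list, pi_, partition)
  if (n_blocks > 1L) {
    model$block_models <- lapply(seq_len(n_blocks), function(b) {
      sb <- lapply(samplings, function(s) {
        blocks <- split_blocks(s$series, n_blocks)
        cell_sampling(s$cell_index, blocks[[b]], partition)
      })
      stb <- lapply(sb, detect_events)
      build_rate_matrix(stb, solve_equilibrium(stb), partition)
    })
  }
  model
}

#' Standard error of the end-to-end MFPT from block models
#' @param model A `milestoning_model` fitted with `n_blocks > 1`.
#' @param direction `"outward"` or `"inward"`.
#' @return Standard error of the mean MFPT, ps.
#' @export
mfpt_block_se <- function(model, direction = "outward") {
  if (is.null(model$block_models))
    stop("model was not fitted with n_blocks > 1")
  v <- vapply(model$block_models, mfpt_end_to_end, numeric(1), direction)
  sd(v) / sqrt(length(v))
}

#' Waiting-time, decorrelation and convergence diagnostics
#'
#' Per cell: the maximum and minimum waiting time between successive hits of
#' different milestones, the positional decorrelation time of the confined
#' series, and running estimates of the transition rates and residence
#' fractions versus sampling time (convergence traces). Milestoning MFPTs
#' are trustworthy when decorrelation times stay below the minimum waiting
#' times and the traces are flat.
#'
#' @param samplings List of [cell_sampling()] objects.
#' @param n_checkpoints Number of prefix checkpoints for the traces.
#' @return A list with `waiting` (data.frame: cell, min_waiting, max_waiting,
#'   decorrelation_time) and `convergence` (data.frame: cell, time, from, to,
#'   n_rate, r_from).
#' @export
milestoning_diagnostics <- function(samplings, n_checkpoints = 10L) {
  waiting <- do.call(rbind, lapply(samplings, function(s) {
    st <- detect_events(s)
    data.frame(cell = st$cell,
               min_waiting = if (length(st$waiting)) min(st$waiting) else NA_real_,
               max_waiting = if (length(st$waiting)) max(st$waiting) else NA_real_,
               decorrelation_time = correlation_time(s$series))
  }))
  convergence <- do.call(rbind, lapply(samplings, function(s) {
    n <- length(s$series)
    rows <- list()
    for (frac in seq_len(n_checkpoints) / n_checkpoints) {
      m <- max(2L, floor(n * frac))
      sub <- cv_series(s$series$times[1:m], s$series$values[1:m],
                       label = s$series$label)
      st <- suppressWarnings(detect_events(
        cell_sampling(s$cell_index, sub, s$partition)))
      if (st$T_assigned <= 0) next
      ids <- rownames(st$counts)
      for (a in ids) for (b in ids) {
        if (a == b) next
        rows[[length(rows) + 1L]] <- data.frame(
          cell = st$cell, time = sub$times[m], from = as.integer(a),
          to = as.integer(b),
          n_rate = st$counts[a, b] / st$T_assigned,
          r_from = st$residence[[a]] / st$T_assigned)
      }
    }
    if (length(rows)) do.call(rbind, rows) else NULL
  }))
  list(waiting = waiting, convergence = convergence)
}

#' MFPT sensitivity to the collective-variable output stride
#'
#' Reruns the full milestoning pipeline on subsampled cell trajectories for
#' each integer factor and reports the end-to-end MFPT and total transition
#' counts. Coarse strides miss milestone recrossings, deflate transition
#' counts and inflate the MFPT.
#'
#' @param samplings List of [cell_sampling()] objects covering all cells.
#' @param partition The [cell_partition()].
#' @param factors Integer subsampling factors (>= 1).
#' @param direction `"outward"` or `"inward"`.
#' @return A data.frame with columns `factor`, `stride` (ps), `mfpt` (ps),
#'   `total_transitions`.
#' @export
stride_sensitivity <- function(samplings, partition, factors = c(1L, 2L, 10L),
                               direction = "outward") {
  stopifnot(all(factors >= 1))
  do.call(rbind, lapply(factors, function(f) {
    sub <- lapply(samplings, function(s)
      cell_sampling(s$cell_index, subsample(s$series, f), partition))
    stats_list <- lapply(sub, detect_events)
    pi_ <- solve_equilibrium(stats_list)
    model <- build_rate_matrix(stats_list, pi_, partition)
    data.frame(factor = f,
               stride = samplings[[1]]$series$stride * f,
               mfpt = mfpt_end_to_end(model, direction),
               total_transitions = sum(vapply(stats_list,
                 function(st) sum(st$counts), numeric(1))))
  }))
}
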