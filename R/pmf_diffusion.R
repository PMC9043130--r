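#' Umbrella-sampling window
#'
#' One harmonically biased window: restraint centre, force constant and the
#' sampled collective-variable series. `k = 0` describes an unbiased window.
#'
#' @param center Restraint centre, angstrom.
#' @param k Force constant, kcal/mol/A^2 (>= 0).
#' @param series A [cv_series()].
#' @return An object of class `umbrella_window`.
#' @export
umbrella_window <- function(center, k, series) {
  stopifnot(is.finite(center), is.finite(k), k >= 0, inherits(series, "cv_series"))
  structure(list(center = center, k = k, series = series),
            class = "umbrella_window")
}

#' Estimate a PMF from biased windows by self-consistent reweighting
#'
#' Binned WHAM: iterates the self-consistent free-energy equations
#' \deqn{P(b) \propto \sum_i n_i(b) \Big/ \sum_i N_i e^{\beta(f_i - U_i(b))},
#'       \qquad f_i = -k_BT \ln \sum_b P(b) e^{-\beta U_i(b)}}
#' until the largest change in any window offset \eqn{f_i} drops below `tol`.
#' The PMF is \eqn{w(b) = -k_BT \ln P(b)}, offset so its mean over
#' `bulk_region` is zero.
#'
#' @param windows List of [umbrella_window()] objects with overlapping
#'   sampled ranges.
#' @param bin_width Bin width in angstrom (default 0.2).
#' @param tol Convergence tolerance on window offsets, kcal/mol.
#' @param max_iter Maximum self-consistency iterations.
#' @param bulk_region `c(lo, hi)` interval (or list of intervals) over which
#'   the PMF is offset to zero; defaults to the outermost 10% of the sampled
#'   range on each side.
#' @param temperature Temperature, K.
#' @param block_error If `TRUE`, a two-block error estimate is attached:
#'   each window is split in half, the PMF re-estimated per half, and
#'   `w_err = |w1 - w2| / 2`.
#' @return An object of class `pmf_profile` with fields `z` (bin centres),
#'   `w`, `w_err` (or NULL), `bulk_region`, `iterations`, `temperature`.
#' @export
estimate_pmf <- function(windows, bin_width = 0.2, tol = 1e-7,
                         max_iter = 10000L, bulk_region = NULL,
                         temperature = 300, block_error = FALSE) {
  stopifnot(length(windows) >= 1L,
            all(vapply(windows, inherits, logical(1), "umbrella_window")))
  rng <- vapply(windows, function(w) range(w$series$values), numeric(2))
  if (length(windows) >= 2L) {
    ord <- order(vapply(windows, `[[`, numeric(1), "center"))
    for (i in seq_len(length(windows) - 1L)) {
      a <- rng[, ord[i]]; b <- rng[, ord[i + 1L]]
      if (a[2] < b[1] || b[2] < a[1])
        stop(sprintf("coverage error: windows at centers %g and %g do not overlap (gap %g to %g A)",
                     windows[[ord[i]]]$center, windows[[ord[i + 1L]]]$center,
                     min(a[2], b[2]), max(a[1], b[1])))
    }
  }
  zmin <- min(rng[1, ]); zmax <- max(rng[2, ])
  edges <- seq(floor(zmin / bin_width) * bin_width,
               ceiling(zmax / bin_width) * bin_width, by = bin_width)
  zc <- edges[-length(edges)] + bin_width / 2
  beta <- inv_thermal_energy(temperature)
  kBT <- thermal_energy(temperature)

  nwin <- length(windows)
  counts <- vapply(windows, function(w) {
    idx <- findInterval(w$series$values, edges, rightmost.closed = TRUE)
    tabulate(idx, nbins = length(zc))
  }, numeric(length(zc)))                       # bins x windows
  Ntot <- colSums(counts)
  nz <- rowSums(counts) > 0
  # bias energy at bin centers, bins x windows
  U <- vapply(windows, function(w) 0.5 * w$k * (zc - w$center)^2,
              numeric(length(zc)))
  expU <- exp(-beta * U)
  f <- numeric(nwin)
  nb_tot <- rowSums(counts)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    denom <- expU %*% (Ntot * exp(beta * f))    # bins x 1
    Pb <- ifelse(nz, nb_tot / pmax(denom, .Machine$double.xmin), 0)
    fz <- -kBT * log(colSums(Pb * expU))
    fz <- fz - fz[1L]
    delta <- max(abs(fz - f))
    f <- fz
    if (delta < tol) break
    if (iter >= max_iter)
      stop(sprintf("convergence error: WHAM residual %.3g kcal/mol after %d iterations",
                   delta, iter))
  }
  keep <- nz
  # interior gaps (empty bins between sampled bins) indicate missing coverage
  kidx <- which(keep)
  if (any(diff(kidx) > 1L)) {
    g <- which(diff(kidx) > 1L)[1L]
    stop(sprintf("coverage error: no samples in bins between z = %.2f and %.2f A",
                 zc[kidx[g]], zc[kidx[g + 1L]]))
  }
  z <- zc[keep]
  w <- -kBT * log(Pb[keep])
  if (is.null(bulk_region)) {
    span <- diff(range(z))
    bulk_region <- list(c(z[1], z[1] + 0.1 * span),
                        c(z[length(z)] - 0.1 * span, z[length(z)]))
  }
  if (!is.list(bulk_region)) bulk_region <- list(bulk_region)
  inbulk <- Reduce(`|`, lapply(bulk_region, function(r) z >= r[1] & z <= r[2]))
  if (!any(inbulk)) stop("bulk_region contains no PMF bins")
  w <- w - mean(w[inbulk])

  w_err <- NULL
  if (block_error) {
    halves <- lapply(1:2, function(b) {
      wb <- lapply(windows, function(win) {
        blocks <- split_blocks(win$series, 2L)
        umbrella_window(win$center, win$k, blocks[[b]])
      })
      estimate_pmf(wb, bin_width = bin_width, tol = tol, max_iter = max_iter,
                   bulk_region = bulk_region, temperature = temperature,
                   block_error = FALSE)
    })
    w1 <- approx(halves[[1]]$z, halves[[1]]$w, xout = z, rule = 2)$y
    w2 <- approx(halves[[2]]$z, halves[[2]]$w, xout = z, rule = 2)$y
    w_err <- abs(w1 - w2) / 2
  }
  structure(list(z = z, w = w, w_err = w_err, bulk_region = bulk_region,
                 iterations = iter, temperature = temperature,
                 bin_width = bin_width),
            class = "pmf_profile")
}

#' Construct a PMF profile from tabulated values
#'
#' For analytic fixtures and externally computed profiles. The profile is
#' offset so its mean over `bulk_region` is zero.
#'
#' @param z Uniform, increasing grid (angstrom).
#' @param w PMF values (kcal/mol).
#' @param bulk_region Interval (or list of intervals) defining the bulk.
#' @param temperature Temperature, K.
#' @return A `pmf_profile`.
#' @export
pmf_profile <- function(z, w, bulk_region = NULL, temperature = 300) {
  stopifnot(length(z) == length(w), length(z) >= 2L)
  dz <- diff(z)
  if (any(dz <= 0) || any(abs(dz - dz[1]) > 1e-8))
    stop("z grid must be uniform and increasing")
  if (is.null(bulk_region)) {
    span <- diff(range(z))
    bulk_region <- list(c(z[1], z[1] + 0.1 * span),
                        c(z[length(z)] - 0.1 * span, z[length(z)]))
  }
  if (!is.list(bulk_region)) bulk_region <- list(bulk_region)
  inbulk <- Reduce(`|`, lapply(bulk_region, function(r) z >= r[1] & z <= r[2]))
  if (!any(inbulk)) stop("bulk_region contains no grid points")
  structure(list(z = z, w = w - mean(w[inbulk]), w_err = NULL,
                 bulk_region = bulk_region, iterations = 0L,
                 temperature = temperature, bin_width = dz[1]),
            class = "pmf_profile")
}

#' @export
print.pmf_profile <- function(x, ...) {
  cat(sprintf("<pmf_profile> %d bins, z = [%.2f, %.2f] A, barrier %.3f kcal/mol (%d iterations)\n",
              length(x$z), x$z[1], x$z[length(x$z)], max(x$w), x$iterations))
  invisible(x)
}

#' Integrated autocorrelation (position decorrelation) time
#'
#' \eqn{\tau = \int_0^\infty \langle\delta z(t)\delta z(0)\rangle /
#' \langle\delta z^2\rangle \, dt}, computed by summing the normalized
#' autocovariance over lags (trapezoid in lag time), truncated at the first
#' lag where it falls below 0.01 or crosses zero, whichever comes first.
#' Lags are scanned up to 10% of the series length.
#'
#' @param series A [cv_series()].
#' @param cutoff Truncation level on the normalized autocovariance.
#' @return tau in ps.
#' @export
correlation_time <- function(series, cutoff = 0.01) {
  stopifnot(inherits(series, "cv_series"))
  x <- series$values
  if (var(x) == 0) stop("degenerate input: zero-variance series")
  n <- length(x)
  Kmax <- max(1L, floor(0.1 * n))
  # autocovariance over all lags at once via FFT (same lag sums as direct
  # summation, with the standard 1/n normalization, at O(n log n))
  xc <- x - mean(x)
  m2 <- 2^ceiling(log2(2 * n))
  ft <- stats::fft(c(xc, rep(0, m2 - n)))
  ac <- Re(stats::fft(Mod(ft)^2, inverse = TRUE))[seq_len(Kmax + 1L)] / m2 / n
  rho <- ac[-1L] / ac[1L]               # lags 1..Kmax
  stop_at <- which(rho < cutoff)        # covers both < 0.01 and zero-crossing
  m <- if (length(stop_at)) stop_at[1L] - 1L else Kmax
  tau <- series$stride * (0.5 + if (m >= 1L) sum(rho[seq_len(m)]) else 0)
  if (n * series$stride < 100 * tau)
    warning(sprintf("series length (%.0f ps) is under 100 decorrelation times (tau = %.2f ps); tau may be unreliable",
                    n * series$stride, tau))
  tau
}

#' Position-dependent diffusion profile from restrained windows
#'
#' Per window i, \eqn{D(z_i) = \langle\delta z^2\rangle_i / \tau_i}: the
#' sampled variance divided by the integrated autocorrelation time
#' ([correlation_time()]). For an overdamped harmonic (Ornstein-Uhlenbeck)
#' window this is exact and independent of the restraint force constant.
#'
#' @param windows List of [umbrella_window()] objects.
#' @param symmetrize Average D(z) with D(-z) (window centres must come in
#'   +/- pairs within `bin_width` tolerance for the averaged pairs).
#' @param bin_width Matching tolerance used by `symmetrize`, angstrom.
#' @return An object of class `diffusion_profile` with fields `z`, `D`
#'   (\eqn{\mathrm{\AA^2/ps}}), `tau` (ps), `variance` (A^2), `symmetrized`.
#' @export
estimate_diffusion <- function(windows, symmetrize = FALSE, bin_width = 0.5) {
  stopifnot(length(windows) >= 1L,
            all(vapply(windows, inherits, logical(1), "umbrella_window")))
  ord <- order(vapply(windows, `[[`, numeric(1), "center"))
  windows <- windows[ord]
  z <- vapply(windows, `[[`, numeric(1), "center")
  v <- vapply(windows, function(w) var(w$series$values), numeric(1))
  tau <- vapply(windows, function(w) correlation_time(w$series), numeric(1))
  D <- v / tau
  if (symmetrize) {
    Ds <- D
    for (i in seq_along(z)) {
      j <- which(abs(z + z[i]) <= bin_width)
      if (length(j)) Ds[i] <- mean(c(D[i], D[j]))
    }
    D <- Ds
  }
  structure(list(z = z, D = D, tau = tau, variance = v,
                 symmetrized = isTRUE(symmetrize)),
            class = "diffusion_profile")
}

#' Construct a diffusion profile from tabulated values
#' @param z Positions, angstrom.
#' @param D Diffusion coefficients, A^2/ps (> 0).
#' @return A `diffusion_profile`.
#' @export
diffusion_profile <- function(z, D) {
  stopifnot(length(z) == length(D), all(D > 0))
  ord <- order(z)
  structure(list(z = z[ord], D = D[ord], tau = rep(NA_real_, length(z)),
                 variance = rep(NA_real_, length(z)), symmetrized = FALSE),
            class = "diffusion_profile")
}

#' @export
print.diffusion_profile <- function(x, ...) {
  cat(sprintf("<diffusion_profile> %d points, z = [%.2f, %.2f] A, D in [%.4g, %.4g] A^2/ps%s\n",
              length(x$z), min(x$z), max(x$z), min(x$D), max(x$D),
              if (x$symmetrized) " (symmetrized)" else ""))
  invisible(x)
}

#' Write a profile (PMF or diffusion) as TSV
#'
#' Columns `z`, `value` (and `error` when available), with `#` metadata lines.
#' @param profile A `pmf_profile` or `diffusion_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  if (inherits(profile, "pmf_profile")) {
    hdr <- c("# pmf_profile (z A, w kcal/mol)",
             sprintf("# temperature %g K", profile$temperature))
    df <- data.frame(z = profile$z, value = profile$w)
    if (!is.null(profile$w_err)) df$error <- profile$w_err
  } else if (inherits(profile, "diffusion_profile")) {
    hdr <- "# diffusion_profile (z A, D A^2/ps)"
    df <- data.frame(z = profile$z, value = profile$D)
  } else stop("unsupported profile class")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.table(format(df, digits = 10, trim = TRUE), con, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
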