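#' Crossing-region definition
#'
#' Splits the coordinate axis into lower (`z < z_lower`), inner (the open
#' interval) and upper (`z > z_upper`) regions for permeation-event counting.
#' Samples landing exactly on a boundary are assigned to the inner region.
#' `pore_length` is the length L used to normalise charge-displacement
#' currents.
#'
#' @param z_lower,z_upper Region boundaries, angstrom (`z_lower < z_upper`).
#' @param pore_length Pore length L for displacement accounting, angstrom
#'   (> 0); defaults to `z_upper - z_lower`.
#' @return An object of class `crossing_regions`.
#' @export
crossing_regions <- function(z_lower, z_upper, pore_length = z_upper - z_lower) {
  stopifnot(is.finite(z_lower), is.finite(z_upper))
  if (z_lower >= z_upper) stop("z_lower must be below z_upper")
  if (pore_length <= 0) stop("pore_length must be positive")
  structure(list(z_lower = z_lower, z_upper = z_upper,
                 pore_length = pore_length), class = "crossing_regions")
}

region_labels <- function(z, regions) {
  lab <- rep("I", length(z))
  lab[z < regions$z_lower] <- "L"
  lab[z > regions$z_upper] <- "U"
  lab
}

#' Count permeation events and the direct-counting current
#'
#' A finite-state machine over region labels per ion: a completed
#' lower -> inner -> upper sequence emits +1, upper -> inner -> lower emits
#' -1, and visits that return to the starting side emit 0. Wrap jumps in
#' periodic trajectories skip the inner region and are therefore never
#' counted. The current is \eqn{I = q \sum \mathrm{events} / \tau}.
#'
#' @param series_list List of per-ion [cv_series()] (each should carry
#'   `metadata$charge` in units of e; default +1).
#' @param regions A [crossing_regions()].
#' @return A list with `n_positive`, `n_negative`, `net` (charge-weighted net
#'   event count), `time_ps`, `current_pA`.
#' @export
count_crossings <- function(series_list, regions) {
  stopifnot(inherits(regions, "crossing_regions"))
  if (inherits(series_list, "cv_series")) series_list <- list(series_list)
  npos <- 0L; nneg <- 0L; net_q <- 0
  tmax <- 0
  for (s in series_list) {
    stopifnot(inherits(s, "cv_series"))
    q <- s$metadata$charge %||% 1
    runs <- rle(region_labels(s$values, regions))$values
    np <- 0L; nn <- 0L
    if (length(runs) >= 3L) {
      a <- runs[seq_len(length(runs) - 2L)]
      b <- runs[seq_len(length(runs) - 2L) + 1L]
      cc <- runs[seq_len(length(runs) - 2L) + 2L]
      np <- sum(a == "L" & b == "I" & cc == "U")
      nn <- sum(a == "U" & b == "I" & cc == "L")
    }
    npos <- npos + np; nneg <- nneg + nn
    net_q <- net_q + q * (np - nn)
    tmax <- max(tmax, s$times[length(s$times)] - s$times[1L])
  }
  # 1 e/ps = 1.602177e5 pA
  e_per_ps_pA <- phys_constants$elementary_charge_C / 1e-12 * 1e12
  list(n_positive = npos, n_negative = nneg, net = net_q, time_ps = tmax,
       current_pA = if (tmax > 0) net_q * e_per_ps_pA / tmax else 0)
}

#' Charge-displacement current
#'
#' \deqn{I = \sum_i q_i \sum_t \frac{z_i(t+\Delta t) - z_i(t)}{\Delta t\, L}}
#' with displacements clipped to the pore interval
#' `[z_lower, z_upper]` and wrap events (from `metadata$wraps`) unfolded so
#' that a periodic re-entry contributes its true path through the pore, not
#' the wrap jump. Does not require completed permeation events.
#'
#' @inheritParams count_crossings
#' @return Current in pA (averaged over the run).
#' @export
displacement_current <- function(series_list, regions) {
  stopifnot(inherits(regions, "crossing_regions"))
  if (inherits(series_list, "cv_series")) series_list <- list(series_list)
  L <- regions$pore_length
  lo <- regions$z_lower; hi <- regions$z_upper
  clip <- function(z) pmin(pmax(z, lo), hi)
  total <- 0   # e * A
  tspan <- 0
  for (s in series_list) {
    q <- s$metadata$charge %||% 1
    z <- s$values
    n <- length(z)
    w <- s$metadata$wraps %||% rep(0L, n)
    dom <- s$metadata$domain %||% range(z)
    dw <- diff(w)
    z1 <- z[-n]; z2 <- z[-1L]
    # steps without a wrap: straight clipped displacement; a wrap step goes
    # z1 -> top, then bottom -> z2 (or mirrored), each leg clipped
    d_plain <- clip(z2) - clip(z1)
    d_up <- (clip(dom[2]) - clip(z1)) + (clip(z2) - clip(dom[1]))
    d_dn <- (clip(dom[1]) - clip(z1)) + (clip(z2) - clip(dom[2]))
    d <- ifelse(dw == 0, d_plain, ifelse(dw > 0, d_up, d_dn))
    total <- total + q * sum(d)
    tspan <- max(tspan, s$times[n] - s$times[1L])
  }
  if (tspan <= 0) return(0)
  e_per_ps_pA <- phys_constants$elementary_charge_C / 1e-12 * 1e12
  total / (tspan * L) * e_per_ps_pA
}

#' Fit single-channel conductance from an I-V curve
#'
#' Ordinary least squares of current on voltage with an intercept; the slope
#' is the unitary conductance (pA/V = pS) and the intercept is reported as a
#' diagnostic (expected ~0 for a symmetric system).
#'
#' @param voltage Voltages, V (at least 2 distinct values).
#' @param current Currents, pA.
#' @return A list with `conductance_pS`, `conductance_se` (NA for an exact
#'   2-point fit), `intercept_pA`, `fit` (the `lm` object).
#' @export
conductance_fit <- function(voltage, current) {
  stopifnot(length(voltage) == length(current))
  if (length(unique(voltage)) < 2L)
    stop("rank error: need at least 2 distinct voltages")
  fit <- lm(current ~ voltage)
  sm <- summary(fit)$coefficients
  list(conductance_pS = unname(coef(fit)[2L]),
       conductance_se = if (nrow(sm) == 2L && length(voltage) > 2L)
         unname(sm[2L, 2L]) else NA_real_,
       intercept_pA = unname(coef(fit)[1L]),
       fit = fit)
}

#' Permeability from conductance via the GHK flux equation
#'
#' Under symmetric concentration and a constant field,
#' \deqn{P = \frac{\gamma\, k_B T}{q^2\, C}}
#' with \eqn{q = z\,e} the permeant charge and C the bulk concentration in
#' molecules/cm^3. Undefined for neutral species.
#'
#' @param conductance_pS Unitary conductance, pS (> 0).
#' @param concentration Symmetric bulk concentration, mol/L (> 0).
#' @param temperature Temperature, K.
#' @param z_charge Integer permeant charge in units of e (non-zero).
#' @param uncertainty_pS Optional conductance standard error, propagated
#'   linearly.
#' @return A [permeability_result()] with method `"GHK"`, P in cm^3/s.
#' @export
ghk_permeability <- function(conductance_pS, concentration, temperature = 300,
                             z_charge = 1L, uncertainty_pS = NULL) {
  if (z_charge == 0)
    stop("GHK flux form undefined for neutral species (zero charge)")
  stopifnot(conductance_pS > 0, concentration > 0, temperature > 0)
  kBT_J <- convert_energy(thermal_energy(temperature), "kcal/mol", "J")
  q_C <- abs(z_charge) * phys_constants$elementary_charge_C
  c_cm3 <- molar_to_per_cm3(concentration)
  scale <- kBT_J / (q_C^2 * c_cm3) * 1e-12        # per pS
  permeability_result(conductance_pS * scale, "GHK",
                      uncertainty = if (!is.null(uncertainty_pS))
                        uncertainty_pS * scale else NULL,
                      inputs = list(conductance_pS = conductance_pS,
                                    concentration_M = concentration,
                                    temperature = temperature,
                                    z_charge = z_charge))
}
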