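#' Channel pore bounds
#'
#' The interval `[z1, z2]` beyond which the PMF is at its bulk value; the
#' integration interval of the permeability and first-passage quadratures.
#'
#' @param z1,z2 Lower and upper pore boundaries, angstrom (`z1 < z2`).
#' @return An object of class `channel_bounds`.
#' @export
channel_bounds <- function(z1, z2) {
  stopifnot(is.finite(z1), is.finite(z2))
  if (z1 >= z2) stop("channel bounds require z1 < z2")
  structure(list(z1 = z1, z2 = z2), class = "channel_bounds")
}

#' Permeability result record
#'
#' @param P Permeability in cm^3/s (> 0).
#' @param method One of `"ISD"`, `"MFPT"`, `"GHK"`, `"rate"`.
#' @param uncertainty Optional uncertainty in cm^3/s.
#' @param inputs Free-form provenance list.
#' @return An object of class `permeability_result`.
#' @export
permeability_result <- function(P, method, uncertainty = NULL, inputs = list()) {
  if (!is.numeric(P) || length(P) != 1L || !is.finite(P) || P <= 0)
    stop("P must be a single positive number (cm^3/s)")
  structure(list(P = P, method = method, uncertainty = uncertainty,
                 inputs = inputs), class = "permeability_result")
}

#' @export
print.permeability_result <- function(x, ...) {
  unc <- if (!is.null(x$uncertainty)) sprintf(" +/- %.3g", x$uncertainty) else ""
  cat(sprintf("<permeability_result> P = %.4g%s cm^3/s [%s]\n", x$P, unc, x$method))
  invisible(x)
}

# common grid: pmf grid restricted to [z1,z2], D linearly interpolated onto it;
# exponentials shifted by the grid maximum to avoid overflow
isd_grids <- function(pmf, d, b, temperature) {
  stopifnot(inherits(pmf, "pmf_profile"), inherits(b, "channel_bounds"))
  if (b$z1 < min(pmf$z) - 1e-9 || b$z2 > max(pmf$z) + 1e-9)
    stop(sprintf("channel bounds [%g, %g] outside the PMF grid [%g, %g]",
                 b$z1, b$z2, min(pmf$z), max(pmf$z)))
  sel <- pmf$z >= b$z1 - 1e-9 & pmf$z <= b$z2 + 1e-9
  z <- pmf$z[sel]
  w <- pmf$w[sel]
  if (length(z) < 2L) stop("fewer than 2 PMF grid points inside the channel bounds")
  if (inherits(d, "diffusion_profile")) {
    D <- approx(d$z, d$D, xout = z, rule = 2)$y
  } else if (inherits(d, "diffusion_spec")) {
    D <- diffusion_eval(d, z)
  } else stop("d must be a diffusion_profile or diffusion_spec")
  if (any(D <= 0)) stop("D must be positive over the channel interval")
  beta <- inv_thermal_energy(temperature)
  list(z = z, w = w, D = D, beta = beta)
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
cum_trapz <- function(x, y) c(0, cumsum(diff(x) * (head(y, -1) + tail(y, -1)) / 2))

#' Permeability from the inhomogeneous solubility-diffusion equation
#'
#' \deqn{P = \pi r^2 \Big(\int_{z_1}^{z_2} \frac{e^{\beta w(z)}}{D(z)}\,dz\Big)^{-1}}
#' Trapezoidal quadrature on the PMF grid with D interpolated linearly onto
#' it; exponentials are computed with the grid maximum subtracted and
#' restored, so kcal/mol-scale barriers cannot overflow. The lateral
#' restraint radius `r` (which must exceed the pore radius) fixes the
#' effective bulk concentration and makes P concentration-independent.
#'
#' @param pmf A `pmf_profile`, offset to zero in the bulk.
#' @param d A `diffusion_profile` or `diffusion_spec` defined on `[z1, z2]`.
#' @param r Bulk lateral restraint radius, angstrom.
#' @param b A [channel_bounds()].
#' @param temperature Temperature, K.
#' @return A [permeability_result()] with method `"ISD"`, P in cm^3/s.
#' @export
isd_permeability <- function(pmf, d, r, b, temperature = 300) {
  stopifnot(is.finite(r), r > 0)
  g <- isd_grids(pmf, d, b, temperature)
  wmax <- max(g$w)
  I <- exp(g$beta * wmax) * trapz(g$z, exp(g$beta * (g$w - wmax)) / g$D)
  P_A3ps <- pi * r^2 / I
  permeability_result(P_A3ps * phys_constants$A3ps_to_cm3s, "ISD",
                      inputs = list(r = r, z1 = b$z1, z2 = b$z2,
                                    temperature = temperature))
}

#' Local and cumulative permeation resistance
#'
#' The integrand \eqn{e^{\beta w(z)}/D(z)} of the ISD equation (local
#' resistance) and its running integral scaled by \eqn{1/\pi r^2}, i.e. the
#' cumulative resistance 1/P(z). The final cumulative value equals 1/P from
#' [isd_permeability()].
#'
#' @inheritParams isd_permeability
#' @return A data.frame with columns `z`, `local_resistance` (ps/A^3 scale
#'   before the area factor), `cumulative_inv_P` (s/cm^3).
#' @export
resistance_profile <- function(pmf, d, r, b, temperature = 300) {
  g <- isd_grids(pmf, d, b, temperature)
  integrand <- exp(g$beta * g$w) / g$D
  cum <- cum_trapz(g$z, integrand) / (pi * r^2) / phys_constants$A3ps_to_cm3s
  data.frame(z = g$z, local_resistance = integrand, cumulative_inv_P = cum)
}

#' Mean first passage time by Smoluchowski quadrature
#'
#' \deqn{\langle t\rangle = \int_{z_1}^{z_2}\frac{e^{\beta w(z)}}{D(z)}
#'  \int_{z_1}^{z} e^{-\beta w(z')}\,dz'\,dz}
#' for diffusion from \eqn{z_1} (reflecting) to \eqn{z_2} (absorbing),
#' by nested trapezoidal quadrature. The inward MFPT is obtained by
#' mirroring the profile (reverse the grid) before calling.
#'
#' @inheritParams isd_permeability
#' @return MFPT in ps.
#' @export
smoluchowski_mfpt <- function(pmf, d, b, temperature = 300) {
  g <- isd_grids(pmf, d, b, temperature)
  # shift w by a reference before exponentiating; the shifts cancel in the
  # product e^{+beta w(z)} e^{-beta w(z')}
  a <- min(g$w)
  inner <- cum_trapz(g$z, exp(-g$beta * (g$w - a)))
  trapz(g$z, exp(g$beta * (g$w - a)) / g$D * inner)
}

#' Permeability from a mean first passage time
#'
#' \deqn{P = \frac{\pi r^2 \int_{z_1}^{z_2} e^{-\beta w(z)}\,dz}{2\,\langle t\rangle}}
#' The factor 2 reflects that at equilibrium half the first-passage flux
#' crosses in each direction; the relation is derived from the ISD and
#' Smoluchowski expressions and is quantitative for symmetric
#' single-barrier profiles.
#'
#' @inheritParams isd_permeability
#' @param mfpt Mean first passage time across `[z1, z2]`, ps (> 0).
#' @return A [permeability_result()] with method `"MFPT"`, P in cm^3/s.
#' @export
mfpt_permeability <- function(pmf, mfpt, r, b, temperature = 300) {
  if (!is.numeric(mfpt) || length(mfpt) != 1L || !is.finite(mfpt) || mfpt <= 0)
    stop("mfpt must be a single positive time in ps")
  stopifnot(is.finite(r), r > 0)
  g <- isd_grids(pmf, diffusion_profile(c(b$z1, b$z2), c(1, 1)), b, temperature)
  I <- trapz(g$z, exp(-g$beta * g$w))
  P_A3ps <- pi * r^2 * I / (2 * mfpt)
  permeability_result(P_A3ps * phys_constants$A3ps_to_cm3s, "MFPT",
                      inputs = list(r = r, mfpt_ps = mfpt, z1 = b$z1,
                                    z2 = b$z2, temperature = temperature))
}

#' Permeability from a crossing rate or MFPT at known concentration
#'
#' \eqn{P = k/c = 1/(c\,\langle t\rangle)} with the symmetric solute
#' concentration converted to molecules/cm^3.
#'
#' @param rate Crossing rate in 1/s, or `NULL` if `mfpt_s` given.
#' @param mfpt_s MFPT in seconds, or `NULL` if `rate` given.
#' @param concentration Symmetric bulk concentration, mol/L.
#' @return A [permeability_result()] with method `"rate"`.
#' @export
permeability_from_rate <- function(rate = NULL, mfpt_s = NULL, concentration) {
  if (is.null(rate) == is.null(mfpt_s))
    stop("supply exactly one of rate or mfpt_s")
  if (is.null(rate)) {
    if (mfpt_s <= 0) stop("mfpt_s must be positive")
    rate <- 1 / mfpt_s
  }
  if (rate <= 0 || concentration <= 0)
    stop("rate and concentration must be positive")
  c_cm3 <- molar_to_per_cm3(concentration)
  permeability_result(rate / c_cm3, "rate",
                      inputs = list(rate_per_s = rate,
                                    concentration_M = concentration))
}
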