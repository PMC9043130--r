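#' Physical constants (CODATA 2018)
#'
#' Fixed constant set used throughout the package. Internal working units are
#' angstrom (length), picosecond (time), kcal/mol (energy) and the elementary
#' charge; conversions to SI or eV happen only at API boundaries.
#'
#' @format A named list:
#' \describe{
#'   \item{avogadro}{Avogadro constant, 1/mol.}
#'   \item{kB_J_per_K}{Boltzmann constant, J/K.}
#'   \item{kB_kcalmol_per_K}{Boltzmann constant, kcal/mol/K.}
#'   \item{kB_eV_per_K}{Boltzmann constant, eV/K.}
#'   \item{elementary_charge_C}{Elementary charge, C.}
#'   \item{faraday_C_per_mol}{Faraday constant, C/mol.}
#'   \item{gas_constant_J_per_molK}{Molar gas constant, J/mol/K.}
#'   \item{kcal_J}{Joules per thermochemical kilocalorie.}
#'   \item{A3ps_to_cm3s}{Conversion factor, \eqn{\mathrm{\AA^3/ps}} to cm^3/s (exact 1e-12).}
#' }
#' @export
phys_constants <- local({
  NA_mol <- 6.02214076e23
  kB     <- 1.380649e-23
  e      <- 1.602176634e-19
  kcal   <- 4184
  list(
    avogadro              = NA_mol,
    kB_J_per_K            = kB,
    kB_kcalmol_per_K      = kB * NA_mol / kcal,   # 0.001987204259
    kB_eV_per_K           = kB / e,               # 8.617333262e-5
    elementary_charge_C   = e,
    faraday_C_per_mol     = e * NA_mol,           # 96485.33212
    gas_constant_J_per_molK = kB * NA_mol,        # 8.314462618
    kcal_J                = kcal,
    A3ps_to_cm3s          = 1e-12
  )
})

#' Table of physical constants
#'
#' Machine-readable constant table (name, value, unit). Use
#' `write.table(constants_table(), ..., sep = "\t")` to export as TSV.
#'
#' @return A data.frame with columns `name`, `value`, `unit`.
#' @export
constants_table <- function() {
  data.frame(
    name = c("avogadro", "kB_J_per_K", "kB_kcalmol_per_K", "kB_eV_per_K",
             "elementary_charge_C", "faraday_C_per_mol",
             "gas_constant_J_per_molK", "kcal_J", "A3ps_to_cm3s"),
    value = unlist(phys_constants, use.names = FALSE),
    unit = c("1/mol", "J/K", "kcal/mol/K", "eV/K", "C", "C/mol",
             "J/mol/K", "J/kcal", "(cm3/s)/(A3/ps)"),
    stringsAsFactors = FALSE
  )
}

#' Convert an energy between units
#'
#' Supported units: `"kcal/mol"`, `"eV"`, `"J"` (joule per particle),
#' `"J/mol"`. Round-trips reproduce the input to better than 1e-12 relative
#' error.
#'
#' @param x Numeric energy value(s).
#' @param from,to Unit names.
#' @return Numeric value(s) in unit `to`.
#' @export
convert_energy <- function(x, from, to) {
  pc <- phys_constants
  # value in J per particle for 1 unit of each
  fac <- c("kcal/mol" = pc$kcal_J / pc$avogadro,
           "eV"       = pc$elementary_charge_C,
           "J"        = 1,
           "J/mol"    = 1 / pc$avogadro)
  if (!from %in% names(fac)) stop("unknown energy unit: ", from)
  if (!to %in% names(fac))   stop("unknown energy unit: ", to)
  x * fac[[from]] / fac[[to]]
}

#' Thermal energy kB*T
#'
#' @param temperature Absolute temperature in K (> 0).
#' @param unit Energy unit, see [convert_energy()]. Default `"kcal/mol"`.
#' @return kB*T in the requested unit. At 300 K this is 0.5962 kcal/mol or
#'   0.0259 eV.
#' @export
thermal_energy <- function(temperature, unit = "kcal/mol") {
  if (!is.numeric(temperature) || length(temperature) != 1L || !is.finite(temperature) ||
      temperature <= 0)
    stop("temperature must be a single positive number (K)")
  convert_energy(phys_constants$kB_kcalmol_per_K * temperature, "kcal/mol", unit)
}

#' Inverse thermal energy beta = 1/kBT in (kcal/mol)^-1
#' @param temperature Temperature in K.
#' @return beta in mol/kcal.
#' @export
inv_thermal_energy <- function(temperature) 1 / thermal_energy(temperature, "kcal/mol")

#' Restrained-bulk geometry
#'
#' Describes the volume accessible to a single tagged particle restrained in
#' the bulk: a cylinder (lateral flat-bottom restraint of radius `radius` over
#' axial length `length`), a hemisphere of radius `radius`, or a hemispherical
#' shell between `inner_radius` and `outer_radius`. This volume sets the
#' effective bulk concentration of the tagged particle.
#'
#' @param kind One of `"cylinder"`, `"hemisphere"`, `"spherical_shell"`.
#' @param radius Radius in angstrom (cylinder, hemisphere).
#' @param length Cylinder length in angstrom.
#' @param inner_radius,outer_radius Shell radii in angstrom
#'   (`outer_radius > inner_radius`).
#' @return An object of class `bulk_geometry`.
#' @export
bulk_geometry <- function(kind = c("cylinder", "hemisphere", "spherical_shell"),
                          radius = NULL, length = NULL,
                          inner_radius = NULL, outer_radius = NULL) {
  kind <- match.arg(kind)
  chk <- function(x, nm) {
    if (is.null(x) || !is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
      stop("invalid geometry: ", nm, " must be a single positive number (angstrom)")
    x
  }
  g <- switch(kind,
    cylinder = list(kind = kind, radius = chk(radius, "radius"),
                    length = chk(length, "length")),
    hemisphere = list(kind = kind, radius = chk(radius, "radius")),
    spherical_shell = {
      ri <- chk(inner_radius, "inner_radius"); ro <- chk(outer_radius, "outer_radius")
      if (ro <= ri) stop("invalid geometry: outer_radius must exceed inner_radius")
      list(kind = kind, inner_radius = ri, outer_radius = ro)
    })
  structure(g, class = "bulk_geometry")
}

#' Volume of a bulk geometry
#'
#' @param g A [bulk_geometry()].
#' @return Volume in cubic angstrom: cylinder \eqn{\pi r^2 L}; hemisphere
#'   \eqn{(2/3)\pi r^3}; shell \eqn{(2/3)\pi(r_o^3 - r_i^3)}.
#' @export
geometry_volume <- function(g) {
  stopifnot(inherits(g, "bulk_geometry"))
  switch(g$kind,
    cylinder        = pi * g$radius^2 * g$length,
    hemisphere      = (2 / 3) * pi * g$radius^3,
    spherical_shell = (2 / 3) * pi * (g$outer_radius^3 - g$inner_radius^3))
}

#' Effective concentration of one particle in a restrained bulk volume
#'
#' One molecule confined to the geometry's volume, expressed in mol/L. Equals
#' `1660.539 / volume[A^3]`. A single ion in a cylinder of radius 6 A and
#' length 28 A gives 0.52 M.
#'
#' @param g A [bulk_geometry()].
#' @return Concentration in mol/L.
#' @export
single_particle_molarity <- function(g) {
  v_L <- geometry_volume(g) * 1e-27   # A^3 -> litre
  1 / (phys_constants$avogadro * v_L)
}

#' Convert molarity to number density
#' @param c_molar Concentration in mol/L.
#' @return Molecules per cm^3.
#' @export
molar_to_per_cm3 <- function(c_molar) c_molar * phys_constants$avogadro / 1000

#' @export
print.bulk_geometry <- function(x, ...) {
  dims <- switch(x$kind,
    cylinder = sprintf("r = %g A, L = %g A", x$radius, x$length),
    hemisphere = sprintf("r = %g A", x$radius),
    spherical_shell = sprintf("ri = %g A, ro = %g A", x$inner_radius, x$outer_radius))
  cat(sprintf("<bulk_geometry> %s (%s): V = %.2f A^3, c1 = %.3f M\n",
              x$kind, dims, geometry_volume(x), single_particle_molarity(x)))
  invisible(x)
}
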