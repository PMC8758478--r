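# Hydrodynamic relations in CGS units internally:
#   eta [poise], rho [g/cm^3], vbar [cm^3/g], s [seconds], M [g/mol].
# User-facing units: s in Svedberg (1 S = 1e-13 s), eta in mPa*s (= cP).

.kB <- 1.380649e-16   # erg/K
.NA <- 6.02214076e23  # 1/mol
.Rgas <- .kB * .NA    # erg/(mol K)

#' Solution conditions for hydrodynamic calculations
#'
#' Bundles the solvent properties needed to interconvert sedimentation
#' coefficient, molar mass and diffusion coefficient. Defaults are water at
#' 20 degrees C with the standard protein partial specific volume.
#'
#' @param temperature Absolute temperature in kelvin.
#' @param density Solvent density in g/mL.
#' @param viscosity Solvent viscosity in mPa*s (equal to centipoise).
#' @param partial_specific_volume Solute partial specific volume in mL/g.
#' @return An object of class `solution_conditions`.
#' @examples
#' solution_conditions()  # water at 20 C, vbar 0.73
#' @export
solution_conditions <- function(temperature = 293.15, density = 0.99823,
                                viscosity = 1.002,
                                partial_specific_volume = 0.73) {
  if (any(c(temperature, density, viscosity, partial_specific_volume) <= 0))
    stop("all solution condition fields must be positive")
  buoy <- 1 - partial_specific_volume * density
  if (buoy <= 0)
    stop("buoyancy factor (1 - vbar*rho) must be positive")
  structure(list(temperature = temperature, density = density,
                 viscosity = viscosity,
                 partial_specific_volume = partial_specific_volume),
            class = "solution_conditions")
}

.eta_cgs <- function(cond) cond$viscosity * 0.01  # mPa*s -> poise
.buoy <- function(cond) 1 - cond$partial_specific_volume * cond$density

# Stokes radius (cm) of the anhydrous sphere with mass M (g/mol)
.r0_sphere <- function(M, cond) {
  (3 * M * cond$partial_specific_volume / (4 * pi * .NA))^(1 / 3)
}

# friction coefficient f (g/s) for mass M and frictional ratio ff0
.friction <- function(M, ff0, cond) {
  ff0 * 6 * pi * .eta_cgs(cond) * .r0_sphere(M, cond)
}

#' Molar mass from sedimentation coefficient and frictional ratio
#'
#' Inverts the Svedberg relation `s = M (1 - vbar rho) / (N_A f)` with the
#' Stokes friction of a sphere scaled by the frictional ratio, yielding the
#' closed form `M = [s N_A (f/f0) 6 pi eta (3 vbar / 4 pi N_A)^(1/3) /
#' (1 - vbar rho)]^(3/2)`.
#'
#' @param s Sedimentation coefficient in Svedberg.
#' @param ff0 Frictional ratio f/f0 (>= 1).
#' @param cond A [solution_conditions()] object.
#' @return Molar mass in g/mol.
#' @examples
#' mass_from_hydro(3.9, 1.40) / 1000  # ~59 kDa, the sAPPalpha-695 peak
#' @export
mass_from_hydro <- function(s, ff0, cond = solution_conditions()) {
  if (any(s <= 0)) stop("sedimentation coefficient must be positive")
  if (any(ff0 < 1)) stop("frictional ratio must be >= 1")
  s_sec <- s * 1e-13
  base <- s_sec * .NA * ff0 * 6 * pi * .eta_cgs(cond) *
    (3 * cond$partial_specific_volume / (4 * pi * .NA))^(1 / 3) / .buoy(cond)
  base^(3 / 2)
}

#' Sedimentation coefficient from molar mass and frictional ratio
#'
#' Forward Svedberg relation; exact inverse of [mass_from_hydro()].
#'
#' @param M Molar mass in g/mol.
#' @param ff0 Frictional ratio f/f0.
#' @param cond A [solution_conditions()] object.
#' @return Sedimentation coefficient in Svedberg.
#' @export
s_from_mass <- function(M, ff0, cond = solution_conditions()) {
  if (any(M <= 0)) stop("molar mass must be positive")
  if (any(ff0 < 1)) stop("frictional ratio must be >= 1")
  s_sec <- M * .buoy(cond) / (.NA * .friction(M, ff0, cond))
  s_sec / 1e-13
}

#' Translational diffusion coefficient of a species
#'
#' Stokes-Einstein `D = kT / f` with `f` the Stokes friction of the
#' equivalent sphere scaled by the frictional ratio. Satisfies the Svedberg
#' identity `D = s R T / (M (1 - vbar rho))`.
#'
#' @param s Sedimentation coefficient in Svedberg (used to derive the mass
#'   when `M` is missing).
#' @param ff0 Frictional ratio.
#' @param cond A [solution_conditions()] object.
#' @param M Optional molar mass in g/mol; derived from `s` and `ff0` when
#'   missing. If both are given they must be Svedberg-consistent.
#' @return Diffusion coefficient in cm^2/s.
#' @export
diffusion_coefficient <- function(s, ff0, cond = solution_conditions(),
                                  M = NULL) {
  if (is.null(M)) {
    M <- mass_from_hydro(s, ff0, cond)
  } else {
    s_chk <- s_from_mass(M, ff0, cond)
    if (abs(s_chk - s) > 1e-6 * s)
      stop("species fields are inconsistent under the Svedberg relation")
  }
  .kB * cond$temperature / .friction(M, ff0, cond)
}

#' Hydrodynamic species description
#'
#' A sedimenting species characterised by `(s, f/f0)` at given solution
#' conditions; mass and diffusion coefficient are derived so that the triple
#' is Svedberg-consistent by construction.
#'
#' @param label Species name.
#' @param s Sedimentation coefficient in Svedberg.
#' @param frictional_ratio f/f0, >= 1.
#' @param loading_signal Initial uniform loading signal in absorbance units.
#' @param signal_weight Signal per molar concentration (AU/M); used when
#'   converting molar concentrations to signal.
#' @param cond A [solution_conditions()] object.
#' @return An object of class `hydro_species` with derived `molar_mass`
#'   (g/mol) and `diffusion_coeff` (cm^2/s).
#' @export
hydro_species <- function(label, s, frictional_ratio,
                          loading_signal = 1, signal_weight = 1,
                          cond = solution_conditions()) {
  if (s <= 0) stop("s must be positive")
  if (frictional_ratio < 1) stop("frictional ratio must be >= 1")
  M <- mass_from_hydro(s, frictional_ratio, cond)
  D <- diffusion_coefficient(s, frictional_ratio, cond, M = M)
  structure(list(label = label, s = s, frictional_ratio = frictional_ratio,
                 molar_mass = M, diffusion_coeff = D,
                 loading_signal = loading_signal,
                 signal_weight = signal_weight),
            class = "hydro_species")
}

#' Partial specific volume implied by a printed (s, f/f0, M) triple
#'
#' Solves for the vbar that makes the Svedberg/Stokes closed form reproduce a
#' stated molar mass exactly, holding the other solvent properties fixed.
#' Useful for diagnosing how much of a mass discrepancy is attributable to an
#' unreported partial specific volume (e.g. glycosylated proteins).
#'
#' @param s Sedimentation coefficient in Svedberg.
#' @param ff0 Frictional ratio.
#' @param M_target Stated molar mass in g/mol.
#' @param cond Solution conditions supplying temperature, density, viscosity.
#' @param interval Search interval for vbar in mL/g.
#' @return The implied vbar in mL/g.
#' @export
implied_vbar <- function(s, ff0, M_target, cond = solution_conditions(),
                         interval = c(0.5, 0.9)) {
  f <- function(v) {
    c2 <- solution_conditions(cond$temperature, cond$density, cond$viscosity, v)
    mass_from_hydro(s, ff0, c2) - M_target
  }
  stats::uniroot(f, interval, tol = 1e-12)$root
}
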