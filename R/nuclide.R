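#' Beta-emitting nuclide constants
#'
#' Bundle the physical decay and beta-spectrum constants of a nuclide used in
#' internal dosimetry: physical half-life, mean and maximum beta energy, and
#' the beta yield per decay.
#'
#' @param name Nuclide label, e.g. `"Ca-45"`.
#' @param half_life_days Physical half-life in days (> 0).
#' @param mean_energy_MeV Mean beta energy per emission, MeV.
#' @param max_energy_MeV Spectrum endpoint (maximum) energy, MeV; must exceed
#'   the mean energy.
#' @param yield Mean number of beta particles emitted per decay, in (0, 1].
#'
#' @return An object of class `beta_nuclide`.
#' @seealso [nuclide_ca45()], [nuclide_sr89()], [equilibrium_dose_constant()]
#' @export
#' @examples
#' beta_nuclide("Ca-45", 163, 0.077, 0.257)
beta_nuclide <- function(name, half_life_days, mean_energy_MeV,
                         max_energy_MeV, yield = 1) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.finite(half_life_days) || half_life_days <= 0)
    stop("invalid nuclide: half-life must be positive", call. = FALSE)
  if (!is.finite(mean_energy_MeV) || mean_energy_MeV <= 0 ||
      mean_energy_MeV >= max_energy_MeV)
    stop("invalid nuclide: need 0 < mean energy < max energy", call. = FALSE)
  if (!is.finite(yield) || yield <= 0 || yield > 1)
    stop("invalid nuclide: beta yield must be in (0, 1]", call. = FALSE)
  structure(
    list(name = name,
         half_life_days = half_life_days,
         mean_energy_MeV = mean_energy_MeV,
         max_energy_MeV = max_energy_MeV,
         yield = yield),
    class = "beta_nuclide")
}

#' @export
print.beta_nuclide <- function(x, ...) {
  cat(sprintf("<beta_nuclide> %s\n", x$name))
  cat(sprintf("  half-life: %.4g d (%.3g wk)\n",
              x$half_life_days, half_life_weeks(x)))
  cat(sprintf("  beta energy: mean %.4g MeV, max %.4g MeV, yield %.3g\n",
              x$mean_energy_MeV, x$max_energy_MeV, x$yield))
  invisible(x)
}

#' Preset: calcium-45
#'
#' Low-energy beta emitter that deposits in mineralized bone: physical
#' half-life 163 days, mean beta energy 0.077 MeV, endpoint 0.257 MeV, one
#' beta per decay.
#'
#' @return A [beta_nuclide()] object.
#' @export
nuclide_ca45 <- function() {
  beta_nuclide("Ca-45", half_life_days = 163,
               mean_energy_MeV = 0.077, max_energy_MeV = 0.257)
}

#' Preset: strontium-89
#'
#' Higher-energy bone-seeking beta emitter: half-life 50.5 days, mean beta
#' energy 0.583 MeV, endpoint 1.495 MeV.
#'
#' @return A [beta_nuclide()] object.
#' @export
nuclide_sr89 <- function() {
  beta_nuclide("Sr-89", half_life_days = 50.5,
               mean_energy_MeV = 0.583, max_energy_MeV = 1.495)
}

# J per MeV
MEV_TO_J <- 1.602e-13

#' Equilibrium dose constant of a beta emitter
#'
#' The mean energy emitted per decay, expressed per unit activity and time:
#' `yield * mean_energy[MeV] * 1.602e-13` in Gy.kg/(Bq.s) (1 Gy.kg = 1 J).
#' Multiplying by an activity concentration (Bq/kg) and an absorbed fraction
#' gives an absorbed dose rate in Gy/s.
#'
#' @param nuclide A [beta_nuclide()].
#' @return Equilibrium dose constant in Gy.kg/(Bq.s).
#' @export
#' @examples
#' equilibrium_dose_constant(nuclide_ca45())  # 1.233e-14
equilibrium_dose_constant <- function(nuclide) {
  stopifnot(inherits(nuclide, "beta_nuclide"))
  nuclide$yield * nuclide$mean_energy_MeV * MEV_TO_J
}

#' Beta-particle range in tissue (Katz-Penfold)
#'
#' Continuous-slowing-down range of beta particles with endpoint energy `E`
#' (MeV) in a medium of the given density, from the Katz-Penfold empirical
#' range-energy relation `R[g/cm^2] = 0.412 E^(1.265 - 0.0954 ln E)`, valid
#' for 0.01 <= E <= 2.5 MeV.
#'
#' @param max_energy_MeV Endpoint energy in MeV (0.01-2.5).
#' @param density_g_cm3 Medium density, g/cm^3 (1.0 for water/soft tissue).
#' @return Range in cm.
#' @export
#' @examples
#' beta_range_tissue(0.257)  # 0.062 cm for Ca-45 betas in water
beta_range_tissue <- function(max_energy_MeV, density_g_cm3 = 1.0) {
  if (any(!is.finite(max_energy_MeV)) ||
      any(max_energy_MeV < 0.01) || any(max_energy_MeV > 2.5))
    stop("endpoint energy outside the 0.01-2.5 MeV validity window",
         call. = FALSE)
  stopifnot(density_g_cm3 > 0)
  r_mass <- 0.412 * max_energy_MeV ^
    (1.265 - 0.0954 * log(max_energy_MeV))
  r_mass / density_g_cm3
}

#' Physical half-life in weeks
#'
#' @param nuclide A [beta_nuclide()].
#' @param digits Significant digits for the report (default 3).
#' @return Half-life in weeks, rounded to `digits` significant figures.
#' @export
#' @examples
#' half_life_weeks(nuclide_ca45())  # 23.3
half_life_weeks <- function(nuclide, digits = 3) {
  stopifnot(inherits(nuclide, "beta_nuclide"))
  signif(nuclide$half_life_days / 7, digits)
}

#' Slab surrogate for the absorbed fraction
#'
#' A deliberately simplified geometric stand-in for point-kernel absorbed
#' fraction calculations: the fraction of beta energy retained by a slab of
#' bone is approximated by `min(1, thickness / range)`.  It captures only the
#' qualitative behaviour (thicker bone or shorter range keeps more energy);
#' for dose calculations use a measured/published absorbed fraction instead
#' (0.9 for Ca-45, 0.4 for Sr-89 in mouse bone).
#'
#' @param beta_range_cm Beta range in tissue, cm (> 0).
#' @param bone_thickness_cm Slab thickness, cm (> 0).
#' @return Absorbed fraction estimate in (0, 1].
#' @export
absorbed_fraction_slab_estimate <- function(beta_range_cm, bone_thickness_cm) {
  if (any(!is.finite(beta_range_cm)) || any(beta_range_cm <= 0) ||
      any(!is.finite(bone_thickness_cm)) || any(bone_thickness_cm <= 0))
    stop("range and thickness must be positive", call. = FALSE)
  pmin(1, bone_thickness_cm / beta_range_cm)
}
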