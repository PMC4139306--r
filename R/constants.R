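# Physical constants (CODATA 2018) in the package's working units:
# lengths in angstrom, charges in elementary charges, energies in kcal/mol.

#' Physical constants and unit conversions
#'
#' Potentials are held internally in kcal/mol/e. `esp_units()` returns the
#' conversion factors to kT/e and mV at a given temperature, for display.
#'
#' @details
#' `coulomb_kcal` is the Coulomb constant expressed so that a unit point
#' charge in a medium of relative dielectric \eqn{\epsilon_r} produces
#' \eqn{\phi(r) = k_C q / (\epsilon_r r)} kcal/mol/e with `r` in angstrom:
#' \eqn{k_C = e^2 N_A / (4\pi\epsilon_0 \cdot 10^{-10}\,\mathrm{m} \cdot
#' 4184\,\mathrm{J/kcal}) \approx 332.06} kcal \eqn{\cdot} A / (mol e^2).
#'
#' @param temperature_K temperature in kelvin.
#' @return `esp_units()`: a named list with `kT_per_e_kcal` (one kT/e in
#'   kcal/mol/e) and `mV_per_kcal` (millivolt per kcal/mol/e).
#' @examples
#' esp_units(296)$kT_per_e_kcal  # ~0.588: the -0.6 kcal/mol/e contour is ~1 kT/e
#' @export
esp_units <- function(temperature_K = 296) {
  stopifnot(temperature_K > 0)
  kT <- .const$kB_kcal * temperature_K           # kcal/mol
  list(
    kT_per_e_kcal = kT,
    # 1 kcal/mol/e = 4184 / (e * NA) J/C = 4184/96485.3 V = 43.364 mV
    mV_per_kcal = 4184 / .const$faraday * 1000
  )
}

.const <- local({
  e <- 1.602176634e-19          # C
  NA_ <- 6.02214076e23          # 1/mol
  eps0 <- 8.8541878128e-12      # F/m
  kB <- 1.380649e-23            # J/K
  list(
    e = e, NA_ = NA_, eps0 = eps0, kB_J = kB,
    kB_kcal = kB * NA_ / 4184,                     # kcal/mol/K
    faraday = e * NA_,                             # C/mol
    # kcal*A/(mol*e^2)
    coulomb_kcal = e^2 * NA_ / (4 * pi * eps0 * 1e-10 * 4184)
  )
})

#' Inverse Debye screening length
#'
#' Computes \eqn{\kappa} in 1/angstrom for a 1:1 electrolyte of the given
#' ionic strength in a solvent of relative dielectric `epsilon` at
#' temperature `temperature_K`:
#' \eqn{\kappa^2 = 2 N_A e^2 (1000 I) / (\epsilon_0 \epsilon k_B T)}.
#'
#' @param ionic_strength_M ionic strength in mol/L.
#' @param epsilon solvent relative dielectric constant.
#' @param temperature_K temperature in kelvin.
#' @return kappa in 1/angstrom (0 when the ionic strength is 0).
#' @examples
#' 1 / debye_kappa(0.1, 80, 296)  # Debye length, ~9.6 A
#' @export
debye_kappa <- function(ionic_strength_M, epsilon = 80, temperature_K = 296) {
  stopifnot(ionic_strength_M >= 0, epsilon > 0, temperature_K > 0)
  if (ionic_strength_M == 0) return(0)
  k2_m2 <- 2 * .const$NA_ * .const$e^2 * (1000 * ionic_strength_M) /
    (.const$eps0 * epsilon * .const$kB_J * temperature_K)
  sqrt(k2_m2) * 1e-10
}
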