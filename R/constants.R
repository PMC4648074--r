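#' Physical constants and unit conversions
#'
#' All unit conversions in the package route through this single table.
#' Internal units are Angstrom for length, elementary charges for charge and
#' kT/e for the electrostatic potential; energies are reported in kcal/mol
#' (and kT).
#'
#' @return A named list with components
#'   \describe{
#'     \item{kB_kcal}{Boltzmann constant times Avogadro's number,
#'       kcal mol^-1 K^-1.}
#'     \item{N_A}{Avogadro's number, mol^-1.}
#'     \item{f_C_kcal}{Coulomb conversion factor e^2/(4 pi eps_0) expressed
#'       as kcal mol^-1 Angstrom per squared elementary charge (332.0637).}
#'     \item{f_C_eV}{The same factor in eV Angstrom (14.3996).}
#'   }
#' @examples
#' pc <- physical_constants()
#' pc$f_C_kcal # 332.0637
#' @export
physical_constants <- function() {
  list(
    kB_kcal  = 1.987204259e-3,
    N_A      = 6.02214076e23,
    f_C_kcal = 332.0637133,
    f_C_eV   = 14.39964548
  )
}

#' Thermal energy kT in kcal/mol at a given temperature
#' @param temperature temperature in K
#' @return kT in kcal/mol
#' @export
kT_kcal <- function(temperature) {
  stopifnot(temperature > 0)
  physical_constants()$kB_kcal * temperature
}

# Vacuum Bjerrum length e^2/(4 pi eps_0 kT) in Angstrom: the factor that
# converts charge/distance (e/Angstrom) into potential in kT/e.
beta_length <- function(temperature) {
  physical_constants()$f_C_kcal / kT_kcal(temperature)
}
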