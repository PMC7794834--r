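#' Physical constants used throughout the package
#'
#' Returns the CODATA-derived constants in the package's internal unit system
#' (lengths in Angstrom, energies in kcal/mol, charges in units of the
#' elementary charge e).
#'
#' @return A list with components:
#' \describe{
#'   \item{coulomb_kcal}{\eqn{e^2 N_A / (4\pi\epsilon_0)} in kcal A/mol
#'     (332.0637...): the Coulomb energy of two unit charges 1 A apart in
#'     vacuum, per mole.}
#'   \item{boltzmann_kcal}{\eqn{k_B N_A} in kcal/(mol K) (1.9872e-3); the
#'     molar gas constant in kcal units.}
#' }
#' @examples
#' kT <- ion_constants()$boltzmann_kcal * 298.15   # ~0.5925 kcal/mol
#' @export
ion_constants <- function() {
  list(
    # e^2 * N_A / (4 pi eps0) converted to kcal*A/mol:
    #   (1.602176634e-19 C)^2 * 6.02214076e23 / (4*pi*8.8541878128e-12 F/m)
    #   = 2.30707755e-18 J*m/mol -> * 1e10 A/m / 4184 J/kcal
    coulomb_kcal   = 332.063713,
    # k_B * N_A / 4184
    boltzmann_kcal = 1.987204259e-3
  )
}

# thermal energy kT in kcal/mol at temperature T (K)
kT_kcal <- function(temperature) ion_constants()$boltzmann_kcal * temperature
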