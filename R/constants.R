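#' Physical constants and the engine unit system
#'
#' The engine works in Angstrom, femtosecond, atomic mass unit and kcal/mol.
#' `cg_constants()` returns the constants used throughout the package in that
#' unit system, centralised so that every term and the integrator agree.
#'
#' @return A named list:
#' \describe{
#'   \item{kB}{Boltzmann constant, kcal/mol/K.}
#'   \item{coulomb}{Coulomb constant, kcal mol^-1 A e^-2 (vacuum).}
#'   \item{accel}{Conversion from (kcal/mol/A)/amu to A/fs^2.}
#'   \item{NA_avogadro}{Avogadro's number, mol^-1.}
#' }
#' @examples
#' cg_constants()$kB * 300  # thermal energy at 300 K in kcal/mol
#' @export
cg_constants <- function() {
  list(
    kB          = 1.987204e-3,   # kcal/mol/K
    coulomb     = 332.0637,      # kcal*A/(mol*e^2), i.e. e_c^2/(4 pi eps0)
    accel       = 4.184e-4,      # (kcal/mol/A)/amu -> A/fs^2
    NA_avogadro = 6.02214076e23
  )
}

# internal shorthands
.kB <- 1.987204e-3
.KC <- 332.0637
.ACC <- 4.184e-4
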