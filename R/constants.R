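#' Physical constants in the internal unit system
#'
#' The package works in a GROMOS-style internal unit system: length in nm,
#' time in ps, charge in units of the elementary charge e, energy in
#' kJ mol^-1 and temperature in K.  In these units the Coulomb prefactor
#' 1/(4 pi eps0) is `felec` = 138.935458 kJ mol^-1 nm e^-2 and masses in
#' g mol^-1 make 1 amu nm^2 ps^-2 = 1 kJ mol^-1, so no mass conversion is
#' ever needed.
#'
#' @return Named list of constants:
#' \describe{
#'   \item{felec}{Coulomb constant, kJ mol^-1 nm e^-2.}
#'   \item{hartree_kjmol}{Hartree energy in kJ mol^-1.}
#'   \item{bohr_nm}{Bohr radius in nm.}
#'   \item{debye_enm}{1 Debye in e nm.}
#'   \item{R_kjmol}{Molar gas constant in kJ mol^-1 K^-1.}
#'   \item{kB_SI}{Boltzmann constant in J K^-1.}
#'   \item{avogadro}{Avogadro constant in mol^-1.}
#'   \item{bar_per_kjmolnm3}{1 kJ mol^-1 nm^-3 expressed in bar.}
#'   \item{atm_bar}{1 atm in bar.}
#' }
#' @export
#' @examples
#' phys_constants()$felec
phys_constants <- function() {
  list(
    felec            = 138.935458,
    hartree_kjmol    = 2625.4996394799,
    bohr_nm          = 0.052917721067,
    debye_enm        = 0.020819434,
    R_kjmol          = 0.0083144626182,
    kB_SI            = 1.380649e-23,
    avogadro         = 6.02214076e23,
    bar_per_kjmolnm3 = 16.60539067,
    atm_bar          = 1.01325
  )
}

# internal short-hands (kept in sync with phys_constants())
.felec       <- 138.935458
.hartree     <- 2625.4996394799
.bohr        <- 0.052917721067
.debye       <- 0.020819434
.Rgas        <- 0.0083144626182
.kB_SI       <- 1.380649e-23
.avogadro    <- 6.02214076e23
.bar_kjmolnm3 <- 16.60539067   # 1 kJ/mol/nm^3 in bar
.atm_bar     <- 1.01325
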