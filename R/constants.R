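# Physical constants (CODATA 2018).  Canonical energy unit throughout the
# package is kcal mol^-1; hartree inputs are converted once, at load time,
# with the single factor below.

#' @rdname units
#' @export
KCAL_PER_HARTREE <- 627.5095

#' Unit conversion constants
#'
#' `KCAL_PER_HARTREE` converts hartree to kcal mol^-1 and is the single
#' conversion point used everywhere in the package.
#'
#' @name units
NULL

.R_KCAL <- 1.98720425e-3    # gas constant, kcal mol^-1 K^-1
.KB     <- 1.380649e-23     # Boltzmann, J K^-1
.H      <- 6.62607015e-34   # Planck, J s
.M_PROTON <- 1.67262192369e-27 # proton mass, kg
.P_ATM  <- 101325           # 1 atm, Pa
.L_ATM_PER_MOL_K <- 0.082057366 # R in L atm mol^-1 K^-1

.check_temperature <- function(T) {
  if (!is.numeric(T) || length(T) != 1L || !is.finite(T) || T <= 0)
    stop("temperature must be a single finite value > 0 (kelvin), got: ",
         deparse(T), call. = FALSE)
  invisible(T)
}

#' The factor ln(10)RT
#'
#' @param T temperature in kelvin.
#' @return ln(10)*R*T in kcal mol^-1 (1.364 at 298.15 K), the factor that
#'   converts a pKa unit into a Gibbs energy.
#' @export
ln10RT <- function(T = 298.15) {
  .check_temperature(T)
  log(10) * .R_KCAL * T
}

#' Ideal calibration slope 1/(ln(10)RT)
#'
#' The slope a thermodynamic-cycle pKa calibration would have if the
#' computed solvation energies carried no systematic error: 0.733 mol
#' kcal^-1 at 298.15 K.
#'
#' @param T temperature in kelvin.
#' @return slope in mol kcal^-1.
#' @export
ideal_slope <- function(T = 298.15) {
  1 / ln10RT(T)
}

#' Gas-phase Gibbs energy of the proton
#'
#' Treats H+ as an ideal monoatomic gas at 1 atm: enthalpy 5/2 RT,
#' entropy from the Sackur-Tetrode equation.  At 298.15 K this gives
#' -6.28 kcal mol^-1.
#'
#' @param T temperature in kelvin.
#' @return Gibbs energy in kcal mol^-1.
#' @export
proton_gas_gibbs <- function(T = 298.15) {
  .check_temperature(T)
  kT <- .KB * T
  # S/R = ln[(2 pi m kT / h^2)^(3/2) * kT/P] + 5/2
  s_over_r <- 1.5 * log(2 * pi * .M_PROTON * kT / .H^2) + log(kT / .P_ATM) + 2.5
  h <- 2.5 * .R_KCAL * T
  h - T * (s_over_r * .R_KCAL)
}

#' Standard-state correction 1 atm -> 1 mol L^-1
#'
#' RT ln(V_m / 1 L mol^-1) with the molar volume V_m = RT/P computed from
#' the temperature (24.46 L mol^-1 at 298.15 K, 1 atm), giving 1.89 kcal
#' mol^-1 at 298.15 K.  Applied only to the proton: the species-level
#' corrections of the neutral and protonated base cancel in the reduced
#' basicity.
#'
#' @param T temperature in kelvin.
#' @return correction in kcal mol^-1.
#' @export
standard_state_correction <- function(T = 298.15) {
  .check_temperature(T)
  vm <- .L_ATM_PER_MOL_K * T   # L mol^-1 at 1 atm
  .R_KCAL * T * log(vm)
}

.check_finite <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop(what, " must be finite numeric", call. = FALSE)
  invisible(x)
}

#' Assemble the total Gibbs energy of the solvated proton
#'
#' Sums the gas-phase Gibbs energy, the solvation Gibbs energy and the
#' standard-state correction: with the literature values -6.28, -252.9
#' and 1.89 kcal mol^-1 the total is -257.3 kcal mol^-1 in acetonitrile.
#'
#' @param g_gas gas-phase Gibbs energy of the proton, kcal mol^-1.
#' @param dg_solv solvation Gibbs energy of the proton, kcal mol^-1.
#' @param ss standard-state correction, kcal mol^-1.
#' @return total Gibbs energy, kcal mol^-1.
#' @seealso [solvation_from_total()] for the inverse.
#' @export
assemble_proton_gibbs <- function(g_gas, dg_solv, ss) {
  .check_finite(g_gas, "g_gas"); .check_finite(dg_solv, "dg_solv")
  .check_finite(ss, "ss")
  g_gas + dg_solv + ss
}

#' Solvation Gibbs energy from a total proton Gibbs energy
#'
#' Inverts [assemble_proton_gibbs()]: given a total proton Gibbs energy
#' (e.g. one extrapolated from calibrations), subtracts the gas-phase term
#' and the standard-state correction to leave the solvation term.
#'
#' @param total total Gibbs energy of the solvated proton, kcal mol^-1.
#' @param g_gas gas-phase Gibbs energy of the proton, kcal mol^-1.
#' @param ss standard-state correction, kcal mol^-1.
#' @return solvation Gibbs energy, kcal mol^-1.
#' @export
solvation_from_total <- function(total, g_gas, ss) {
  .check_finite(total, "total"); .check_finite(g_gas, "g_gas")
  .check_finite(ss, "ss")
  total - g_gas - ss
}

#' Bundle of thermodynamic constants
#'
#' Evaluates the whole constants chain at one temperature: the gas
#' constant, ln(10)RT, the proton gas-phase Gibbs energy, the
#' standard-state correction, the literature proton solvation energy in
#' acetonitrile and the assembled total literature proton Gibbs energy.
#'
#' @param T temperature in kelvin.
#' @param dgs_proton_lit literature Gibbs energy of solvation of the proton
#'   in acetonitrile, kcal mol^-1.
#' @return an object of class `thermo_constants`: a list with elements
#'   `T`, `R`, `ln10RT`, `g_gas_proton`, `ss_correction`,
#'   `dgs_proton_lit` and `g_lit` (the three-term sum).
#' @examples
#' tc <- thermo_constants()
#' tc$g_lit   # about -257.3 kcal/mol
#' @export
thermo_constants <- function(T = 298.15, dgs_proton_lit = -252.9) {
  .check_temperature(T)
  .check_finite(dgs_proton_lit, "dgs_proton_lit")
  g_gas <- proton_gas_gibbs(T)
  ss <- standard_state_correction(T)
  structure(list(
    T = T,
    R = .R_KCAL,
    ln10RT = ln10RT(T),
    g_gas_proton = g_gas,
    ss_correction = ss,
    dgs_proton_lit = dgs_proton_lit,
    g_lit = assemble_proton_gibbs(g_gas, dgs_proton_lit, ss)
  ), class = "thermo_constants")
}

#' @export
print.thermo_constants <- function(x, ...) {
  cat("Thermodynamic constants at T =", format(x$T), "K\n")
  cat(sprintf("  ln(10)RT            : %8.4f kcal/mol\n", x$ln10RT))
  cat(sprintf("  ideal slope         : %8.3f mol/kcal\n", 1 / x$ln10RT))
  cat(sprintf("  G_gas(H+)           : %8.2f kcal/mol\n", x$g_gas_proton))
  cat(sprintf("  std-state correction: %8.2f kcal/mol\n", x$ss_correction))
  cat(sprintf("  dG_s(H+) literature : %8.1f kcal/mol\n", x$dgs_proton_lit))
  cat(sprintf("  G_lit(H+) total     : %8.1f kcal/mol\n", x$g_lit))
  invisible(x)
}
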