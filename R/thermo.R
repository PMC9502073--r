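# Species- and pair-level thermochemistry: reduced basicity in solution,
# gas-phase basicity, and the thermodynamic-cycle pKa.

#' Gibbs energies of one species
#'
#' Holds the gas-phase Gibbs energy and the solvation Gibbs energy of a
#' single species (a neutral base B or its conjugate acid BH+).  Energies
#' are converted to kcal mol^-1 at construction; hartree inputs use
#' [KCAL_PER_HARTREE].  The solvation energy is the gas-to-solution
#' transfer Gibbs energy, negative for stabilisation; it is stored as
#' given, never negated internally.
#'
#' @param g_gas gas-phase Gibbs energy.
#' @param dg_solv solvation Gibbs energy.
#' @param label free-text species identifier.
#' @param unit_gas unit of `g_gas`: `"kcal/mol"` or `"hartree"`.
#' @param unit_solv unit of `dg_solv`: `"kcal/mol"` or `"hartree"`.
#' @return an object of class `species_thermo` with both energies in
#'   kcal mol^-1.
#' @export
species_thermo <- function(g_gas, dg_solv, label = "",
                           unit_gas = c("kcal/mol", "hartree"),
                           unit_solv = c("kcal/mol", "hartree")) {
  unit_gas <- match.arg(unit_gas)
  unit_solv <- match.arg(unit_solv)
  .check_finite(g_gas, paste0("g_gas (", label, ")"))
  .check_finite(dg_solv, paste0("dg_solv (", label, ")"))
  if (unit_gas == "hartree") g_gas <- g_gas * KCAL_PER_HARTREE
  if (unit_solv == "hartree") dg_solv <- dg_solv * KCAL_PER_HARTREE
  structure(list(g_gas = g_gas, dg_solv = dg_solv, label = label),
            class = "species_thermo")
}

#' A base / conjugate-acid pair
#'
#' Bundles the neutral base and its protonated form with the experimental
#' data and labels the calibration machinery needs.  A positive solvation
#' energy for the cation BH+ is physically suspicious in acetonitrile and
#' triggers a warning (not an error).
#'
#' @param id record identifier (must be unique within a table).
#' @param base_class protonation-site element class: `"N"`, `"P"` or `"C"`.
#' @param model computational-model label, free text (e.g. `"IPCM//M6"`).
#' @param neutral a [species_thermo] for B.
#' @param protonated a [species_thermo] for BH+.
#' @param pka_exp experimental pKa (optional).
#' @param gb_exp experimental gas-phase basicity in kcal mol^-1 (optional).
#' @return an object of class `base_record`.
#' @export
base_record <- function(id, base_class, model, neutral, protonated,
                        pka_exp = NA_real_, gb_exp = NA_real_) {
  if (!inherits(neutral, "species_thermo") ||
      !inherits(protonated, "species_thermo"))
    stop("neutral and protonated must be species_thermo objects", call. = FALSE)
  base_class <- as.character(base_class)
  if (!base_class %in% c("N", "P", "C"))
    stop("base_class of record '", id, "' must be one of {N, P, C}, got '",
         base_class, "'", call. = FALSE)
  if (!is.na(pka_exp) && !is.finite(pka_exp))
    stop("pka_exp of record '", id, "' must be finite when present",
         call. = FALSE)
  if (is.finite(protonated$dg_solv) && protonated$dg_solv > 0)
    warning("record '", id, "': positive solvation energy (",
            format(protonated$dg_solv), " kcal/mol) for the cation BH+",
            call. = FALSE)
  structure(list(id = as.character(id), base_class = base_class,
                 model = as.character(model), neutral = neutral,
                 protonated = protonated, pka_exp = pka_exp, gb_exp = gb_exp),
            class = "base_record")
}

#' Reduced basicity in solution
#'
#' The deprotonation Gibbs energy of BH+ in solution excluding the
#' proton's own Gibbs energy: G_sol(B) - G_sol(BH+), where each solution
#' Gibbs energy is the gas-phase Gibbs energy plus the solvation Gibbs
#' energy.  Species-level standard-state corrections cancel between the
#' neutral and the cation and are deliberately absent here; only the
#' proton carries one, inside [assemble_proton_gibbs()].
#'
#' @param rec a [base_record], or an energy-table `data.frame` with
#'   columns `g_gas_B`, `g_gas_BH`, `dg_solv_B`, `dg_solv_BH` (kcal
#'   mol^-1), for which a vector is returned.
#' @return reduced basicity in kcal mol^-1; positive for any realistic base.
#' @export
reduced_basicity <- function(rec) {
  UseMethod("reduced_basicity")
}

#' @export
reduced_basicity.base_record <- function(rec) {
  for (side in c("neutral", "protonated")) {
    sp <- rec[[side]]
    if (is.null(sp$g_gas) || is.null(sp$dg_solv) ||
        !is.finite(sp$g_gas) || !is.finite(sp$dg_solv))
      stop("record '", rec$id, "': missing or non-finite energy for the ",
           side, " species", call. = FALSE)
  }
  (rec$neutral$g_gas + rec$neutral$dg_solv) -
    (rec$protonated$g_gas + rec$protonated$dg_solv)
}

#' @export
reduced_basicity.data.frame <- function(rec) {
  need <- c("g_gas_B", "g_gas_BH", "dg_solv_B", "dg_solv_BH")
  miss <- setdiff(need, names(rec))
  if (length(miss))
    stop("energy table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  (rec$g_gas_B + rec$dg_solv_B) - (rec$g_gas_BH + rec$dg_solv_BH)
}

#' Gas-phase basicity
#'
#' The negative Gibbs energy of the gas-phase protonation B + H+ -> BH+:
#' GB = G_gas(B) + G_gas(H+) - G_gas(BH+), with the proton term from
#' [proton_gas_gibbs()].
#'
#' @param rec a [base_record].
#' @param T temperature in kelvin.
#' @return gas-phase basicity in kcal mol^-1.
#' @export
gas_basicity <- function(rec, T = 298.15) {
  if (!inherits(rec, "base_record"))
    stop("rec must be a base_record", call. = FALSE)
  if (!is.finite(rec$neutral$g_gas) || !is.finite(rec$protonated$g_gas))
    stop("record '", rec$id, "': missing gas-phase energy", call. = FALSE)
  rec$neutral$g_gas + proton_gas_gibbs(T) - rec$protonated$g_gas
}

#' pKa from a reduced basicity and a proton Gibbs energy
#'
#' The thermodynamic-cycle relation: pKa = (dG' + G_sol(H+)) / ln(10)RT.
#' Increasing `dg` by one ln(10)RT raises the pKa by exactly one unit.
#'
#' @param dg reduced basicity, kcal mol^-1 (vectorised).
#' @param g_proton_sol total Gibbs energy of the solvated proton,
#'   kcal mol^-1.
#' @param T temperature in kelvin.
#' @return pKa (dimensionless).
#' @export
pka_from_reduced_basicity <- function(dg, g_proton_sol, T = 298.15) {
  .check_finite(dg, "dg"); .check_finite(g_proton_sol, "g_proton_sol")
  (dg + g_proton_sol) / ln10RT(T)
}
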