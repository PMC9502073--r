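# The "two-fit" inference: express each calibration in energy units,
# then regress the energy-unit intercept n on the slope m across methods
# and classes and extrapolate to the ideal slope m = 1, where n equals
# the total Gibbs energy of the solvated proton.

#' Express a calibration in energy units
#'
#' Rewrites a pKa calibration pKa = a dG' + b as
#' ln(10)RT pKa = m dG' + n with m = a ln(10)RT and n = b ln(10)RT.
#' In this representation the systematic solvation error is a deviation
#' of the dimensionless slope m from 1, and the intercept n contains the
#' proton Gibbs energy.
#'
#' @param fit a `calibration_fit`.
#' @param T temperature in kelvin.
#' @param g_lit reference total proton Gibbs energy used to scale the
#'   intercept (`n_scaled = n / g_lit`); defaults to the assembled
#'   literature chain from [thermo_constants()].
#' @return a one-row `data.frame` (class `meta_point`) with columns
#'   `m`, `n`, `n_scaled`, `model`, `base_class`, `r2`.
#' @export
to_energy_units <- function(fit, T = 298.15, g_lit = NULL) {
  if (!inherits(fit, "calibration_fit"))
    stop("fit must be a calibration_fit", call. = FALSE)
  f <- ln10RT(T)
  if (is.null(g_lit)) g_lit <- thermo_constants(T)$g_lit
  n <- fit$b * f
  structure(data.frame(m = fit$a * f, n = n,
                       n_scaled = scaled_intercept(n, g_lit),
                       model = fit$model, base_class = fit$base_class,
                       r2 = fit$r2, stringsAsFactors = FALSE),
            class = c("meta_point", "data.frame"))
}

#' Scaled intercept n' = n / G_lit(H+)
#'
#' Diagnostic ratio comparing the energy-unit intercept with a reference
#' proton Gibbs energy.  If the systematic error were a pure scaling of
#' the whole relation, n' would equal the slope m.
#'
#' @param n energy-unit intercept, kcal mol^-1 (vectorised).
#' @param g_lit reference total proton Gibbs energy, kcal mol^-1 (nonzero).
#' @return n / g_lit, dimensionless.
#' @export
scaled_intercept <- function(n, g_lit) {
  .check_finite(n, "n"); .check_finite(g_lit, "g_lit")
  if (any(g_lit == 0))
    stop("reference proton Gibbs energy must be nonzero", call. = FALSE)
  n / g_lit
}

#' Meta-regression of intercept on slope
#'
#' Pools every (m, n) calibration point — all computational models and
#' all base classes — into one unweighted OLS of n on m and evaluates the
#' fitted line at the ideal slope m = 1.  At m = 1 the systematic
#' solvation error vanishes by construction, so the fitted value
#' estimates the total Gibbs energy of the solvated proton without using
#' any external reference value.
#'
#' @param points meta points: a `data.frame` with columns `m` and `n`
#'   (e.g. `rbind` of [to_energy_units()] rows) or a list of such rows.
#' @param r2_floor calibrations with R-squared below this are still used,
#'   with a warning (set to 0 to silence); preset points with unknown
#'   R-squared are never warned about.
#' @return an object of class `meta_fit`: `alpha` (slope of n on m,
#'   kcal mol^-1), `beta` (intercept, kcal mol^-1), `g_sol_opt`
#'   (= alpha + beta, the value at m = 1), `r2`, `n_points`, and the
#'   points used.
#' @export
meta_fit <- function(points, r2_floor = 0.95) {
  if (is.list(points) && !is.data.frame(points))
    points <- do.call(rbind, points)
  if (!is.data.frame(points) || !all(c("m", "n") %in% names(points)))
    stop("points must be a data.frame with columns m and n", call. = FALSE)
  if (nrow(points) < 2L)
    stop("meta-regression needs at least 2 (m, n) points", call. = FALSE)
  .check_finite(points$m, "m"); .check_finite(points$n, "n")
  if (length(unique(points$m)) < 2L)
    stop("meta-regression abscissae (m) are degenerate", call. = FALSE)
  if ("r2" %in% names(points)) {
    low <- is.finite(points$r2) & points$r2 < r2_floor
    if (any(low))
      warning(sum(low), " meta point(s) come from calibrations with R2 < ",
              r2_floor, "; they are still used", call. = FALSE)
  }
  fit <- stats::lm(n ~ m, data = points)
  co <- stats::coef(fit)
  alpha <- unname(co["m"]); beta <- unname(co["(Intercept)"])
  structure(list(alpha = alpha, beta = beta, g_sol_opt = alpha + beta,
                 r2 = if (nrow(points) > 2L)
                   suppressWarnings(summary(fit))$r.squared else 1,
                 n_points = nrow(points), points = points),
            class = "meta_fit")
}

#' @export
print.meta_fit <- function(x, ...) {
  cat("Intercept-vs-slope meta-regression (", x$n_points, " points)\n",
      sep = "")
  cat(sprintf("  n = %.2f x m %+.2f   (R2 = %.4f)\n", x$alpha, x$beta, x$r2))
  cat(sprintf("  extrapolated at m = 1: G_sol(H+) = %.1f kcal/mol\n",
              x$g_sol_opt))
  invisible(x)
}

#' Proton-energy report
#'
#' Turns an extrapolated total proton Gibbs energy into a solvation Gibbs
#' energy by removing the gas-phase term and the standard-state
#' correction, and compares both numbers with the literature chain.
#'
#' @param meta a `meta_fit` (or a single total Gibbs energy in
#'   kcal mol^-1).
#' @param constants a [thermo_constants()] bundle.
#' @return a list of class `proton_energy_report`: `g_sol_opt`,
#'   `dgs_calc` (the derived solvation energy), `g_lit`, `dgs_lit` and
#'   the differences `delta_g` and `delta_dgs` against the literature.
#' @export
proton_energy_report <- function(meta, constants = thermo_constants()) {
  g_opt <- if (inherits(meta, "meta_fit")) meta$g_sol_opt else {
    .check_finite(meta, "meta"); meta
  }
  dgs_calc <- solvation_from_total(g_opt, constants$g_gas_proton,
                                   constants$ss_correction)
  structure(list(g_sol_opt = g_opt, dgs_calc = dgs_calc,
                 g_lit = constants$g_lit, dgs_lit = constants$dgs_proton_lit,
                 delta_g = g_opt - constants$g_lit,
                 delta_dgs = dgs_calc - constants$dgs_proton_lit),
            class = "proton_energy_report")
}

#' @export
print.proton_energy_report <- function(x, ...) {
  cat("Gibbs energy of the proton in solution\n")
  cat(sprintf("  G_sol,opt(H+)  = %8.1f kcal/mol  (literature %8.1f, delta %+.1f)\n",
              x$g_sol_opt, x$g_lit, x$delta_g))
  cat(sprintf("  dG_s,calc(H+)  = %8.1f kcal/mol  (literature %8.1f, delta %+.1f)\n",
              x$dgs_calc, x$dgs_lit, x$delta_dgs))
  invisible(x)
}

#' Full pipeline: energy table to proton Gibbs energy
#'
#' Convenience wrapper: per-group calibrations
#' ([calibrate_energy_table()]), conversion to energy units
#' ([to_energy_units()]), pooled meta-regression ([meta_fit()]) and the
#' final report ([proton_energy_report()]).
#'
#' @param table an energy table `data.frame`.
#' @param T temperature in kelvin.
#' @param r2_floor passed to [meta_fit()].
#' @return a list with `fits`, `points`, `meta` and `report`.
#' @export
estimate_proton_energy <- function(table, T = 298.15, r2_floor = 0.95) {
  fits <- calibrate_energy_table(table)
  constants <- thermo_constants(T)
  points <- do.call(rbind, lapply(fits, to_energy_units, T = T,
                                  g_lit = constants$g_lit))
  meta <- meta_fit(points, r2_floor = r2_floor)
  list(fits = fits, points = points, meta = meta,
       report = proton_energy_report(meta, constants))
}
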