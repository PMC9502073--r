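# Per-class, per-method linear calibration of experimental pKa against the
# computed reduced basicity, with diagnostics and shipped presets.

.PRESETS <- list(
  N = c(a = 0.601, b = -146.8),
  P = c(a = 0.636, b = -158.5),
  C = c(a = 0.705, b = -178.3)
)

new_calibration_fit <- function(a, b, base_class, model, n_points,
                                r2 = NA_real_, mue = NA_real_, rms = NA_real_,
                                residuals = numeric(0), ids = character(0),
                                flagged = character(0), preset = FALSE) {
  structure(list(a = a, b = b, base_class = base_class, model = model,
                 n_points = n_points, r2 = r2, mue = mue, rms = rms,
                 residuals = residuals, ids = ids, flagged = flagged,
                 preset = preset),
            class = "calibration_fit")
}

#' Fit a linear pKa calibration
#'
#' Ordinary least squares of experimental pKa on the computed reduced
#' basicity for one base class under one computational model:
#' pKa = a * dG' + b.  The continuum-solvation systematic error shows up
#' as a slope well below the ideal 1/(ln(10)RT); the calibration absorbs
#' it.  Unweighted OLS via [stats::lm()].
#'
#' @param dg reduced basicities, kcal mol^-1.
#' @param pka experimental pKa values, same length.
#' @param base_class base class label (`"N"`, `"P"` or `"C"`).
#' @param model computational-model label.
#' @param ids optional per-base identifiers (used in diagnostics).
#' @param exclude optional character vector of ids to drop before fitting;
#'   there is no automatic outlier exclusion, only flagging
#'   (|studentized residual| > 3).
#' @return a `calibration_fit`: slope `a` (mol kcal^-1), intercept `b`,
#'   `n_points`, `r2`, `mue` (mean unsigned pKa error), `rms`
#'   (root-mean-square pKa error), signed residuals (predicted minus
#'   experimental) and flagged ids.
#' @examples
#' fit <- fit_linear_pka(c(270, 284), c(10, 20), "N", "demo")
#' fit$a  # 0.714...
#' @export
fit_linear_pka <- function(dg, pka, base_class = "N", model = "",
                           ids = NULL, exclude = NULL) {
  .check_finite(dg, "dg"); .check_finite(pka, "pka")
  if (length(dg) != length(pka))
    stop("dg and pka must have the same length", call. = FALSE)
  if (is.null(ids)) ids <- as.character(seq_along(dg))
  ids <- as.character(ids)
  if (!is.null(exclude)) {
    keep <- !ids %in% exclude
    dg <- dg[keep]; pka <- pka[keep]; ids <- ids[keep]
  }
  n <- length(dg)
  if (n < 2L)
    stop("calibration needs at least 2 points, got ", n, call. = FALSE)
  if (isTRUE(all.equal(stats::var(dg), 0)) || length(unique(dg)) < 2L)
    stop("calibration abscissae (reduced basicities) have zero variance",
         call. = FALSE)
  fit <- stats::lm(pka ~ dg)
  co <- stats::coef(fit)
  resid <- as.numeric(stats::fitted(fit) - pka)  # predicted - experimental
  # noiseless inputs are legitimate; silence the perfect-fit warning
  r2 <- if (n > 2L) suppressWarnings(summary(fit))$r.squared else 1
  flagged <- character(0)
  if (n > 3L) {
    rs <- suppressWarnings(stats::rstudent(fit))
    # NaN with a nonzero residual: the leave-one-out fit is exact, i.e.
    # the point is an infinitely significant outlier
    big <- (!is.na(rs) & abs(rs) > 3) |
      (is.nan(rs) & abs(resid) > 1e-8)
    flagged <- ids[big]
  }
  new_calibration_fit(a = unname(co["dg"]), b = unname(co["(Intercept)"]),
                      base_class = base_class, model = model, n_points = n,
                      r2 = r2, mue = mean(abs(resid)),
                      rms = sqrt(mean(resid^2)),
                      residuals = stats::setNames(resid, ids), ids = ids,
                      flagged = flagged)
}

#' Predict pKa from a calibration
#'
#' @param fit a `calibration_fit` (from [fit_linear_pka()] or
#'   [preset_equation()]).
#' @param dg reduced basicity values, kcal mol^-1 (vectorised).
#' @return predicted pKa values, a * dg + b.
#' @export
predict_pka <- function(fit, dg) {
  if (!inherits(fit, "calibration_fit"))
    stop("fit must be a calibration_fit", call. = FALSE)
  .check_finite(dg, "dg")
  fit$a * dg + fit$b
}

#' Error statistics of predicted vs experimental pKa
#'
#' @param predicted predicted pKa values.
#' @param experimental experimental pKa values, same length.
#' @param ids optional identifiers; the id of the largest absolute
#'   deviation is reported.
#' @return a list with `r2` (squared Pearson correlation of predicted and
#'   experimental; `NA` for a single pair or degenerate input), `mue`,
#'   `rms`, `max_abs_dev` and `max_id`.
#' @export
fit_statistics <- function(predicted, experimental, ids = NULL) {
  if (length(predicted) == 0L)
    stop("fit_statistics needs at least one pair", call. = FALSE)
  if (length(predicted) != length(experimental))
    stop("predicted and experimental must have the same length", call. = FALSE)
  .check_finite(predicted, "predicted"); .check_finite(experimental, "experimental")
  if (is.null(ids)) ids <- as.character(seq_along(predicted))
  d <- predicted - experimental
  r2 <- if (length(d) > 1L &&
            stats::sd(predicted) > 0 && stats::sd(experimental) > 0)
    stats::cor(predicted, experimental)^2 else NA_real_
  i <- which.max(abs(d))
  list(r2 = r2, mue = mean(abs(d)), rms = sqrt(mean(d^2)),
       max_abs_dev = abs(d[i]), max_id = as.character(ids[i]))
}

#' Recommended calibration equations
#'
#' The shipped IPCM//M6 calibrations for the three base classes:
#' N: pKa = 0.601 dG' - 146.8; P: pKa = 0.636 dG' - 158.5;
#' C: pKa = 0.705 dG' - 178.3.  Returned as preset `calibration_fit`
#' objects without diagnostics.
#'
#' @param base_class `"N"`, `"P"` or `"C"`.
#' @return a preset `calibration_fit`.
#' @export
preset_equation <- function(base_class) {
  base_class <- as.character(base_class)
  if (length(base_class) != 1L || !base_class %in% names(.PRESETS))
    stop("unknown base class '", base_class,
         "'; presets exist for {N, P, C}", call. = FALSE)
  p <- .PRESETS[[base_class]]
  new_calibration_fit(a = unname(p["a"]), b = unname(p["b"]),
                      base_class = base_class, model = "IPCM//M6",
                      n_points = NA_integer_, preset = TRUE)
}

#' @export
print.calibration_fit <- function(x, ...) {
  tag <- if (isTRUE(x$preset)) " (preset)" else ""
  cat(sprintf("%s-bases [%s]%s: pKa = %.3f x dG'_a,sol %+.1f\n",
              x$base_class, x$model, tag, x$a, x$b))
  if (!isTRUE(x$preset)) {
    cat(sprintf("  n = %d, R2 = %.3f, MUE = %.2f, RMS = %.2f pKa units\n",
                x$n_points, x$r2, x$mue, x$rms))
    if (length(x$flagged))
      cat("  flagged (|studentized residual| > 3):",
          paste(x$flagged, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Calibrate every model x class group of an energy table
#'
#' Splits an energy table by computational model and base class, computes
#' reduced basicities and fits one linear calibration per group that has
#' experimental pKa values.
#'
#' @param table an energy table `data.frame` (see [read_energy_table()]):
#'   columns `id`, `class`, `model`, the four energy columns, `pka_exp`.
#' @param min_points groups with fewer usable points are skipped with a
#'   message.
#' @return a list of `calibration_fit` objects, named `model/class`.
#' @export
calibrate_energy_table <- function(table, min_points = 2L) {
  if (!is.data.frame(table))
    stop("table must be a data.frame", call. = FALSE)
  need <- c("id", "class", "model", "pka_exp")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("energy table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  table$.dg <- reduced_basicity(table)
  groups <- split(table, list(table$model, table$class), drop = TRUE,
                  sep = "/")
  fits <- list()
  for (nm in names(groups)) {
    g <- groups[[nm]]
    g <- g[is.finite(g$pka_exp), , drop = FALSE]
    if (nrow(g) < min_points) {
      message("skipping group ", nm, ": only ", nrow(g),
              " point(s) with experimental pKa")
      next
    }
    fits[[nm]] <- fit_linear_pka(g$.dg, g$pka_exp,
                                 base_class = g$class[1L],
                                 model = g$model[1L], ids = g$id)
  }
  if (!length(fits))
    stop("no model/class group had enough experimental pKa values to fit",
         call. = FALSE)
  fits
}
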