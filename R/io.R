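# Delimited energy tables: a metadata header line (units, temperature),
# then a plain CSV/TSV with one base/conjugate-acid pair per row.

.REQUIRED_COLS <- c("id", "class", "model",
                    "g_gas_B", "g_gas_BH", "dg_solv_B", "dg_solv_BH")
.ENERGY_COLS <- c("g_gas_B", "g_gas_BH", "dg_solv_B", "dg_solv_BH")

.parse_meta_line <- function(line) {
  toks <- strsplit(sub("^#+\\s*", "", line), "\\s+")[[1]]
  toks <- toks[grepl("=", toks, fixed = TRUE)]
  kv <- strsplit(toks, "=", fixed = TRUE)
  stats::setNames(lapply(kv, function(p) paste(p[-1], collapse = "=")),
                  vapply(kv, `[[`, "", 1L))
}

#' Read an energy table
#'
#' Reads a delimited table of per-species Gibbs energies.  Leading `#`
#' lines carry metadata as `key=value` pairs; recognised keys are
#' `units_gas` (`kcal/mol` or `hartree`), `units_solv`, `T` (kelvin) and
#' `provenance`.  Unit conversion is applied once at load.  Required
#' columns: `id`, `class`, `model`, `g_gas_B`, `g_gas_BH`, `dg_solv_B`,
#' `dg_solv_BH`; optional: `pka_exp`, `gb_exp`.  Extra columns are kept.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"csv"` or `"tsv"`.
#' @param quiet suppress the row-count/unit message.
#' @return a `data.frame` with all energies in kcal mol^-1 and attributes
#'   `T`, `units_gas`, `units_solv`, `provenance`.
#' @export
read_energy_table <- function(path, format = c("auto", "csv", "tsv"),
                              quiet = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("energy table not found: ", path, call. = FALSE)
  if (format == "auto")
    format <- if (grepl("\\.tsv$|\\.tab$", path, ignore.case = TRUE))
      "tsv" else "csv"
  sep <- if (format == "tsv") "\t" else ","
  lines <- readLines(path, warn = FALSE)
  n_meta <- 0L
  meta <- list(units_gas = "kcal/mol", units_solv = "kcal/mol",
               T = "298.15", provenance = "")
  while (n_meta < length(lines) && grepl("^#", lines[n_meta + 1L])) {
    n_meta <- n_meta + 1L
    meta <- utils::modifyList(meta, .parse_meta_line(lines[n_meta]))
  }
  for (u in c("units_gas", "units_solv"))
    if (!meta[[u]] %in% c("kcal/mol", "hartree"))
      stop("unknown ", u, " '", meta[[u]], "'; expected kcal/mol or hartree",
           call. = FALSE)
  tab <- utils::read.table(text = lines[-seq_len(n_meta)], sep = sep,
                           header = TRUE, stringsAsFactors = FALSE,
                           strip.white = TRUE, colClasses = "character")
  miss <- setdiff(.REQUIRED_COLS, names(tab))
  if (length(miss))
    stop("energy table ", path, " lacks required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  file_line <- function(i) n_meta + 1L + i   # header occupies one line
  num_cols <- intersect(c(.ENERGY_COLS, "pka_exp", "gb_exp"), names(tab))
  for (cl in num_cols) {
    raw <- tab[[cl]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & nzchar(raw) & is.na(val))
    if (length(bad))
      stop("unparseable number in column '", cl, "' for id '",
           tab$id[bad[1L]], "' (line ", file_line(bad[1L]), " of ", path,
           ")", call. = FALSE)
    if (cl %in% .ENERGY_COLS) {
      missing_e <- which(is.na(val))
      if (length(missing_e))
        stop("missing energy in column '", cl, "' for id '",
             tab$id[missing_e[1L]], "' (line ", file_line(missing_e[1L]),
             " of ", path, ")", call. = FALSE)
    }
    tab[[cl]] <- val
  }
  if (!"pka_exp" %in% names(tab)) tab$pka_exp <- NA_real_
  bad_class <- which(!tab$class %in% c("N", "P", "C"))
  if (length(bad_class))
    stop("unknown base class '", tab$class[bad_class[1L]], "' for id '",
         tab$id[bad_class[1L]], "' (line ", file_line(bad_class[1L]),
         "); allowed classes are {N, P, C}", call. = FALSE)
  dup <- tab$id[duplicated(tab$id)]
  if (length(dup))
    stop("duplicate id(s) in energy table: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  if (meta$units_gas == "hartree")
    for (cl in c("g_gas_B", "g_gas_BH"))
      tab[[cl]] <- tab[[cl]] * KCAL_PER_HARTREE
  if (meta$units_solv == "hartree")
    for (cl in c("dg_solv_B", "dg_solv_BH"))
      tab[[cl]] <- tab[[cl]] * KCAL_PER_HARTREE
  pos <- which(tab$dg_solv_BH > 0)
  if (length(pos))
    warning("positive solvation energy for cation BH+ in record(s): ",
            paste(tab$id[pos], collapse = ", "), call. = FALSE)
  attr(tab, "T") <- as.numeric(meta$T)
  attr(tab, "units_gas") <- "kcal/mol"
  attr(tab, "units_solv") <- "kcal/mol"
  attr(tab, "provenance") <- meta$provenance
  if (!quiet)
    message("read ", nrow(tab), " record(s) from ", path,
            " (gas energies ", meta$units_gas, ", solvation ",
            meta$units_solv, ", T = ", meta$T, " K)")
  tab
}

#' Write an energy table
#'
#' Writes the metadata header line followed by the delimited table, the
#' inverse of [read_energy_table()].  Energies are written in
#' kcal mol^-1 at full precision.
#'
#' @param table an energy-table `data.frame`.
#' @param path output path; extension selects the delimiter unless
#'   `format` is given.
#' @param format `"auto"`, `"csv"` or `"tsv"`.
#' @param T temperature recorded in the header.
#' @param provenance free-text note recorded in the header.
#' @return the path, invisibly.
#' @export
write_energy_table <- function(table, path, format = c("auto", "csv", "tsv"),
                               T = 298.15, provenance = "") {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.tsv$|\\.tab$", path, ignore.case = TRUE))
      "tsv" else "csv"
  sep <- if (format == "tsv") "\t" else ","
  miss <- setdiff(.REQUIRED_COLS, names(table))
  if (length(miss))
    stop("cannot write energy table; missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  header <- paste0("# units_gas=kcal/mol units_solv=kcal/mol T=", format(T),
                   if (nzchar(provenance))
                     paste0(" provenance=", gsub("\\s", "_", provenance)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(format(table, digits = 15, trim = TRUE,
                            scientific = FALSE),
                     con, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write calibration and proton-energy results
#'
#' Writes a machine-readable results table (`<path>.csv`: slope `a`,
#' intercept `b`, energy-unit `m`, `n`, scaled intercept `n_scaled`, R2,
#' MUE, RMS per model x class) and a plain-text summary (`<path>.txt`)
#' with the calibration equations and the proton-energy chain.
#'
#' @param fits a non-empty list of `calibration_fit` objects.
#' @param meta a `meta_fit`, or `NULL` to omit the proton-energy section.
#' @param path output path prefix (no extension).
#' @param T temperature in kelvin.
#' @return paths of the two files, invisibly.
#' @export
write_results <- function(fits, meta, path, T = 298.15) {
  if (inherits(fits, "calibration_fit")) fits <- list(fits)
  if (!length(fits) || !all(vapply(fits, inherits, TRUE, "calibration_fit")))
    stop("fits must be a non-empty list of calibration_fit objects",
         call. = FALSE)
  constants <- thermo_constants(T)
  rows <- do.call(rbind, lapply(fits, function(f) {
    mp <- to_energy_units(f, T = T, g_lit = constants$g_lit)
    data.frame(model = f$model, base_class = f$base_class,
               a = f$a, b = f$b, m = mp$m, n = mp$n,
               n_scaled = mp$n_scaled, r2 = f$r2, mue = f$mue, rms = f$rms,
               n_points = f$n_points, stringsAsFactors = FALSE)
  }))
  csv_path <- paste0(path, ".csv")
  txt_path <- paste0(path, ".txt")
  utils::write.csv(format(rows, digits = 15, trim = TRUE,
                          scientific = FALSE),
                   csv_path, row.names = FALSE, quote = FALSE)
  txt <- c("Calibration equations (pKa = a x dG'_a,sol + b):",
           vapply(fits, function(f)
             sprintf("  %s-bases [%s]: pKa = %.3f x dG'_a,sol %+.1f%s",
                     f$base_class, f$model, f$a, f$b,
                     if (isTRUE(f$preset)) "  (preset)"
                     else sprintf("  (n = %d, R2 = %.3f, MUE = %.2f, RMS = %.2f)",
                                  f$n_points, f$r2, f$mue, f$rms)),
             ""))
  if (!is.null(meta)) {
    stopifnot(inherits(meta, "meta_fit"))
    rep <- proton_energy_report(meta, constants)
    txt <- c(txt, "",
             sprintf("Meta-regression n = %.2f x m %+.2f over %d points (R2 = %.4f)",
                     meta$alpha, meta$beta, meta$n_points, meta$r2),
             sprintf("G_sol,opt(H+) at m = 1 : %.1f kcal/mol", rep$g_sol_opt),
             sprintf("dG_s,calc(H+)          : %.1f kcal/mol", rep$dgs_calc),
             sprintf("literature chain       : G_lit = %.1f, dG_s,lit = %.1f kcal/mol",
                     rep$g_lit, rep$dgs_lit))
  }
  writeLines(txt, txt_path)
  invisible(c(csv = csv_path, txt = txt_path))
}
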