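# Convenience extraction of Gibbs energies from quantum-chemistry log
# text ("Sum of electronic and thermal Free Energies=" lines).  This is a
# transcription aid for building energy tables, not a log parser.

#' Extract Gibbs free energies from quantum-chemistry log text
#'
#' Scans log text for lines of the form
#' `Sum of electronic and thermal Free Energies=  -700.123456` (values in
#' hartree) and returns them converted to kcal mol^-1.
#'
#' @param path path to a log file, or `NULL` if `text` is given.
#' @param text character vector of log lines (alternative to `path`).
#' @return a `data.frame` with columns `line` (line number in the input),
#'   `g_hartree` and `g_kcal`; zero rows when nothing matches.
#' @export
read_qm_free_energies <- function(path = NULL, text = NULL) {
  if (is.null(text)) {
    if (is.null(path) || !file.exists(path))
      stop("log file not found: ", path, call. = FALSE)
    text <- readLines(path, warn = FALSE)
  }
  pat <- "Sum of electronic and thermal Free Energies=\\s*(-?[0-9]*\\.?[0-9]+)"
  hit <- regmatches(text, regexec(pat, text))
  idx <- which(lengths(hit) == 2L)
  g_hartree <- as.numeric(vapply(hit[idx], `[[`, "", 2L))
  data.frame(line = idx, g_hartree = g_hartree,
             g_kcal = g_hartree * KCAL_PER_HARTREE)
}
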