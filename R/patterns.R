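# Motif patterns. All patterns are written on the mRNA sense strand in the
# DNA alphabet (U -> T); degenerate positions use IUPAC codes.

# IUPAC expansion used by the scanner contract and the tests' oracle.
# N additionally matches an N in the subject (an unknown base is only ever
# matched by the fully degenerate code, never by a specific one).
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T", "N")
)

#' Define a motif pattern
#'
#' A named degenerate-nucleotide pattern with an element class. PAS and CPE
#' patterns feed the rule engine; PBE patterns are annotate-only.
#'
#' @param name Short identifier for the pattern.
#' @param element_class One of `"PAS"`, `"CPE"`, `"PBE"`.
#' @param pattern Degenerate-nucleotide string (IUPAC codes, sense strand),
#'   at least 4 nt long.
#' @return A one-row `data.frame` with columns `name`, `element_class`,
#'   `pattern`.
#' @examples
#' motif_pattern("PAS-canonical", "PAS", "AATAAA")
#' @export
motif_pattern <- function(name, element_class, pattern) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  element_class <- match.arg(element_class, c("PAS", "CPE", "PBE"))
  pattern <- toupper(chartr("u", "t", pattern))
  pattern <- chartr("U", "T", pattern)
  if (nchar(pattern) < 4L)
    stop("pattern '", name, "' is shorter than 4 nt", call. = FALSE)
  bad <- setdiff(strsplit(pattern, "")[[1]], names(IUPAC_SETS))
  if (length(bad) > 0L)
    stop("pattern '", name, "' contains non-IUPAC characters: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  data.frame(name = name, element_class = element_class, pattern = pattern,
             stringsAsFactors = FALSE)
}

#' Default motif set
#'
#' The motif definitions the package is calibrated with:
#' * PAS: the canonical hexamer `AATAAA`. The `ATTAAA` variant is shipped
#'   but disabled by default (`pas_variants = TRUE` enables it), because the
#'   reporter-mutagenesis series the engine is validated against uses and
#'   mutates only the canonical hexamer.
#' * CPE: the U-rich consensus, expanded to the four literal words
#'   `TTTTAT`, `TTTTAAT`, `TTTTTAT`, `TTTTTAAT` (T4-5 A1-2 T).
#' * PBE: `TGTANATA`, annotate-only.
#'
#' @param pas_variants If `TRUE`, also include the `ATTAAA` PAS variant.
#' @return A `data.frame` of patterns (see [motif_pattern()]).
#' @export
default_patterns <- function(pas_variants = FALSE) {
  pats <- list(motif_pattern("PAS-AATAAA", "PAS", "AATAAA"))
  if (pas_variants)
    pats <- c(pats, list(motif_pattern("PAS-ATTAAA", "PAS", "ATTAAA")))
  pats <- c(pats, list(
    motif_pattern("CPE-TTTTAT",   "CPE", "TTTTAT"),
    motif_pattern("CPE-TTTTAAT",  "CPE", "TTTTAAT"),
    motif_pattern("CPE-TTTTTAT",  "CPE", "TTTTTAT"),
    motif_pattern("CPE-TTTTTAAT", "CPE", "TTTTTAAT"),
    motif_pattern("PBE-TGTANATA", "PBE", "TGTANATA")
  ))
  do.call(rbind, pats)
}

validate_patterns <- function(patterns) {
  if (!is.data.frame(patterns) || nrow(patterns) == 0L)
    stop("'patterns' must be a non-empty data.frame of motif patterns",
         call. = FALSE)
  need <- c("name", "element_class", "pattern")
  if (!all(need %in% names(patterns)))
    stop("'patterns' must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  invisible(patterns)
}
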