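# Motif scanning and 3'-UTR architectures.
#
# Coordinates are 0-based half-open ([start, end)), as in BED, throughout
# the package; the GFF3 writer converts on output. Labels (PAS1, CPE3, ...)
# number elements 5'->3' within each class and are a pure function of the
# sorted element positions.

empty_elements <- function() {
  data.frame(element_class = character(0), start = integer(0),
             end = integer(0), matched_seq = character(0),
             label = character(0), stringsAsFactors = FALSE)
}

label_elements <- function(elements) {
  if (nrow(elements) == 0L) return(elements)
  elements <- elements[order(elements$start, elements$end,
                             elements$element_class), , drop = FALSE]
  for (cl in unique(elements$element_class)) {
    idx <- which(elements$element_class == cl)
    elements$label[idx] <- paste0(cl, seq_along(idx))
  }
  rownames(elements) <- NULL
  elements
}

# Merge overlapping same-class intervals into their union and relabel.
merge_elements <- function(elements, sequence = NULL) {
  if (nrow(elements) == 0L) return(empty_elements())
  out <- lapply(split(elements, elements$element_class), function(df) {
    ir <- IRanges::reduce(IRanges::IRanges(df$start + 1L, df$end))
    data.frame(element_class = df$element_class[1],
               start = IRanges::start(ir) - 1L, end = IRanges::end(ir),
               matched_seq = NA_character_, label = NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (!is.null(sequence))
    out$matched_seq <- substring(sequence, out$start + 1L, out$end)
  label_elements(out)
}

#' Scan a 3'-UTR for cis-element motifs
#'
#' Reports every substring of the sequence matching any pattern (IUPAC
#' codes in the pattern are expanded; the subject is matched literally;
#' sense strand only). Overlapping matches of the same element class are
#' merged into a single element spanning their union. Labels are assigned
#' 5'->3' within each class.
#'
#' @param record A [utr_record()].
#' @param patterns Motif set, see [default_patterns()].
#' @return A `data.frame` of cis-elements with columns `element_class`,
#'   `start` (0-based), `end` (exclusive), `matched_seq`, `label`, sorted
#'   by position.
#' @examples
#' rec <- utr_record("toy", "GGAATAAAGG")
#' scan_motifs(rec)
#' @export
scan_motifs <- function(record, patterns = default_patterns()) {
  stopifnot(inherits(record, "UtrRecord"))
  validate_patterns(patterns)
  subj <- Biostrings::DNAString(record$sequence)
  hits <- lapply(seq_len(nrow(patterns)), function(i) {
    m <- Biostrings::matchPattern(Biostrings::DNAString(patterns$pattern[i]),
                                  subj, fixed = "subject")
    if (length(m) == 0L) return(NULL)
    data.frame(element_class = patterns$element_class[i],
               start = IRanges::start(m) - 1L, end = IRanges::end(m),
               matched_seq = NA_character_, label = NA_character_,
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits)) return(empty_elements())
  merge_elements(hits, record$sequence)
}

#' Spacer length between two cis-elements
#'
#' The number of nucleotides strictly between two non-overlapping motifs
#' (edge-to-edge gap); symmetric in argument order. Two adjacent motifs
#' have gap 0.
#'
#' @param a,b Elements: one-row data.frames (or lists) with `start`/`end`.
#' @return Integer gap in nt.
#' @export
gap_distance <- function(a, b) {
  sa <- as.integer(a$start); ea <- as.integer(a$end)
  sb <- as.integer(b$start); eb <- as.integer(b$end)
  if (sa > sb) { tmp <- c(sa, ea); sa <- sb; ea <- eb; sb <- tmp[1]; eb <- tmp[2] }
  if (sb < ea)
    stop("elements overlap; gap distance is undefined", call. = FALSE)
  sb - ea
}

new_architecture <- function(utr_id, utr_length, elements,
                             sequence = NULL) {
  elements <- label_elements(merge_elements(elements, sequence))
  if (nrow(elements) > 0L &&
      (any(elements$start < 0L) || any(elements$end > utr_length) ||
       any(elements$start >= elements$end)))
    stop("element coordinates outside the sequence (length ", utr_length,
         ")", call. = FALSE)
  structure(list(utr_id = utr_id, utr_length = as.integer(utr_length),
                 elements = elements),
            class = "UtrArchitecture")
}

#' Build a 3'-UTR element architecture
#'
#' Sorts, merges and relabels a set of scanned elements into a
#' `UtrArchitecture`: the object the rule engine consumes. Idempotent.
#'
#' @param record The [utr_record()] the elements were scanned from.
#' @param elements Elements as returned by [scan_motifs()].
#' @return A `UtrArchitecture`: list with `utr_id`, `utr_length` and the
#'   sorted `elements` data.frame.
#' @export
build_architecture <- function(record, elements) {
  stopifnot(inherits(record, "UtrRecord"))
  len <- nchar(record$sequence)
  if (nrow(elements) > 0L &&
      (any(elements$start < 0L) || any(elements$end > len)))
    stop("element coordinates outside sequence '", record$id, "' (length ",
         len, ")", call. = FALSE)
  arch <- new_architecture(record$id, len, elements, record$sequence)
  bad <- if (nrow(arch$elements) == 0L) logical(0) else
    arch$elements$matched_seq !=
      substring(record$sequence, arch$elements$start + 1L,
                arch$elements$end)
  if (any(bad))
    stop("matched_seq does not agree with the sequence for ",
         paste(arch$elements$label[bad], collapse = ", "), call. = FALSE)
  arch
}

#' @export
print.UtrArchitecture <- function(x, ...) {
  cat(sprintf("UtrArchitecture '%s' (%d nt): %d element(s)\n",
              x$utr_id, x$utr_length, nrow(x$elements)))
  if (nrow(x$elements) > 0L)
    print(x$elements[, c("label", "element_class", "start", "end",
                         "matched_seq")], row.names = FALSE)
  invisible(x)
}

# Resolve an element by label (e.g. "PAS2"); errors if absent.
get_element <- function(arch, label, element_class = NULL) {
  el <- arch$elements
  idx <- which(el$label == label)
  if (!is.null(element_class))
    idx <- idx[el$element_class[idx] == element_class]
  if (length(idx) != 1L)
    stop("element '", label, "'",
         if (!is.null(element_class)) paste0(" of class ", element_class),
         " not found in architecture '", arch$utr_id, "'", call. = FALSE)
  el[idx, , drop = FALSE]
}
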