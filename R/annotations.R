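# BED / GFF3 export and import of element architectures.
#
# BED is 0-based half-open; GFF3 is 1-based inclusive. The element class
# goes into the GFF3 type column (BED recovers it from the label prefix);
# the label goes into the BED name column / GFF3 Name attribute.

arch_to_granges <- function(arch) {
  el <- arch$elements
  gr <- GenomicRanges::GRanges(
    seqnames = arch$utr_id,
    ranges = IRanges::IRanges(start = el$start + 1L, end = el$end),
    seqlengths = setNames(arch$utr_length, arch$utr_id))
  S4Vectors::mcols(gr)$name <- el$label
  S4Vectors::mcols(gr)$type <- el$element_class
  S4Vectors::mcols(gr)$matched_seq <- el$matched_seq
  gr
}

#' Write an architecture to BED or GFF3
#'
#' @param arch A `UtrArchitecture`.
#' @param path Output file path.
#' @param format `"BED"` (0-based half-open starts) or `"GFF3"` (1-based
#'   inclusive).
#' @return `path`, invisibly.
#' @export
write_annotations <- function(arch, path, format = c("BED", "GFF3")) {
  stopifnot(inherits(arch, "UtrArchitecture"))
  if (is.character(format) && length(format) == 1L)
    format <- toupper(format)
  format <- match.arg(format)
  gr <- arch_to_granges(arch)
  if (format == "BED") {
    S4Vectors::mcols(gr) <-
      S4Vectors::mcols(gr)[, "name", drop = FALSE]
    rtracklayer::export(gr, path, format = "BED")
  } else {
    S4Vectors::mcols(gr)$source <- "utrcode"
    S4Vectors::mcols(gr)$ID <- S4Vectors::mcols(gr)$name
    S4Vectors::mcols(gr)$Name <- S4Vectors::mcols(gr)$name
    S4Vectors::mcols(gr) <-
      S4Vectors::mcols(gr)[, c("source", "type", "ID", "Name",
                               "matched_seq")]
    rtracklayer::export(gr, path, format = "GFF3")
    # carry the UTR length in the standard directive so the round trip
    # restores it (rtracklayer neither writes nor parses it)
    lines <- readLines(path)
    writeLines(append(lines,
                      sprintf("##sequence-region %s 1 %d", arch$utr_id,
                              arch$utr_length),
                      after = 1L), path)
  }
  invisible(path)
}

#' Read an architecture from BED or GFF3
#'
#' Inverse of [write_annotations()]. BED stores no sequence length, so
#' `utr_length` (or the source `record`) must be supplied for an exact
#' round trip; GFF3 carries it in the `##sequence-region` directive.
#' `matched_seq` is restored from the GFF3 attribute or, when `record` is
#' given, from the sequence.
#'
#' @param path Annotation file.
#' @param format `"BED"` or `"GFF3"`.
#' @param utr_length Sequence length in nt (BED; defaults to the largest
#'   element end).
#' @param record Optional [utr_record()] to restore `matched_seq` and the
#'   length from.
#' @return A `UtrArchitecture`.
#' @export
read_annotations <- function(path, format = c("BED", "GFF3"),
                             utr_length = NULL, record = NULL) {
  if (is.character(format) && length(format) == 1L)
    format <- toupper(format)
  format <- match.arg(format)
  gr <- rtracklayer::import(path, format = if (format == "BED") "BED" else "GFF3")
  if (length(gr) == 0L && is.null(utr_length) && is.null(record))
    stop("empty annotation file and no utr_length given: ", path,
         call. = FALSE)
  md <- S4Vectors::mcols(gr)
  if (format == "BED") {
    label <- md$name
    cls <- sub("^(PAS|CPE|PBE).*$", "\\1", label)
    mseq <- rep(NA_character_, length(gr))
  } else {
    label <- if ("Name" %in% names(md)) md$Name else md$ID
    cls <- as.character(md$type)
    mseq <- if ("matched_seq" %in% names(md)) as.character(md$matched_seq)
            else rep(NA_character_, length(gr))
  }
  if (length(gr) > 0L && !all(cls %in% c("PAS", "CPE", "PBE")))
    stop("cannot determine element classes from ", path, call. = FALSE)
  utr_id <- if (length(gr) > 0L) as.character(GenomicRanges::seqnames(gr))[1]
            else record$id %||% "UTR"
  len <- utr_length %||%
    (if (!is.null(record)) nchar(record$sequence)
     else {
       sr <- if (format == "GFF3")
         grep("^##sequence-region", readLines(path, n = 20L),
              value = TRUE) else character(0)
       if (length(sr) >= 1L)
         as.integer(strsplit(sr[1], "\\s+")[[1]][4])
       else if (length(gr) > 0L) max(IRanges::end(gr)) else 0L
     })
  elements <- data.frame(
    element_class = cls,
    start = IRanges::start(gr) - 1L,
    end = IRanges::end(gr),
    matched_seq = mseq,
    label = label,
    stringsAsFactors = FALSE)
  arch <- new_architecture(utr_id, len, elements)
  if (!is.null(record))
    arch$elements$matched_seq <- substring(record$sequence,
                                           arch$elements$start + 1L,
                                           arch$elements$end)
  else if (any(!is.na(mseq)))
    arch$elements$matched_seq <-
      mseq[order(elements$start, elements$end, elements$element_class)]
  arch
}
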