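# 3'-UTR sequence records. Sequences are held internally in the DNA
# alphabet on the mRNA sense strand; RNA input (U) is normalized on read.

#' Create a 3'-UTR sequence record
#'
#' @param id Sequence identifier.
#' @param sequence Nucleotide string (DNA or RNA alphabet; lowercase
#'   accepted). Stored uppercased with U converted to T.
#' @param source_alphabet `"DNA"` or `"RNA"`. Autodetected (presence of U)
#'   when `NULL`.
#' @return An object of class `UtrRecord`: a list with fields `id`,
#'   `sequence` and `source_alphabet`.
#' @export
utr_record <- function(id, sequence, source_alphabet = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(sequence), length(sequence) == 1L)
  raw <- toupper(sequence)
  if (nchar(raw) == 0L)
    stop("record '", id, "': empty sequence", call. = FALSE)
  if (is.null(source_alphabet))
    source_alphabet <- if (grepl("U", raw, fixed = TRUE)) "RNA" else "DNA"
  source_alphabet <- match.arg(source_alphabet, c("DNA", "RNA"))
  norm <- chartr("U", "T", raw)
  bad <- regexpr("[^ACGTN]", norm)
  if (bad > 0L)
    stop("record '", id, "': invalid character '",
         substr(raw, bad, bad), "' at offset ", bad, call. = FALSE)
  structure(list(id = id, sequence = norm,
                 source_alphabet = source_alphabet),
            class = "UtrRecord")
}

#' @export
print.UtrRecord <- function(x, ...) {
  cat(sprintf("UtrRecord '%s': %d nt (%s input)\n",
              x$id, nchar(x$sequence), x$source_alphabet))
  invisible(x)
}

#' Read 3'-UTR sequences from a FASTA file
#'
#' Accepts DNA or RNA alphabets; U is normalized to T and lowercase is
#' uppercased. The source alphabet of each entry is recorded.
#'
#' @param path Path to a FASTA file.
#' @return A list of [utr_record()] objects, in file order.
#' @export
read_utr_fasta <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("no records in ", path, " (",
                                           conditionMessage(e), ")",
                                           call. = FALSE))
  if (length(set) == 0L)
    stop("no records in ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  lapply(seq_along(set), function(i) {
    utr_record(ids[i], as.character(set[[i]]))
  })
}

#' Write 3'-UTR records to FASTA
#'
#' @param records A list of [utr_record()] objects (or a single record).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_utr_fasta <- function(records, path) {
  if (inherits(records, "UtrRecord")) records <- list(records)
  seqs <- Biostrings::DNAStringSet(
    setNames(vapply(records, function(r) r$sequence, character(1)),
             vapply(records, function(r) r$id, character(1))))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
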