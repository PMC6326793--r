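# In-silico reporter mutagenesis: rebuild every reporter construct of the
# validation set (and arbitrary user constructs) by editing sequences and
# rescanning. All edits are deterministic, length-accounted, and verified
# by a rescan diff: untouched elements must survive with their gaps.

#' Scan a record into an editable construct
#'
#' Bundles a sequence record with its scanned architecture and the motif
#' set used, the unit all edit operations work on.
#'
#' @param record A [utr_record()].
#' @param patterns Motif set used for scanning and rescanning.
#' @return A `UtrConstruct`: list with `record`, `arch`, `patterns`, `log`.
#' @export
scan_utr <- function(record, patterns = default_patterns()) {
  stopifnot(inherits(record, "UtrRecord"))
  arch <- build_architecture(record, scan_motifs(record, patterns))
  structure(list(record = record, arch = arch, patterns = patterns,
                 log = character(0)),
            class = "UtrConstruct")
}

#' @export
print.UtrConstruct <- function(x, ...) {
  cat(sprintf("UtrConstruct '%s' (%d nt, %d edit(s))\n", x$record$id,
              nchar(x$record$sequence), length(x$log)))
  if (length(x$log) > 0L) cat(paste0("  - ", x$log, collapse = "\n"), "\n")
  print(x$arch)
  invisible(x)
}

rescan_construct <- function(x) {
  x$arch <- build_architecture(x$record, scan_motifs(x$record, x$patterns))
  x
}

replace_sub <- function(seq, start0, end0, replacement) {
  paste0(substr(seq, 1L, start0), replacement,
         substr(seq, end0 + 1L, nchar(seq)))
}

# Rescan-diff check: all elements except those overlapping the edited
# window(s) must be preserved exactly (after applying a coordinate shift
# downstream of `shift_from`).
check_untouched <- function(before, after, windows, shift = 0L,
                            shift_from = 0L) {
  shifted <- before
  if (shift != 0L) {
    idx <- shifted$start >= shift_from
    shifted$start[idx] <- shifted$start[idx] + shift
    shifted$end[idx] <- shifted$end[idx] + shift
  }
  touched <- function(df) {
    hit <- rep(FALSE, nrow(df))
    for (w in windows)
      hit <- hit | (df$start < w[2] & df$end > w[1])
    hit
  }
  keep_b <- shifted[!touched(shifted), c("element_class", "start", "end")]
  keep_a <- after[!touched(after), c("element_class", "start", "end")]
  rownames(keep_b) <- rownames(keep_a) <- NULL
  isTRUE(all.equal(keep_b, keep_a))
}

# Length-preserving motif-killing substitution: T -> G at the three
# central positions; if a motif survives rescanning, fall back to a fixed
# full scramble (T->G, A->C).
kill_motif <- function(sub) {
  n <- nchar(sub)
  mid <- floor((n - 3L) / 2L) + 1L
  chars <- strsplit(sub, "")[[1]]
  idx <- mid:(mid + 2L)
  chars[idx] <- ifelse(chars[idx] == "T", "G", chars[idx])
  paste(chars, collapse = "")
}

kill_motif_fallback <- function(sub) chartr("TA", "GC", sub)

mutate_element <- function(x, label, element_class, replacement_fun) {
  stopifnot(inherits(x, "UtrConstruct"))
  el <- get_element(x$arch, label, element_class)
  before <- x$arch$elements
  site <- c(el$start, el$end)
  for (fun in replacement_fun) {
    repl <- fun(el$matched_seq)
    stopifnot(nchar(repl) == nchar(el$matched_seq))
    cand <- x
    cand$record$sequence <- replace_sub(x$record$sequence, el$start,
                                        el$end, repl)
    cand <- rescan_construct(cand)
    still <- cand$arch$elements
    hit <- still$element_class == element_class &
      still$start < el$end & still$end > el$start
    if (!any(hit)) {
      if (!check_untouched(before[before$label != label, , drop = FALSE],
                           still, list(site)))
        stop("mutating '", label, "' disturbed other elements",
             call. = FALSE)
      cand$log <- c(x$log, sprintf("%s %s [%d,%d) %s -> %s",
                                   switch(element_class, PAS = "mutate_pas",
                                          CPE = "mutate_cpe",
                                          PBE = "delete_pbe"),
                                   label, el$start, el$end,
                                   el$matched_seq, repl))
      return(cand)
    }
  }
  stop("could not find a motif-free substitution for '", label, "'",
       call. = FALSE)
}

#' Mutate a polyadenylation signal
#'
#' Replaces the PAS hexamer in place (AATAAA -> AAGGAA; length preserved)
#' and rescans; the edited site is verified to match no active pattern.
#'
#' @param x A `UtrConstruct` from [scan_utr()].
#' @param label PAS label in the current architecture (e.g. `"PAS3"`).
#'   Remaining elements are relabelled 5'->3' after the rescan.
#' @return The edited `UtrConstruct`.
#' @export
mutate_pas <- function(x, label) {
  pas_sub <- function(sub) {
    out <- gsub("AATAAA", "AAGGAA", sub, fixed = TRUE)
    if (identical(out, sub))
      out <- gsub("ATTAAA", "ATGGAA", sub, fixed = TRUE)
    if (identical(out, sub)) out <- kill_motif(sub)
    out
  }
  mutate_element(x, label, "PAS", list(pas_sub, kill_motif_fallback))
}

#' Mutate a cytoplasmic polyadenylation element
#'
#' Replaces the CPE with an equal-length non-motif substitution (T -> G at
#' the three central positions, verified motif-free by rescan, with a
#' fixed scramble fallback).
#'
#' @inheritParams mutate_pas
#' @param label CPE label in the current architecture.
#' @return The edited `UtrConstruct`.
#' @export
mutate_cpe <- function(x, label) {
  mutate_element(x, label, "CPE", list(kill_motif, kill_motif_fallback))
}

#' Remove a Pumilio-binding element
#'
#' Kills the PBE motif by a length-preserving substitution (coordinates of
#' all other elements are untouched, which keeps gap bookkeeping simple;
#' PBEs are annotate-only, so this has no effect on predictions by
#' default).
#'
#' @inheritParams mutate_pas
#' @param label PBE label in the current architecture.
#' @return The edited `UtrConstruct`.
#' @export
delete_pbe <- function(x, label) {
  mutate_element(x, label, "PBE", list(kill_motif, kill_motif_fallback))
}

#' Shorten the spacer between two elements
#'
#' Removes nucleotides symmetrically around the spacer midpoint so that
#' exactly `remaining_gap` nt separate the two motifs; both motifs stay
#' intact and downstream coordinates shift accordingly. A rescan verifies
#' that no motif was gained or lost.
#'
#' @inheritParams mutate_pas
#' @param upstream_label,downstream_label Labels of the two elements
#'   (order is normalized internally).
#' @param remaining_gap Spacer length to leave, nt; must be smaller than
#'   the current gap.
#' @return The edited `UtrConstruct`.
#' @export
delete_spacer <- function(x, upstream_label, downstream_label,
                          remaining_gap) {
  stopifnot(inherits(x, "UtrConstruct"), remaining_gap >= 0)
  a <- get_element(x$arch, upstream_label)
  b <- get_element(x$arch, downstream_label)
  if (a$start > b$start) { tmp <- a; a <- b; b <- tmp }
  gap <- gap_distance(a, b)
  if (remaining_gap >= gap)
    stop("remaining_gap (", remaining_gap, ") must be smaller than the ",
         "current gap (", gap, ")", call. = FALSE)
  remove <- as.integer(gap - remaining_gap)
  # Preferred cut: symmetric around the spacer midpoint. If the junction
  # happens to create or destroy a motif, slide the cut window outward by
  # a deterministic offset search until the rescan diff is clean.
  left_keep <- floor(remaining_gap / 2)
  offsets <- c(0L, as.vector(rbind(seq_len(gap), -seq_len(gap))))
  out <- NULL
  for (off in offsets) {
    cut_start <- a$end + left_keep + off   # 0-based
    if (cut_start < a$end || cut_start + remove > b$start) next
    cand <- x
    cand$record$sequence <- replace_sub(x$record$sequence, cut_start,
                                        cut_start + remove, "")
    cand <- rescan_construct(cand)
    ok <- nrow(cand$arch$elements) == nrow(x$arch$elements) &&
      check_untouched(x$arch$elements, cand$arch$elements,
                      list(c(cut_start, cut_start)),
                      shift = -remove, shift_from = cut_start + remove)
    if (ok) { out <- cand; break }
  }
  if (is.null(out))
    stop("spacer deletion between '", upstream_label, "' and '",
         downstream_label, "' gained or lost a motif", call. = FALSE)
  out$log <- c(x$log, sprintf("delete_spacer %s..%s gap %d -> %d",
                              a$label, b$label, gap,
                              as.integer(remaining_gap)))
  out
}

#' Insert a CPE downstream of a PAS
#'
#' Inserts a canonical CPE heptamer (`TTTTAAT` by default) so that its
#' gap to the PAS equals `gap`; the UTR grows by the motif length and a
#' rescan must show exactly one new CPE.
#'
#' @inheritParams mutate_pas
#' @param pas_label PAS the insertion is positioned relative to.
#' @param gap Spacer between the PAS and the inserted CPE, nt.
#' @param motif CPE sequence to insert.
#' @return The edited `UtrConstruct`.
#' @export
insert_cpe <- function(x, pas_label, gap, motif = "TTTTAAT") {
  stopifnot(inherits(x, "UtrConstruct"), gap >= 0)
  pas <- get_element(x$arch, pas_label, "PAS")
  pos <- pas$end + as.integer(gap)          # 0-based insertion point
  w <- nchar(motif)
  if (pos > nchar(x$record$sequence))
    stop("insertion site lies outside the UTR", call. = FALSE)
  el <- x$arch$elements
  if (any(el$start < pos & el$end > pos))  # insertion splits an element
    stop("insertion at gap ", gap, " would overlap an existing element",
         call. = FALSE)
  out <- x
  out$record$sequence <- replace_sub(x$record$sequence, pos, pos, motif)
  out <- rescan_construct(out)
  # If a junction base extends the inserted motif (e.g. a background T in
  # front of the heptamer), the merged match would misplace the element
  # edge and shrink the requested gap; repair such flanking background
  # bases to C, deterministically.
  for (i in 1:10) {
    merged <- out$arch$elements
    merged <- merged[merged$element_class == "CPE" &
                     merged$start < pos + w & merged$end > pos, ,
                     drop = FALSE]
    if (nrow(merged) == 0L) break
    if (nrow(merged) == 1L && merged$start == pos &&
        merged$end == pos + w) break
    flank <- setdiff(seq.int(min(merged$start, pos) + 1L,
                             max(merged$end, pos + w)),
                     seq.int(pos + 1L, pos + w))
    if (length(flank) == 0L) break
    for (p in flank) substr(out$record$sequence, p, p) <- "C"
    out <- rescan_construct(out)
  }
  new_cpe <- out$arch$elements
  new_cpe <- new_cpe[new_cpe$element_class == "CPE" &
                     new_cpe$start == pos & new_cpe$end == pos + w, ,
                     drop = FALSE]
  n_before <- table(factor(x$arch$elements$element_class,
                           c("PAS", "CPE", "PBE")))
  n_after <- table(factor(out$arch$elements$element_class,
                          c("PAS", "CPE", "PBE")))
  ok <- nrow(new_cpe) == 1L &&
    n_after[["CPE"]] == n_before[["CPE"]] + 1L &&
    n_after[["PAS"]] == n_before[["PAS"]] &&
    n_after[["PBE"]] == n_before[["PBE"]] &&
    check_untouched(x$arch$elements, out$arch$elements,
                    list(c(pos, pos + w)), shift = w, shift_from = pos)
  if (!ok)
    stop("CPE insertion at gap ", gap, " did not yield exactly one new ",
         "CPE with all other elements preserved", call. = FALSE)
  out$log <- c(x$log, sprintf("insert_cpe %s downstream of %s at gap %d",
                              motif, pas_label, as.integer(gap)))
  out
}

#' Truncate a 3'-UTR to its distal fragment
#'
#' Keeps the 3'-most `retained_length` nt, rescans, and re-bases all
#' coordinates to the new fragment.
#'
#' @inheritParams mutate_pas
#' @param retained_length Length of the distal fragment to keep, nt.
#' @return The edited `UtrConstruct`.
#' @export
truncate_distal <- function(x, retained_length) {
  stopifnot(inherits(x, "UtrConstruct"))
  len <- nchar(x$record$sequence)
  if (retained_length <= 0 || retained_length > len)
    stop("retained_length must lie in (0, ", len, "]", call. = FALSE)
  out <- x
  out$record$sequence <- substr(x$record$sequence,
                                len - retained_length + 1L, len)
  out <- rescan_construct(out)
  out$log <- c(x$log, sprintf("truncate_distal to %d nt",
                              as.integer(retained_length)))
  out
}

#' Define a reporter construct
#'
#' @param name Construct identifier (unique within a set).
#' @param base Identifier of the base fixture or record.
#' @param edits Ordered list of edit operations, each created by
#'   [edit_op()].
#' @param note Free-text note (e.g. the assay background).
#' @param figure_ref Figure panel the construct appears in.
#' @return A `ConstructSpec`.
#' @export
construct_spec <- function(name, base, edits = list(), note = "",
                           figure_ref = "") {
  stopifnot(is.character(name), nzchar(name), is.character(base))
  structure(list(name = name, base = base, edits = edits, note = note,
                 figure_ref = figure_ref),
            class = "ConstructSpec")
}

#' Define a single edit operation
#'
#' @param kind One of `MUTATE_PAS`, `MUTATE_CPE`, `DELETE_PBE`,
#'   `DELETE_SPACER`, `INSERT_CPE`, `TRUNCATE_DISTAL`.
#' @param target Element label (or `c(upstream, downstream)` pair for
#'   `DELETE_SPACER`), interpreted against the construct's architecture at
#'   application time.
#' @param param Integer parameter: remaining gap (`DELETE_SPACER`), gap
#'   downstream of the PAS (`INSERT_CPE`), or retained length
#'   (`TRUNCATE_DISTAL`).
#' @return An `EditOp` list.
#' @export
edit_op <- function(kind, target = NULL, param = NULL) {
  kind <- match.arg(kind, c("MUTATE_PAS", "MUTATE_CPE", "DELETE_PBE",
                            "DELETE_SPACER", "INSERT_CPE",
                            "TRUNCATE_DISTAL"))
  structure(list(kind = kind, target = target, param = param),
            class = "EditOp")
}

apply_edit <- function(x, op) {
  switch(op$kind,
         MUTATE_PAS = mutate_pas(x, op$target),
         MUTATE_CPE = mutate_cpe(x, op$target),
         DELETE_PBE = delete_pbe(x, op$target),
         DELETE_SPACER = delete_spacer(x, op$target[1], op$target[2],
                                       op$param),
         INSERT_CPE = insert_cpe(x, op$target, op$param),
         TRUNCATE_DISTAL = truncate_distal(x, op$param))
}

#' Apply a construct specification to its base fixture
#'
#' Applies the edits in order (labels are resolved against the current,
#' rescanned architecture at each step), records an edit log, and returns
#' the edited construct. Deterministic.
#'
#' @param spec A [construct_spec()].
#' @param fixtures A named list of base fixtures; each entry must contain
#'   a `record` (as returned by [paper_fixtures()]), or be a
#'   [utr_record()] itself.
#' @param patterns Motif set.
#' @return The edited `UtrConstruct`.
#' @export
apply_construct <- function(spec, fixtures = paper_fixtures(),
                            patterns = default_patterns()) {
  stopifnot(inherits(spec, "ConstructSpec"))
  base <- fixtures[[spec$base]]
  if (is.null(base))
    stop("base fixture '", spec$base, "' not found", call. = FALSE)
  rec <- if (inherits(base, "UtrRecord")) base else base$record
  x <- scan_utr(rec, patterns)
  for (i in seq_along(spec$edits)) {
    op <- spec$edits[[i]]
    x <- tryCatch(apply_edit(x, op),
                  error = function(e)
                    stop("construct '", spec$name, "': edit ", i, " (",
                         op$kind, " ",
                         paste(op$target, collapse = ".."), ") failed: ",
                         conditionMessage(e), call. = FALSE))
  }
  x$name <- spec$name
  x
}

#' The packaged reporter-construct set
#'
#' All reporter constructs of the validation set, expressed as ordered
#' edits on the three packaged fixtures. Multi-element mutations are
#' applied distal-first so that labels of not-yet-edited elements are
#' stable. Spacer-deletion and CPE-insertion constructs are built in the
#' proximal-PAS-only (dPAS2/3) background, and the Fig 4 CPE series in the
#' middle-PAS-only (dPAS1/3) background, matching the assays they
#' reproduce.
#'
#' @return A named list of [construct_spec()] objects (n >= 28).
#' @export
enumerate_paper_constructs <- function() {
  mp <- function(l) edit_op("MUTATE_PAS", l)
  mc <- function(l) edit_op("MUTATE_CPE", l)
  specs <- list(
    ## -- Cpeb1 ---------------------------------------------------------
    construct_spec("Cpeb1-WT", "Cpeb1", list(), figure_ref = "Fig 1C-E"),
    construct_spec("Cpeb1-dPAS3", "Cpeb1", list(mp("PAS3")),
                   figure_ref = "Fig 1C-E"),
    construct_spec("Cpeb1-dPAS1", "Cpeb1", list(mp("PAS1")),
                   figure_ref = "Fig 1C-E"),
    construct_spec("Cpeb1-dPAS2", "Cpeb1", list(mp("PAS2")),
                   figure_ref = "Fig 1C-E"),
    construct_spec("Cpeb1-dPAS2/3", "Cpeb1", list(mp("PAS3"), mp("PAS2")),
                   figure_ref = "Fig 1F-H"),
    construct_spec("Cpeb1-dPAS1/2", "Cpeb1", list(mp("PAS2"), mp("PAS1")),
                   figure_ref = "Fig 1F-H"),
    construct_spec("Cpeb1-dPAS1/3", "Cpeb1", list(mp("PAS3"), mp("PAS1")),
                   figure_ref = "Fig 1F-H"),
    construct_spec("Cpeb1-dPAS1/2/3", "Cpeb1",
                   list(mp("PAS3"), mp("PAS2"), mp("PAS1")),
                   figure_ref = "Fig 1F-H"),
    construct_spec("Cpeb1-dCPE1-4", "Cpeb1",
                   list(mc("CPE4"), mc("CPE3"), mc("CPE2"), mc("CPE1")),
                   figure_ref = "Fig 3A-B"),
    construct_spec("Cpeb1-dPAS1/3+dCPE1-4", "Cpeb1",
                   list(mp("PAS3"), mp("PAS1"),
                        mc("CPE4"), mc("CPE3"), mc("CPE2"), mc("CPE1")),
                   note = "middle-PAS-only background",
                   figure_ref = "Fig 3C-D"),
    construct_spec("Cpeb1-dPAS1/3+dCPE1/2", "Cpeb1",
                   list(mp("PAS3"), mp("PAS1"), mc("CPE2"), mc("CPE1")),
                   note = "middle-PAS-only background; same-side CPE pair",
                   figure_ref = "Fig 4A-B"),
    construct_spec("Cpeb1-dPAS1/3+dCPE2/4", "Cpeb1",
                   list(mp("PAS3"), mp("PAS1"), mc("CPE4"), mc("CPE2")),
                   note = "middle-PAS-only background; flanking CPE pair",
                   figure_ref = "Fig 4A-B"),
    construct_spec("Cpeb1-dPAS2/3+dCPE1-4", "Cpeb1",
                   list(mp("PAS3"), mp("PAS2"),
                        mc("CPE4"), mc("CPE3"), mc("CPE2"), mc("CPE1")),
                   note = "proximal-PAS-only background",
                   figure_ref = "Fig 4C-D"),
    construct_spec("Cpeb1-spacer-50", "Cpeb1",
                   list(mp("PAS3"), mp("PAS2"),
                        edit_op("DELETE_SPACER", c("PAS1", "CPE1"), 50L)),
                   note = "proximal-PAS-only background",
                   figure_ref = "Fig 4E-F"),
    construct_spec("Cpeb1-spacer-35", "Cpeb1",
                   list(mp("PAS3"), mp("PAS2"),
                        edit_op("DELETE_SPACER", c("PAS1", "CPE1"), 35L)),
                   note = "proximal-PAS-only background",
                   figure_ref = "Fig 4E-F"),
    construct_spec("Cpeb1-spacer-15", "Cpeb1",
                   list(mp("PAS3"), mp("PAS2"),
                        edit_op("DELETE_SPACER", c("PAS1", "CPE1"), 15L)),
                   note = "proximal-PAS-only background",
                   figure_ref = "Fig 4E-F"),
    construct_spec("Cpeb1-insert-CPE-35", "Cpeb1",
                   list(mp("PAS3"), mp("PAS2"),
                        edit_op("INSERT_CPE", "PAS1", 35L)),
                   note = "proximal-PAS-only background",
                   figure_ref = "Supplementary (Fig 4 series)"),
    construct_spec("Cpeb1-insert-CPE-50", "Cpeb1",
                   list(mp("PAS3"), mp("PAS2"),
                        edit_op("INSERT_CPE", "PAS1", 50L)),
                   note = "proximal-PAS-only background",
                   figure_ref = "Supplementary (Fig 4 series)"),
    construct_spec("Cpeb1-dPBE", "Cpeb1",
                   list(edit_op("DELETE_PBE", "PBE1")),
                   figure_ref = "Supplementary (Fig 4 series)"),
    ## -- Btg4 ----------------------------------------------------------
    construct_spec("Btg4-WT", "Btg4", list(), figure_ref = "Fig 5B-C"),
    construct_spec("Btg4-dCPE1", "Btg4", list(mc("CPE1")),
                   figure_ref = "Fig 5F-G"),
    construct_spec("Btg4-dCPE2", "Btg4", list(mc("CPE2")),
                   figure_ref = "Fig 5F-G"),
    construct_spec("Btg4-dCPE3", "Btg4", list(mc("CPE3")),
                   figure_ref = "Fig 5F-G"),
    construct_spec("Btg4-dCPE1/3", "Btg4", list(mc("CPE3"), mc("CPE1")),
                   figure_ref = "Fig 5F-G"),
    construct_spec("Btg4-dCPE1/2", "Btg4", list(mc("CPE2"), mc("CPE1")),
                   figure_ref = "Fig 5F-G"),
    construct_spec("Btg4-dCPE1/2/3", "Btg4",
                   list(mc("CPE3"), mc("CPE2"), mc("CPE1")),
                   figure_ref = "Fig 5B-C"),
    ## -- Cnot6l --------------------------------------------------------
    construct_spec("Cnot6l-WT", "Cnot6l", list(),
                   figure_ref = "Fig 6B-C"),
    construct_spec("Cnot6l-dPAS1", "Cnot6l", list(mp("PAS1")),
                   figure_ref = "Fig 6B-C; Fig 6H-I"),
    construct_spec("Cnot6l-dPAS2", "Cnot6l", list(mp("PAS2")),
                   figure_ref = "Fig 6B-C"),
    construct_spec("Cnot6l-dPAS1+dCPE4", "Cnot6l",
                   list(mc("CPE4"), mp("PAS1")),
                   figure_ref = "Fig 6F-G"),
    construct_spec("Cnot6l-dPAS1+dCPE2/3", "Cnot6l",
                   list(mc("CPE3"), mc("CPE2"), mp("PAS1")),
                   figure_ref = "Fig 6F-G"),
    construct_spec("Cnot6l-trunc-402", "Cnot6l",
                   list(edit_op("TRUNCATE_DISTAL", param = 402L)),
                   note = "distal fragment used by the earlier reporter study",
                   figure_ref = "Fig 6A (402-bp fragment)")
  )
  names(specs) <- vapply(specs, function(s) s$name, character(1))
  if (anyDuplicated(names(specs)))
    stop("duplicated construct names", call. = FALSE)
  specs
}
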