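# Seeded generation of motif-controlled synthetic 3'-UTRs, and the three
# packaged reference architectures. Backgrounds are guaranteed motif-free
# under the active pattern set, so rescanning a planted architecture
# recovers exactly the planted elements.

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

scan_string <- function(sequence, patterns) {
  scan_motifs(utr_record("tmp", sequence), patterns)
}

# Deterministic repair: set the middle base of each offending match to C
# (kills the AT-rich PAS/CPE motifs and the PBE alike).
repair_motif_free <- function(sequence, patterns, protect = NULL,
                              max_iter = 100L) {
  for (i in seq_len(max_iter)) {
    hits <- scan_string(sequence, patterns)
    if (!is.null(protect)) {
      keep <- !vapply(seq_len(nrow(hits)), function(j) {
        any(protect$start == hits$start[j] & protect$end == hits$end[j] &
              protect$element_class == hits$element_class[j])
      }, logical(1))
      hits <- hits[keep, , drop = FALSE]
    }
    if (nrow(hits) == 0L) return(sequence)
    for (j in seq_len(nrow(hits))) {
      cand <- seq.int(hits$start[j] + 1L, hits$end[j])  # 1-based positions
      if (!is.null(protect) && nrow(protect) > 0L) {
        inside <- vapply(cand, function(p) {
          any(p > protect$start & p <= protect$end)
        }, logical(1))
        cand <- cand[!inside]
      }
      if (length(cand) == 0L) next
      p <- cand[ceiling(length(cand) / 2)]
      substr(sequence, p, p) <- "C"
    }
  }
  stop("could not generate a motif-free sequence within ", max_iter,
       " repair iterations", call. = FALSE)
}

#' Generate a motif-free random background sequence
#'
#' Pseudo-random nucleotide sequence with a target GC content,
#' reproducible under `seed`, containing zero matches to the active motif
#' set (offending windows are deterministically repaired).
#'
#' @param length Sequence length, nt (> 0).
#' @param gc Target GC fraction in (0, 1); realized GC is within a few
#'   percentage points for lengths of a few hundred nt and up.
#' @param seed Integer seed (mandatory: all randomness in the package is
#'   explicitly seeded).
#' @param patterns Motif set the background must be free of.
#' @return A nucleotide string.
#' @export
random_background <- function(length, gc = 0.4, seed,
                              patterns = default_patterns()) {
  stopifnot(length > 0, gc > 0, gc < 1)
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  seq <- with_seed(seed, paste(
    sample(c("A", "C", "G", "T"), length, replace = TRUE,
           prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
    collapse = ""))
  repair_motif_free(seq, patterns)
}

#' Specify a synthetic 3'-UTR architecture
#'
#' @param utr_length Total UTR length, nt.
#' @param placements `data.frame` with columns `element_class`
#'   (`PAS`/`CPE`/`PBE`), `motif` (the literal sequence to plant) and
#'   `start` (0-based position); an optional `provenance` column marks
#'   which coordinates are printed constraints vs. reconstructed filler.
#' @param background_gc Background GC fraction.
#' @param seed Integer seed for the background (mandatory).
#' @return An `ArchitectureSpec`.
#' @export
architecture_spec <- function(utr_length, placements, background_gc = 0.4,
                              seed) {
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  stopifnot(is.data.frame(placements),
            all(c("element_class", "motif", "start") %in%
                  names(placements)))
  placements$start <- as.integer(placements$start)
  placements$end <- placements$start + nchar(placements$motif)
  if (!"provenance" %in% names(placements))
    placements$provenance <- "reconstructed"
  placements <- placements[order(placements$start), , drop = FALSE]
  rownames(placements) <- NULL
  if (any(placements$start < 0L) || any(placements$end > utr_length))
    stop("placement outside the UTR", call. = FALSE)
  if (nrow(placements) > 1L &&
      any(placements$start[-1] < placements$end[-nrow(placements)]))
    stop("placements overlap", call. = FALSE)
  structure(list(utr_length = as.integer(utr_length),
                 placements = placements,
                 background_gc = background_gc, seed = as.integer(seed)),
            class = "ArchitectureSpec")
}

#' Realize an architecture specification as sequence
#'
#' Writes the specified motifs at their positions over a motif-free
#' random background and verifies that rescanning recovers exactly the
#' planted elements (junctions that create spurious or merged matches are
#' deterministically repaired first).
#'
#' @param spec An [architecture_spec()].
#' @param utr_id Identifier for the generated record.
#' @param patterns Motif set used for verification.
#' @return List with the `record` ([utr_record()]), the scanned
#'   `architecture` and the `expected` element table.
#' @export
plant_architecture <- function(spec, utr_id = "synthetic",
                               patterns = default_patterns()) {
  stopifnot(inherits(spec, "ArchitectureSpec"))
  seqc <- random_background(spec$utr_length, spec$background_gc,
                            spec$seed, patterns)
  pl <- spec$placements
  for (i in seq_len(nrow(pl)))
    substr(seqc, pl$start[i] + 1L, pl$end[i]) <- pl$motif[i]
  expected <- data.frame(element_class = pl$element_class,
                         start = pl$start, end = pl$end,
                         matched_seq = pl$motif, label = NA_character_,
                         stringsAsFactors = FALSE)
  expected <- label_elements(expected)
  seqc <- repair_motif_free(seqc, patterns, protect = expected)
  rec <- utr_record(utr_id, seqc)
  arch <- build_architecture(rec, scan_motifs(rec, patterns))
  got <- arch$elements[, c("element_class", "start", "end", "label")]
  want <- expected[, c("element_class", "start", "end", "label")]
  rownames(got) <- rownames(want) <- NULL
  if (!isTRUE(all.equal(want, got)))
    stop("planted architecture could not be realized exactly",
         call. = FALSE)
  list(record = rec, architecture = arch, expected = expected)
}

fixture_layouts <- function() {
  pas <- "AATAAA"; cpe <- "TTTTAAT"; pbe <- "TGTACATA"
  list(
    # Three PASs; four CPEs flanking the middle PAS (two per side); the
    # proximal and distal PASs sit 386 and 228 nt from the nearest CPE.
    Cpeb1 = architecture_spec(
      utr_length = 811,
      placements = data.frame(
        element_class = c("PAS", "CPE", "CPE", "PAS", "CPE", "CPE",
                          "PBE", "PAS"),
        motif = c(pas, cpe, cpe, pas, cpe, cpe, pbe, pas),
        start = c(30L, 422L, 472L, 499L, 520L, 540L, 647L, 775L),
        provenance = c("reconstructed", "printed:gap-386",
                       "reconstructed", "reconstructed",
                       "reconstructed", "reconstructed",
                       "reconstructed", "printed:gap-228"),
        stringsAsFactors = FALSE),
      seed = 11L),
    # Two PASs close together, flanked by two CPEs upstream and one
    # downstream, each flank 66 nt from the nearer PAS.
    Btg4 = architecture_spec(
      utr_length = 263,
      placements = data.frame(
        element_class = c("CPE", "CPE", "PAS", "PAS", "CPE"),
        motif = c(cpe, cpe, pas, pas, cpe),
        start = c(40L, 57L, 130L, 144L, 216L),
        provenance = c("reconstructed", "printed:gap-66",
                       "reconstructed", "reconstructed",
                       "printed:gap-66"),
        stringsAsFactors = FALSE),
      seed = 12L),
    # 1597 nt; free proximal PAS1 (CPE1 150 nt away), distal PAS2
    # flanked by CPE3 (60 nt upstream) and the closely adjacent CPE4
    # (10 nt downstream); the distal 402 nt hold CPE2-4 and PAS2.
    Cnot6l = architecture_spec(
      utr_length = 1597,
      placements = data.frame(
        element_class = c("PAS", "CPE", "CPE", "CPE", "PAS", "CPE"),
        motif = c(pas, cpe, cpe, cpe, pas, cpe),
        start = c(40L, 196L, 1417L, 1477L, 1544L, 1560L),
        provenance = c("reconstructed", "reconstructed",
                       "printed:within-402", "reconstructed",
                       "reconstructed", "printed:adjacent"),
        stringsAsFactors = FALSE),
      seed = 13L)
  )
}

#' The packaged Cpeb1-, Btg4- and Cnot6l-like fixtures
#'
#' Deterministic synthetic realizations of the three reference 3'-UTR
#' architectures. Every printed constraint holds exactly: Cpeb1-like --
#' 3 PAS / 4 CPE, middle PAS flanked by the four CPEs, proximal and
#' distal PASs 386 and 228 nt from the nearest CPE; Btg4-like -- 2 PAS /
#' 3 CPE, both PASs flanked at 66 nt; Cnot6l-like -- 1597 nt, 2 PAS /
#' 4 CPE, free proximal PAS, distal PAS with a closely adjacent CPE, and
#' a distal 402-nt fragment containing three CPEs and the distal PAS.
#' Coordinates not fixed by those constraints are reconstructed filler,
#' marked in the `provenance` column of each spec's placements.
#'
#' @param patterns Motif set used to realize and verify the fixtures.
#' @return A `FixtureSet`: named list (`Cpeb1`, `Btg4`, `Cnot6l`) of
#'   fixtures (each with `record`, `architecture`, `expected`, `spec`)
#'   plus the observed `truth_table`.
#' @export
paper_fixtures <- function(patterns = default_patterns()) {
  layouts <- fixture_layouts()
  out <- lapply(names(layouts), function(id) {
    f <- plant_architecture(layouts[[id]], utr_id = id,
                            patterns = patterns)
    f$spec <- layouts[[id]]
    f
  })
  names(out) <- names(layouts)
  out$truth_table <- observed_truth_table()
  structure(out, class = "FixtureSet")
}
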