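# Shared fixtures and the independent brute-force scanning oracle.

FIX <- paper_fixtures()
CFG <- code_config()

# Brute-force window-enumeration oracle: pure R, character-by-character
# IUPAC set membership, manual interval union -- independent of the
# Biostrings-based scanner it checks.
IUPAC_ORACLE <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T", "N")
)

brute_scan <- function(sequence, patterns = default_patterns()) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  hits <- list()
  for (i in seq_len(nrow(patterns))) {
    pat <- strsplit(patterns$pattern[i], "")[[1]]
    L <- length(pat)
    if (L > n) next
    ok <- rep(TRUE, n - L + 1L)
    for (j in seq_len(L))
      ok <- ok & chars[j:(n - L + j)] %in% IUPAC_ORACLE[[pat[j]]]
    for (s in which(ok))
      hits[[length(hits) + 1L]] <-
        c(class = patterns$element_class[i], start = s - 1L, end = s + L - 1L)
  }
  if (length(hits) == 0L)
    return(data.frame(element_class = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  df <- data.frame(element_class = vapply(hits, `[[`, "", "class"),
                   start = as.integer(vapply(hits, `[[`, "", "start")),
                   end = as.integer(vapply(hits, `[[`, "", "end")),
                   stringsAsFactors = FALSE)
  # manual sweep-merge of overlapping same-class intervals
  out <- lapply(split(df, df$element_class), function(d) {
    d <- d[order(d$start, d$end), , drop = FALSE]
    ms <- d$start[1]; me <- d$end[1]
    starts <- integer(0); ends <- integer(0)
    for (k in seq_len(nrow(d))[-1]) {
      if (d$start[k] <= me) me <- max(me, d$end[k])
      else { starts <- c(starts, ms); ends <- c(ends, me)
             ms <- d$start[k]; me <- d$end[k] }
    }
    starts <- c(starts, ms); ends <- c(ends, me)
    data.frame(element_class = d$element_class[1], start = starts,
               end = ends, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$start, out$end, out$element_class), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Random test sequence with motifs planted into a random background
# (junction effects intact -- that is the point of the oracle check).
random_motif_sequence <- function(seed, max_len = 2000L) {
  set.seed(seed)
  n <- sample(200:max_len, 1)
  chars <- sample(c("A", "C", "G", "T"), n, replace = TRUE,
                  prob = c(0.3, 0.2, 0.2, 0.3))
  motifs <- c("AATAAA", "TTTTAAT", "TTTTAT", "TTTTTAAT", "TTTTTAT",
              "TGTACATA", "TGTATATA")
  for (m in sample(motifs, sample(0:6, 1), replace = TRUE)) {
    pos <- sample(n - nchar(m), 1)
    chars[pos:(pos + nchar(m) - 1L)] <- strsplit(m, "")[[1]]
  }
  paste(chars, collapse = "")
}

scan_coords <- function(record, patterns = default_patterns()) {
  el <- scan_motifs(record, patterns)
  el <- el[, c("element_class", "start", "end")]
  el <- el[order(el$start, el$end, el$element_class), , drop = FALSE]
  rownames(el) <- NULL
  el
}

# Random architecture spec for property tests: 1-3 PASs, 0-4 CPEs at
# non-overlapping positions.
random_arch_spec <- function(seed, offset = 0L) {
  set.seed(seed)
  len <- sample(400:900, 1)
  n_pas <- sample(1:3, 1)
  n_cpe <- sample(0:4, 1)
  k <- n_pas + n_cpe
  repeat {
    starts <- sort(sample(seq(5L, len - 15L), k))
    if (k < 2L || min(diff(starts)) >= 12L) break
  }
  cls <- sample(c(rep("PAS", n_pas), rep("CPE", n_cpe)))
  architecture_spec(
    utr_length = len + offset,
    placements = data.frame(
      element_class = cls,
      motif = ifelse(cls == "PAS", "AATAAA", "TTTTAAT"),
      start = starts + offset,
      stringsAsFactors = FALSE),
    seed = seed + 1000L)
}
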