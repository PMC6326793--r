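# Scoring engine predictions against the observed reporter-assay
# outcomes, plus the optional external calibration on user-supplied real
# 3'-UTR sequences.

#' The observed reporter-assay truth table
#'
#' One entry per packaged construct: the observed GV-stage call
#' (`ACTIVE` / `PARTIAL` / `SILENT`), the observed direction of change of
#' the construct's own activity after meiotic resumption (`UP` / `DOWN` /
#' `UNCHANGED`, `NA` where the assays did not address it), the figure
#' panel, and a one-line description of the observed outcome.
#'
#' @return A `data.frame` with columns `construct`, `base`,
#'   `observed_gv`, `observed_post_gvbd`, `figure_ref`, `note`.
#' @export
observed_truth_table <- function() {
  path <- system.file("extdata", "observed_truth_table.tsv",
                      package = "utrcode", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = "NA")
  stopifnot(all(c("construct", "base", "observed_gv",
                  "observed_post_gvbd", "figure_ref", "note") %in%
                  names(tab)),
            all(tab$observed_gv %in% c("ACTIVE", "PARTIAL", "SILENT")),
            all(is.na(tab$observed_post_gvbd) |
                  tab$observed_post_gvbd %in%
                    c("UP", "DOWN", "UNCHANGED")),
            all(nzchar(tab$figure_ref)),
            !anyDuplicated(tab$construct))
  tab
}

#' Map a predicted profile to a GV-stage call
#'
#' `SILENT`: zero predicted GV activity. `ACTIVE`: at least one FREE
#' (unrepressed) PAS and activity at or above the threshold. `PARTIAL`:
#' nonzero activity carried only by partially repressed (one-sided)
#' PASs. This structural mapping mirrors the assay vocabulary: a free PAS
#' gives clear translation, a one-sided CPE gives impaired/partial
#' translation, flanked-only PASs give none.
#'
#' @param profile A `TranslationProfile` from [predict_profile()].
#' @param cfg The [code_config()] used for the prediction.
#' @return `"ACTIVE"`, `"PARTIAL"` or `"SILENT"`.
#' @export
map_gv_call <- function(profile, cfg = code_config()) {
  stopifnot(inherits(profile, "TranslationProfile"))
  eps <- 1e-9
  if (profile$gv_activity < eps) return("SILENT")
  if (any(profile$per_pas$call == "FREE") &&
      profile$gv_activity >= cfg$active_threshold - eps) return("ACTIVE")
  "PARTIAL"
}

predicted_direction <- function(profile, eps = 1e-9) {
  d <- profile$post_gvbd_activity - profile$gv_activity
  if (d > eps) "UP" else if (d < -eps) "DOWN" else "UNCHANGED"
}

#' Score the packaged construct set against the observed outcomes
#'
#' Applies every construct, predicts its profile (normalized to the
#' wild-type architecture of its base UTR), maps the prediction to the
#' observed vocabulary and reports concordance. GV-stage calls are scored
#' for all constructs; post-GVBD direction only where an observed
#' direction is recorded.
#'
#' @param cfg A [code_config()].
#' @param constructs Construct set, see [enumerate_paper_constructs()].
#' @param fixtures Fixture set, see [paper_fixtures()].
#' @param patterns Motif set.
#' @param truth Observed truth table, see [observed_truth_table()].
#' @return A `ConcordanceReport`: list with `n_constructs`,
#'   `n_concordant`, `gv_concordance`, `n_mii_scored`, `n_mii_concordant`,
#'   the per-construct `table` and the `mismatches` subset (each row
#'   citing its figure anchor).
#' @export
evaluate_constructs <- function(cfg = code_config(),
                                constructs = enumerate_paper_constructs(),
                                fixtures = paper_fixtures(),
                                patterns = default_patterns(),
                                truth = observed_truth_table()) {
  if (length(constructs) == 0L) {
    warning("empty construct list; nothing to evaluate", call. = FALSE)
    return(structure(list(n_constructs = 0L, n_concordant = 0L,
                          gv_concordance = NaN, n_mii_scored = 0L,
                          n_mii_concordant = 0L,
                          table = data.frame(), mismatches = data.frame()),
                     class = "ConcordanceReport"))
  }
  rows <- lapply(constructs, function(spec) {
    obs <- truth[truth$construct == spec$name, , drop = FALSE]
    if (nrow(obs) != 1L)
      stop("construct '", spec$name,
           "' is missing from the truth table", call. = FALSE)
    x <- apply_construct(spec, fixtures, patterns)
    ref <- fixtures[[spec$base]]$architecture
    prof <- suppressWarnings(predict_profile(x$arch, cfg,
                                             reference = ref))
    data.frame(
      construct = spec$name, base = spec$base,
      figure_ref = obs$figure_ref,
      gv_activity = prof$gv_activity,
      post_gvbd_activity = prof$post_gvbd_activity,
      fate = prof$fate,
      predicted_gv = map_gv_call(prof, cfg),
      observed_gv = obs$observed_gv,
      predicted_post_gvbd = predicted_direction(prof),
      observed_post_gvbd = obs$observed_post_gvbd,
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab$gv_concordant <- tab$predicted_gv == tab$observed_gv
  tab$mii_concordant <- ifelse(is.na(tab$observed_post_gvbd), NA,
                               tab$predicted_post_gvbd ==
                                 tab$observed_post_gvbd)
  mism <- tab[!tab$gv_concordant |
                (!is.na(tab$mii_concordant) & !tab$mii_concordant), ,
              drop = FALSE]
  structure(list(
    n_constructs = nrow(tab),
    n_concordant = sum(tab$gv_concordant),
    gv_concordance = mean(tab$gv_concordant),
    n_mii_scored = sum(!is.na(tab$mii_concordant)),
    n_mii_concordant = sum(tab$mii_concordant, na.rm = TRUE),
    table = tab, mismatches = mism),
    class = "ConcordanceReport")
}

#' @export
print.ConcordanceReport <- function(x, ...) {
  cat(sprintf(paste0("ConcordanceReport: GV calls %d/%d concordant ",
                     "(%.1f%%); post-GVBD direction %d/%d\n"),
              x$n_concordant, x$n_constructs, 100 * x$gv_concordance,
              x$n_mii_concordant, x$n_mii_scored))
  if (nrow(x$mismatches) > 0L) {
    cat("mismatches:\n")
    print(x$mismatches[, c("construct", "figure_ref", "predicted_gv",
                           "observed_gv")], row.names = FALSE)
  }
  invisible(x)
}

#' Element-count calibration on user-supplied real 3'-UTR sequences
#'
#' Optional check of the default motif set against real sequences (none
#' are bundled): per-UTR PAS/CPE/PBE counts and the nearest-CPE gap of
#' every PAS, for comparison with the printed counts (Cpeb1 3 PAS /
#' 4 CPE; Btg4 2/3; Cnot6l 2/4; Cpeb1 nearest gaps 386 and 228 nt).
#'
#' @param fasta_path FASTA of real 3'-UTR sequences. When missing, the
#'   calibration is skipped with a message and `NULL` is returned.
#' @param patterns Motif set to calibrate.
#' @param cfg A [code_config()] (used only to annotate PAS calls).
#' @return A list with per-UTR `counts` and the per-PAS `gap` table, or
#'   `NULL` when skipped.
#' @export
calibrate_external <- function(fasta_path,
                               patterns = default_patterns(),
                               cfg = code_config()) {
  if (missing(fasta_path) || is.null(fasta_path) ||
      !file.exists(fasta_path)) {
    message("external calibration skipped: no 3'-UTR FASTA supplied",
            if (!missing(fasta_path) && is.character(fasta_path))
              paste0(" (", fasta_path, " not found)") else "")
    return(invisible(NULL))
  }
  recs <- read_utr_fasta(fasta_path)
  counts <- do.call(rbind, lapply(recs, function(r) {
    el <- scan_motifs(r, patterns)
    data.frame(utr_id = r$id,
               n_pas = sum(el$element_class == "PAS"),
               n_cpe = sum(el$element_class == "CPE"),
               n_pbe = sum(el$element_class == "PBE"),
               stringsAsFactors = FALSE)
  }))
  gaps <- do.call(rbind, lapply(recs, function(r) {
    arch <- build_architecture(r, scan_motifs(r, patterns))
    tab <- pas_table(arch, cfg)
    if (nrow(tab) == 0L) return(NULL)
    data.frame(utr_id = r$id, pas_label = tab$pas_label,
               nearest_cpe_gap = tab$nearest_gap, call = tab$call,
               stringsAsFactors = FALSE)
  }))
  list(counts = counts, gaps = gaps)
}
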