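# The rule engine: classify each PAS by its CPE context and turn an
# element architecture into per-stage relative translational activities
# and a transcript fate.
#
# The code, in brief:
#   (i)   a transcript is translated at the GV stage iff it carries at
#         least one PAS far away from all CPEs;
#   (ii)  proximal and distal PASs are equally effective (only gaps
#         matter, never absolute position);
#   (iii) repression at GV and stimulation after GVBD both require a CPE
#         near the PAS;
#   (iv)  the number and sidedness of nearby CPEs sets the repression
#         efficiency (flanking > one-sided; dose-dependent).

#' Rule-engine configuration
#'
#' Distance windows and weights of the combinatorial code. The defaults
#' are calibrated on the reporter spacer series: a one-sided CPE represses
#' at 35 nt but not at 50 nt (so `w_one = 40`), while flanking CPEs still
#' repress at 66 nt on each side (so `w_flank = 100`).
#'
#' @param w_one One-sided repression window, nt. A CPE on only one side of
#'   a PAS represses only within this gap.
#' @param w_flank Flanking repression window, nt. CPEs on both sides
#'   within this gap silence the PAS completely; it is also the reach of
#'   post-GVBD stimulation.
#' @param one_sided_penalty Fraction of activity removed by an in-window
#'   same-side CPE cluster.
#' @param dose_step Additional repression per extra in-window CPE
#'   (activity is floored at 0).
#' @param stim_per_cpe Post-GVBD stimulation increment per CPE within
#'   `w_flank` of a PAS.
#' @param active_threshold Minimum relative activity for a transcript to
#'   count as GV-active; must lie in (0, 1).
#' @return A `CodeConfig` list.
#' @export
code_config <- function(w_one = 40, w_flank = 100, one_sided_penalty = 0.5,
                        dose_step = 0.25, stim_per_cpe = 0.5,
                        active_threshold = 0.25) {
  if (w_one > w_flank)
    stop("w_one must not exceed w_flank", call. = FALSE)
  if (any(c(w_one, w_flank, one_sided_penalty, dose_step, stim_per_cpe) < 0))
    stop("windows and weights must be non-negative", call. = FALSE)
  if (active_threshold <= 0 || active_threshold >= 1)
    stop("active_threshold must lie in (0, 1)", call. = FALSE)
  structure(list(w_one = w_one, w_flank = w_flank,
                 one_sided_penalty = one_sided_penalty,
                 dose_step = dose_step, stim_per_cpe = stim_per_cpe,
                 active_threshold = active_threshold),
            class = "CodeConfig")
}

#' @export
print.CodeConfig <- function(x, ...) {
  cat("CodeConfig:\n")
  for (f in names(x)) cat(sprintf("  %-18s %s\n", f, format(x[[f]])))
  invisible(x)
}

# Signed gaps from one PAS to every CPE of the architecture.
pas_cpe_gaps <- function(arch, pas) {
  cpe <- arch$elements[arch$elements$element_class == "CPE", , drop = FALSE]
  if (nrow(cpe) == 0L)
    return(data.frame(gap = numeric(0), side = character(0)))
  side <- ifelse(cpe$end <= pas$start, "up",
          ifelse(cpe$start >= pas$end, "down",
                 # cross-class overlap: assign by midpoint, gap 0
                 ifelse((cpe$start + cpe$end) < (pas$start + pas$end),
                        "up", "down")))
  gap <- ifelse(side == "up", pmax(0L, pas$start - cpe$end),
                pmax(0L, cpe$start - pas$end))
  data.frame(gap = as.numeric(gap), side = side)
}

#' Classify a PAS by its CPE context
#'
#' `FLANKED`: at least one CPE within `w_flank` on each side (complete
#' repression at GV). `ONE_SIDED`: CPEs within `w_one` on exactly one side
#' (partial repression). `FREE` otherwise -- including a CPE on one side
#' at a gap between `w_one` and `w_flank`, the conservative reading of the
#' 50-nt spacer result.
#'
#' @param arch A `UtrArchitecture`.
#' @param pas A PAS label (e.g. `"PAS2"`) or one-row element.
#' @param cfg A [code_config()].
#' @return A `PasContext`: list with `pas_label`, `n_up`/`n_down` (CPEs
#'   within `w_flank` on each side), `n_one` (CPEs within `w_one` on the
#'   repressing side), `nearest_gap` (NA when the UTR has no CPE) and
#'   `call`.
#' @export
classify_pas <- function(arch, pas, cfg = code_config()) {
  stopifnot(inherits(arch, "UtrArchitecture"))
  if (is.character(pas)) pas <- get_element(arch, pas, "PAS")
  else {
    # accept an element row, but insist it belongs to this architecture
    get_element(arch, pas$label, "PAS")
  }
  g <- pas_cpe_gaps(arch, pas)
  n_up <- sum(g$side == "up" & g$gap <= cfg$w_flank)
  n_down <- sum(g$side == "down" & g$gap <= cfg$w_flank)
  n_one <- sum(g$gap <= cfg$w_one)
  call <- if (n_up >= 1L && n_down >= 1L) "FLANKED"
          else if (n_one >= 1L) "ONE_SIDED"
          else "FREE"
  structure(list(pas_label = pas$label,
                 n_up = n_up, n_down = n_down, n_one = n_one,
                 nearest_gap = if (nrow(g) == 0L) NA_real_ else min(g$gap),
                 call = call),
            class = "PasContext")
}

#' GV-stage activity of a single PAS
#'
#' `FREE` -> 1; `FLANKED` -> 0; `ONE_SIDED` -> `max(0, 1 -
#' one_sided_penalty - dose_step * (n_one - 1))`, i.e. partial repression
#' that deepens with each extra in-window CPE. Monotonically
#' non-increasing in the CPE counts.
#'
#' @param ctx A `PasContext` from [classify_pas()].
#' @param cfg A [code_config()].
#' @return Activity fraction in \[0, 1\].
#' @export
pas_gv_activity <- function(ctx, cfg = code_config()) {
  stopifnot(inherits(ctx, "PasContext"))
  switch(ctx$call,
         FREE = 1,
         FLANKED = 0,
         ONE_SIDED = max(0, 1 - cfg$one_sided_penalty -
                           cfg$dose_step * (max(1L, ctx$n_one) - 1L)))
}

pas_table <- function(arch, cfg) {
  pas <- arch$elements[arch$elements$element_class == "PAS", , drop = FALSE]
  if (nrow(pas) == 0L)
    return(data.frame(pas_label = character(0), call = character(0),
                      n_up = integer(0), n_down = integer(0),
                      n_one = integer(0), nearest_gap = numeric(0),
                      gv = numeric(0), post_gvbd = numeric(0)))
  rows <- lapply(seq_len(nrow(pas)), function(i) {
    ctx <- classify_pas(arch, pas$label[i], cfg)
    data.frame(pas_label = ctx$pas_label, call = ctx$call,
               n_up = ctx$n_up, n_down = ctx$n_down, n_one = ctx$n_one,
               nearest_gap = ctx$nearest_gap,
               gv = pas_gv_activity(ctx, cfg),
               post_gvbd = 1 + cfg$stim_per_cpe * (ctx$n_up + ctx$n_down),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Normalizer: the number of PASs of the reference architecture that are
# translation-competent (nonzero GV activity); all PASs when none is
# competent (a fully dormant reference), so post-GVBD values stay finite.
activity_normalizer <- function(reference, cfg) {
  tab <- pas_table(reference, cfg)
  if (nrow(tab) == 0L) return(1)
  competent <- sum(tab$gv > 0)
  if (competent > 0L) competent else nrow(tab)
}

stage_activity <- function(arch, cfg, reference, column) {
  tab <- pas_table(arch, cfg)
  ref <- reference %||% arch
  if (is.null(reference)) {
    # stand-alone evaluation: normalize by the architecture's own PAS
    # count at full freedom
    norm <- max(1L, nrow(tab))
  } else {
    stopifnot(inherits(ref, "UtrArchitecture"))
    norm <- activity_normalizer(ref, cfg)
  }
  if (nrow(tab) == 0L) {
    warning("architecture '", arch$utr_id,
            "' has no PAS; activity is 0", call. = FALSE)
    return(list(activity = 0, per_pas = tab, normalizer = norm))
  }
  list(activity = sum(tab[[column]]) / norm, per_pas = tab,
       normalizer = norm)
}

#' GV-stage relative activity of a transcript
#'
#' Per-PAS activities are additive with equal weights; the sum is divided
#' by the number of translation-competent PASs of the reference
#' architecture (wild-type normalization, so a single-free-PAS construct
#' of a two-competent-PAS wild type scores 0.5), or by the architecture's
#' own PAS count when evaluated stand-alone.
#'
#' @param arch A `UtrArchitecture`.
#' @param cfg A [code_config()].
#' @param reference Optional reference (wild-type) `UtrArchitecture` for
#'   normalization.
#' @return List with `activity`, the `per_pas` detail table and the
#'   `normalizer` used. A PAS-free architecture yields 0 with a warning.
#' @export
gv_activity <- function(arch, cfg = code_config(), reference = NULL) {
  stopifnot(inherits(arch, "UtrArchitecture"))
  stage_activity(arch, cfg, reference, "gv")
}

#' Post-GVBD relative activity of a transcript
#'
#' After germinal vesicle breakdown every PAS becomes accessible
#' (activity 1) regardless of CPE context, and gains `stim_per_cpe` for
#' each CPE within `w_flank` (the repressors turned stimulators).
#' Normalization as in [gv_activity()]; consequently post-GVBD activity
#' is never below GV activity.
#'
#' @inheritParams gv_activity
#' @return List with `activity`, `per_pas`, `normalizer`.
#' @export
post_gvbd_activity <- function(arch, cfg = code_config(),
                               reference = NULL) {
  stopifnot(inherits(arch, "UtrArchitecture"))
  stage_activity(arch, cfg, reference, "post_gvbd")
}

#' Predict the translational profile of a transcript
#'
#' Combines both stages into a fate class:
#' * `CONSTITUTIVE_GV` -- GV-active with no CPE within reach of any PAS
#'   (same activity at both stages);
#' * `GV_ACTIVE_BOOSTED` -- GV-active, and at least one PAS has an
#'   in-window CPE, so translation strengthens after GVBD;
#' * `DORMANT_ACTIVATED` -- below threshold at GV, above after GVBD;
#' * `INACTIVE` -- no PAS yields activity at any stage.
#'
#' @inheritParams gv_activity
#' @return A `TranslationProfile`: list with `utr_id`, `gv_activity`,
#'   `post_gvbd_activity`, `fate` and the `per_pas` table.
#' @export
predict_profile <- function(arch, cfg = code_config(), reference = NULL) {
  stopifnot(inherits(arch, "UtrArchitecture"))
  gv <- stage_activity(arch, cfg, reference, "gv")
  post <- stage_activity(arch, cfg, reference, "post_gvbd")
  tab <- gv$per_pas
  tab$post_gvbd <- post$per_pas$post_gvbd %||% numeric(0)
  thr <- cfg$active_threshold
  any_inwindow <- nrow(tab) > 0L && any(tab$n_up + tab$n_down > 0L)
  fate <- if (nrow(tab) == 0L) "INACTIVE"
          else if (gv$activity >= thr)
            (if (any_inwindow) "GV_ACTIVE_BOOSTED" else "CONSTITUTIVE_GV")
          else if (post$activity >= thr) "DORMANT_ACTIVATED"
          else "INACTIVE"
  structure(list(utr_id = arch$utr_id,
                 gv_activity = gv$activity,
                 post_gvbd_activity = post$activity,
                 fate = fate, per_pas = tab,
                 normalizer = gv$normalizer),
            class = "TranslationProfile")
}

#' @export
print.TranslationProfile <- function(x, ...) {
  cat(sprintf("TranslationProfile '%s': GV %.3g, post-GVBD %.3g -> %s\n",
              x$utr_id, x$gv_activity, x$post_gvbd_activity, x$fate))
  if (nrow(x$per_pas) > 0L)
    print(x$per_pas, row.names = FALSE)
  invisible(x)
}

#' Is a PAS accessible to CPSF?
#'
#' Models CPSF4 binding: at the GV stage a PAS is accessible iff it is not
#' repressed by nearby CPEs (a `ONE_SIDED` PAS with residual activity is
#' accessible with `partial = TRUE`); after GVBD every PAS is accessible.
#'
#' @param arch A `UtrArchitecture`.
#' @param pas PAS label or element row.
#' @param stage `"GV"` or `"POST_GVBD"`.
#' @param cfg A [code_config()].
#' @return List with logical `accessible` and `partial`.
#' @export
cpsf_accessibility <- function(arch, pas, stage = c("GV", "POST_GVBD"),
                               cfg = code_config()) {
  stage <- match.arg(stage)
  ctx <- classify_pas(arch, pas, cfg)   # errors if the PAS is absent
  if (stage == "POST_GVBD")
    return(list(accessible = TRUE, partial = FALSE))
  switch(ctx$call,
         FREE = list(accessible = TRUE, partial = FALSE),
         FLANKED = list(accessible = FALSE, partial = FALSE),
         ONE_SIDED = {
           acc <- pas_gv_activity(ctx, cfg) > 0
           list(accessible = acc, partial = acc)
         })
}
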