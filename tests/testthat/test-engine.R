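# The rule engine: PAS classification, activities, fates, accessibility.

toy_arch <- function(layout, len = NULL) {
  # layout: data.frame(element_class, start); PAS=AATAAA, CPE=TTTTAAT
  motif <- ifelse(layout$element_class == "PAS", "AATAAA", "TTTTAAT")
  len <- len %||% (max(layout$start + nchar(motif)) + 20L)
  spec <- architecture_spec(
    utr_length = len,
    placements = data.frame(element_class = layout$element_class,
                            motif = motif, start = layout$start,
                            stringsAsFactors = FALSE),
    seed = 99L)
  plant_architecture(spec)$architecture
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("code_config validates its invariants", {
  expect_error(code_config(w_one = 120, w_flank = 100), "w_one")
  expect_error(code_config(dose_step = -1), "non-negative")
  expect_error(code_config(active_threshold = 0), "active_threshold")
  expect_error(code_config(active_threshold = 1), "active_threshold")
})

test_that("classify_pas applies the two-window flanked/one-sided/free rule", {
  # fixture anchors: free at 386, flanked middle PAS
  expect_equal(classify_pas(FIX$Cpeb1$architecture, "PAS1", CFG)$call,
               "FREE")
  ctx2 <- classify_pas(FIX$Cpeb1$architecture, "PAS2", CFG)
  expect_equal(ctx2$call, "FLANKED")
  expect_equal(ctx2$n_up + ctx2$n_down, 4)

  # one-sided window boundary: 35 represses, 50 does not
  a35 <- toy_arch(data.frame(element_class = c("PAS", "CPE"),
                             start = c(10L, 51L)))   # gap 35
  a50 <- toy_arch(data.frame(element_class = c("PAS", "CPE"),
                             start = c(10L, 66L)))   # gap 50
  expect_equal(classify_pas(a35, "PAS1", CFG)$call, "ONE_SIDED")
  expect_equal(classify_pas(a50, "PAS1", CFG)$call, "FREE")

  # one side within w_flank (but not w_one) and nothing opposite -> FREE;
  # CPEs within w_flank on both sides -> FLANKED even without a w_one hit
  a80 <- toy_arch(data.frame(element_class = c("PAS", "CPE"),
                             start = c(10L, 96L)))   # gap 80
  expect_equal(classify_pas(a80, "PAS1", CFG)$call, "FREE")
  afl <- toy_arch(data.frame(element_class = c("CPE", "PAS", "CPE"),
                             start = c(10L, 80L, 150L)))  # gaps 63/64
  expect_equal(classify_pas(afl, "PAS1", CFG)$call, "FLANKED")

  expect_error(classify_pas(FIX$Btg4$architecture, "PAS9", CFG),
               "not found")
})

test_that("per-PAS GV activity follows the dose rule", {
  mk <- function(call, n_one) structure(
    list(pas_label = "PAS1", n_up = 0L, n_down = 1L, n_one = n_one,
         nearest_gap = 10, call = call), class = "PasContext")
  expect_equal(pas_gv_activity(mk("FREE", 0L), CFG), 1)
  expect_equal(pas_gv_activity(mk("FLANKED", 1L), CFG), 0)
  expect_equal(pas_gv_activity(mk("ONE_SIDED", 1L), CFG), 0.5)
  expect_equal(pas_gv_activity(mk("ONE_SIDED", 2L), CFG), 0.25)
  expect_equal(pas_gv_activity(mk("ONE_SIDED", 3L), CFG), 0)  # floored

  # Btg4: both PASs flanked at 66 nt -> zero GV activity
  for (lab in c("PAS1", "PAS2"))
    expect_equal(pas_gv_activity(
      classify_pas(FIX$Btg4$architecture, lab, CFG), CFG), 0)
})

test_that("transcript activities use wild-type-competent normalization", {
  wt <- FIX$Cpeb1$architecture
  expect_equal(gv_activity(wt, CFG, reference = wt)$activity, 1.0)

  cs <- enumerate_paper_constructs()
  pas1_only <- apply_construct(cs[["Cpeb1-dPAS2/3"]], FIX)
  expect_equal(gv_activity(pas1_only$arch, CFG, reference = wt)$activity,
               0.5)

  # CPEs but no PAS -> 0, with a warning
  cpe_only <- toy_arch(data.frame(element_class = "CPE", start = 10L))
  expect_warning(res <- gv_activity(cpe_only, CFG), "no PAS")
  expect_equal(res$activity, 0)
})

test_that("post-GVBD activity releases and stimulates every PAS", {
  btg4 <- FIX$Btg4$architecture
  expect_equal(gv_activity(btg4, CFG)$activity, 0)
  post <- post_gvbd_activity(btg4, CFG)$activity
  expect_gt(post, CFG$active_threshold)

  # CPE mutation removes the stimulation: post-GVBD drops to <= WT's
  cs <- enumerate_paper_constructs()
  nocpe <- apply_construct(cs[["Btg4-dCPE1/2/3"]], FIX)
  post_nocpe <- post_gvbd_activity(nocpe$arch, CFG,
                                   reference = btg4)$activity
  expect_lte(post_nocpe, post_gvbd_activity(btg4, CFG,
                                            reference = btg4)$activity)
})

test_that("fate assignment covers the four classes and degenerate cases", {
  expect_equal(predict_profile(FIX$Cpeb1$architecture, CFG)$fate,
               "GV_ACTIVE_BOOSTED")
  expect_equal(predict_profile(FIX$Btg4$architecture, CFG)$fate,
               "DORMANT_ACTIVATED")

  cs <- enumerate_paper_constructs()
  dpas1 <- apply_construct(cs[["Cnot6l-dPAS1"]], FIX)
  expect_equal(predict_profile(dpas1$arch, CFG)$fate, "DORMANT_ACTIVATED")
  allmut <- apply_construct(cs[["Cpeb1-dPAS1/2/3"]], FIX)
  expect_equal(suppressWarnings(predict_profile(allmut$arch, CFG))$fate,
               "INACTIVE")

  # single free PAS, no CPE: constitutive, equal activity at both stages
  lone <- toy_arch(data.frame(element_class = "PAS", start = 40L))
  prof <- predict_profile(lone, CFG)
  expect_equal(prof$fate, "CONSTITUTIVE_GV")
  expect_equal(prof$gv_activity, prof$post_gvbd_activity)
  expect_equal(prof$gv_activity, 1)
})

test_that("monotonicity: in-window CPEs never help at GV; stages ordered", {
  for (seed in 1:60) {
    spec <- random_arch_spec(seed)
    base <- plant_architecture(spec)$architecture
    prof <- suppressWarnings(predict_profile(base, CFG))
    expect_gte(prof$post_gvbd_activity, prof$gv_activity)

    # plant one extra CPE within w_flank of a random PAS
    pl <- spec$placements
    pas <- pl[pl$element_class == "PAS", ][1, ]
    hi <- min(pas$end + CFG$w_flank - 7L, spec$utr_length - 8L)
    if (hi < pas$end + 1L) next
    slots <- seq.int(pas$end + 1L, hi)
    # keep >= 1 nt of repairable background around the new CPE
    free <- slots[vapply(slots, function(s) {
      all(s + 8L <= pl$start | s >= pl$end + 1L)
    }, logical(1))]
    if (length(free) == 0L) next
    pl2 <- rbind(pl[, c("element_class", "motif", "start")],
                 data.frame(element_class = "CPE", motif = "TTTTAAT",
                            start = free[1]))
    spec2 <- architecture_spec(spec$utr_length, pl2, seed = spec$seed)
    more <- plant_architecture(spec2)$architecture
    expect_lte(gv_activity(more, CFG)$activity,
               gv_activity(base, CFG)$activity,
               label = paste("seed", seed, "gv with extra CPE"))
  }
})

test_that("profiles are invariant under rigid translation of the elements", {
  for (seed in 101:115) {
    a <- plant_architecture(random_arch_spec(seed))$architecture
    b <- plant_architecture(random_arch_spec(seed, offset = 57L))$architecture
    pa <- suppressWarnings(predict_profile(a, CFG))
    pb <- suppressWarnings(predict_profile(b, CFG))
    expect_equal(pa$gv_activity, pb$gv_activity)
    expect_equal(pa$post_gvbd_activity, pb$post_gvbd_activity)
    expect_equal(pa$fate, pb$fate)
    expect_equal(pa$per_pas$call, pb$per_pas$call)
  }
})

test_that("CPSF accessibility mirrors repression and the stage switch", {
  wt <- FIX$Cpeb1$architecture
  expect_false(cpsf_accessibility(wt, "PAS2", "GV", CFG)$accessible)
  expect_true(cpsf_accessibility(wt, "PAS1", "GV", CFG)$accessible)
  expect_true(cpsf_accessibility(wt, "PAS2", "POST_GVBD", CFG)$accessible)

  cs <- enumerate_paper_constructs()
  decpe <- apply_construct(cs[["Cpeb1-dCPE1-4"]], FIX)
  expect_true(cpsf_accessibility(decpe$arch, "PAS2", "GV",
                                 CFG)$accessible)

  one <- toy_arch(data.frame(element_class = c("PAS", "CPE"),
                             start = c(10L, 51L)))
  acc <- cpsf_accessibility(one, "PAS1", "GV", CFG)
  expect_true(acc$accessible)
  expect_true(acc$partial)

  expect_error(cpsf_accessibility(wt, "PAS7", "GV", CFG), "not found")
})
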