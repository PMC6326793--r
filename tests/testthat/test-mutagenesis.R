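# In-silico reporter construction: element mutations, spacer surgery,
# insertions, truncations, and the packaged construct set.

test_that("mutate_pas substitutes AATAAA -> AAGGAA in place", {
  x <- scan_utr(utr_record("toy", "CCAATAAACC"))
  y <- mutate_pas(x, "PAS1")
  expect_equal(y$record$sequence, "CCAAGGAACC")
  expect_equal(nrow(y$arch$elements), 0)
  expect_error(mutate_pas(y, "PAS1"), "not found")

  cs <- enumerate_paper_constructs()
  allmut <- apply_construct(cs[["Cpeb1-dPAS1/2/3"]], FIX)
  expect_equal(sum(allmut$arch$elements$element_class == "PAS"), 0)
  expect_equal(sum(allmut$arch$elements$element_class == "CPE"), 4)
})

test_that("mutate_cpe yields a motif-free, length-preserving substitution", {
  x <- scan_utr(utr_record("toy", "CCTTTTAATCC"))
  y <- mutate_cpe(x, "CPE1")
  expect_equal(nchar(y$record$sequence), nchar(x$record$sequence))
  expect_equal(nrow(y$arch$elements), 0)

  cs <- enumerate_paper_constructs()
  derep <- apply_construct(cs[["Btg4-dCPE1/2/3"]], FIX)
  expect_equal(sum(derep$arch$elements$element_class == "CPE"), 0)
  expect_equal(sum(derep$arch$elements$element_class == "PAS"), 2)
  # fate flips from dormant to GV-active
  expect_equal(predict_profile(FIX$Btg4$architecture, CFG)$fate,
               "DORMANT_ACTIVATED")
  prof <- predict_profile(derep$arch, CFG, reference = FIX$Btg4$architecture)
  expect_gte(prof$gv_activity, CFG$active_threshold)

  rescue <- apply_construct(cs[["Cnot6l-dPAS1+dCPE4"]], FIX)
  expect_equal(classify_pas(rescue$arch, "PAS1", CFG)$call, "FREE")
  expect_equal(map_gv_call(predict_profile(
    rescue$arch, CFG, reference = FIX$Cnot6l$architecture), CFG),
    "ACTIVE")
})

test_that("delete_spacer shortens exactly one gap and preserves motifs", {
  x <- scan_utr(FIX$Cpeb1$record)
  x <- mutate_pas(x, "PAS3")
  x <- mutate_pas(x, "PAS2")

  for (gap in c(50L, 35L, 15L)) {
    y <- delete_spacer(x, "PAS1", "CPE1", gap)
    el <- y$arch$elements
    expect_equal(gap_distance(el[el$label == "PAS1", ],
                              el[el$label == "CPE1", ]), gap)
    expect_equal(nrow(el), nrow(x$arch$elements))
    expect_equal(el$element_class, x$arch$elements$element_class)
    # gaps among the untouched CPE cluster are preserved
    cpe <- el[el$element_class == "CPE", ]
    cpe0 <- x$arch$elements[x$arch$elements$element_class == "CPE", ]
    expect_equal(diff(cpe$start), diff(cpe0$start))
  }
  expect_equal(classify_pas(delete_spacer(x, "PAS1", "CPE1", 50)$arch,
                            "PAS1", CFG)$call, "FREE")
  expect_equal(classify_pas(delete_spacer(x, "PAS1", "CPE1", 35)$arch,
                            "PAS1", CFG)$call, "ONE_SIDED")

  expect_error(delete_spacer(x, "PAS1", "CPE1", 386), "smaller")
  expect_error(delete_spacer(x, "PAS1", "CPE1", 9999), "smaller")
})

test_that("insert_cpe plants exactly one new CPE at the requested gap", {
  x <- scan_utr(FIX$Cpeb1$record)
  x <- mutate_pas(x, "PAS3")
  x <- mutate_pas(x, "PAS2")
  expect_equal(classify_pas(x$arch, "PAS1", CFG)$call, "FREE")

  y35 <- insert_cpe(x, "PAS1", 35)
  expect_equal(classify_pas(y35$arch, "PAS1", CFG)$call, "ONE_SIDED")
  expect_equal(nchar(y35$record$sequence), nchar(x$record$sequence) + 7)
  expect_equal(sum(y35$arch$elements$element_class == "CPE"),
               sum(x$arch$elements$element_class == "CPE") + 1)

  y50 <- insert_cpe(x, "PAS1", 50)
  expect_equal(classify_pas(y50$arch, "PAS1", CFG)$call, "FREE")

  # PAS-free toy: an insertion is impossible without a PAS anchor, but a
  # CPE added to a PAS-free architecture leaves it inactive
  nopas <- scan_utr(utr_record("toy",
                               paste0("CCTTTTAATCC",
                                      strrep("CGA", 20))))
  expect_error(insert_cpe(nopas, "PAS1", 10), "not found")
  expect_equal(suppressWarnings(predict_profile(nopas$arch, CFG))$fate,
               "INACTIVE")

  # inserting inside an existing element errors
  z <- scan_utr(utr_record("z", paste0("AATAAA", "CC", "TTTTAAT",
                                       strrep("GCA", 10))))
  expect_error(insert_cpe(z, "PAS1", 4), "overlap")
})

test_that("truncate_distal keeps the 3' fragment and re-bases coordinates", {
  x <- scan_utr(FIX$Cnot6l$record)
  tr <- truncate_distal(x, 402)
  expect_equal(nchar(tr$record$sequence), 402)
  expect_equal(sum(tr$arch$elements$element_class == "CPE"), 3)
  expect_equal(sum(tr$arch$elements$element_class == "PAS"), 1)
  expect_equal(predict_profile(tr$arch, CFG)$fate, "DORMANT_ACTIVATED")
  expect_equal(predict_profile(FIX$Cnot6l$architecture, CFG)$fate,
               "GV_ACTIVE_BOOSTED")

  full <- truncate_distal(x, nchar(x$record$sequence))
  expect_equal(full$record$sequence, x$record$sequence)
  expect_equal(full$arch$elements, x$arch$elements)

  expect_error(truncate_distal(x, 0), "retained_length")
  expect_error(truncate_distal(x, 1e6), "retained_length")
})

test_that("apply_construct is deterministic and reports failing edits", {
  cs <- enumerate_paper_constructs()
  wt <- apply_construct(cs[["Cpeb1-WT"]], FIX)
  expect_equal(wt$record$sequence, FIX$Cpeb1$record$sequence)
  expect_equal(wt$arch$elements, FIX$Cpeb1$architecture$elements)

  a <- apply_construct(cs[["Btg4-dCPE1/2"]], FIX)
  b <- apply_construct(cs[["Btg4-dCPE1/2"]], FIX)
  expect_identical(a$record$sequence, b$record$sequence)

  dup <- construct_spec("bad", "Btg4",
                        list(edit_op("MUTATE_CPE", "CPE3"),
                             edit_op("MUTATE_CPE", "CPE3")))
  expect_error(apply_construct(dup, FIX), "edit 2")
  expect_error(apply_construct(construct_spec("x", "Nope", list()), FIX),
               "base fixture")
})

test_that("the packaged construct set is complete and self-consistent", {
  cs <- enumerate_paper_constructs()
  expect_gte(length(cs), 28)
  expect_false(anyDuplicated(names(cs)) > 0)

  # closure: every construct applies to its fixture without error, and
  # edits never create a motif of another class
  for (spec in cs) {
    x <- suppressWarnings(apply_construct(spec, FIX))
    base_el <- FIX[[spec$base]]$architecture$elements
    got <- table(factor(x$arch$elements$element_class,
                        c("PAS", "CPE", "PBE")))
    want <- table(factor(base_el$element_class, c("PAS", "CPE", "PBE")))
    expect_true(all(got <= want |
                      c(PAS = FALSE, CPE = TRUE, PBE = FALSE)),
                info = spec$name)
    expect_equal(length(x$log), length(spec$edits))
  }
})
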