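test_that("tRF classes are assigned from position and length", {
  trna <- make_trna_model()
  # 19-nt fragment ending at the mature 3' terminus
  f1 <- trna_fragment(trna, 54L, 72L)
  expect_equal(classify_trf(f1, trna)$trf_class, "3p_short")
  # 33-nt fragment anchored at the 3' end
  f2 <- trna_fragment(trna, 40L, 72L)
  expect_equal(classify_trf(f2, trna)$trf_class, "3p_long")
  # 30-nt fragment from position 1 (ends before the anticodon loop)
  f3 <- trna_fragment(trna, 1L, 30L)
  expect_equal(classify_trf(f3, trna)$trf_class, "5p_long")
  # fragment from position 1 into the anticodon loop: half tRNA
  f4 <- trna_fragment(trna, 1L, 35L)
  expect_equal(classify_trf(f4, trna)$trf_class, "half_tRNA")
  # 19-nt fragment over the D loop, not 3'-anchored
  f5 <- trna_fragment(trna, 12L, 30L)
  expect_equal(classify_trf(f5, trna)$trf_class, "dloop_anticodon")
  # 25-nt mid-gene fragment matches no class
  f6 <- trna_fragment(trna, 40L, 64L)
  expect_equal(classify_trf(f6, trna)$trf_class, "unclassified")
  # fragments outside any tRNA raise an error
  expect_error(classify_trf(make_reads("chr1", 5000L, 20L), trna),
               "tRNA")
})

test_that("class boundaries behave as closed intervals with slack 3", {
  trna <- make_trna_model()
  # length 22 still short, 23 no longer
  expect_equal(classify_trf(trna_fragment(trna, 51L, 72L),
                            trna)$trf_class, "3p_short")
  expect_equal(classify_trf(trna_fragment(trna, 50L, 72L),
                            trna)$trf_class, "unclassified")
  # 3' anchor slack: ending 3 nt before the terminus anchors, 4 does
  # not
  expect_equal(classify_trf(trna_fragment(trna, 51L, 69L),
                            trna)$trf_class, "3p_short")
  f <- classify_trf(trna_fragment(trna, 50L, 68L), trna)
  expect_false(f$trf_class %in% c("3p_short", "3p_long"))
  # classification is strand-aware
  tm <- make_trna_model(strand = "-", id = "tRNA-Glu-GAG")
  expect_equal(classify_trf(trna_fragment(tm, 54L, 72L),
                            tm)$trf_class, "3p_short")
  expect_equal(classify_trf(trna_fragment(tm, 1L, 30L),
                            tm)$trf_class, "5p_long")
})

test_that("CCA detection reads the fragment sequence", {
  trna <- make_trna_model()
  f <- trna_fragment(trna, 54L, 72L,
                     seq = paste0(strrep("G", 16L), "CCA"))
  rec <- classify_trf(f, trna)
  expect_equal(rec$cca, "present")
  f2 <- trna_fragment(trna, 40L, 72L,
                      seq = paste0(strrep("G", 30L), "GAU"))
  expect_equal(classify_trf(f2, trna)$cca, "absent")
  # non-3'-anchored classes are not applicable
  f3 <- trna_fragment(trna, 12L, 30L, seq = strrep("G", 19L))
  expect_equal(classify_trf(f3, trna)$cca, "not_applicable")
  expect_equal(detect_cca(c("GGCCA", "GGGAU", NA),
                          c("3p_short", "3p_long", "3p_short")),
               c("present", "absent", NA))
})

test_that("generator truth labels are recovered on synthetic tRFs", {
  b <- synth_generate(synth_config(seed = 2))
  frag <- b$reads[overlapsAny(b$reads, b$annotations$trnas,
                              ignore.strand = TRUE) &
                    !mcols(b$reads)$flagged]
  rec <- classify_trf(frag, b$annotations$trnas)
  rec$read_id <- mcols(frag)$name[rec$fragment]
  cmp <- truth_compare(trf = rec, truth_trf = b$truth$trf)
  expect_gte(cmp$trf$n, 9000L)
  expect_gte(cmp$trf$class_agreement, 0.98)
  expect_gte(cmp$trf$cca_agreement, 0.98)
})
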