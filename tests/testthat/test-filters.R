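# Exclusivity classification and the filter cascade.

test_that("classifyExclusivity follows the presence/absence rule", {
  expect_equal(classifyExclusivity(makeEvent(LM = c("S1", "S2"))), "LM_unique")
  expect_equal(classifyExclusivity(makeEvent(pCRC = "P1")), "pCRC_unique")
  expect_equal(classifyExclusivity(makeEvent(LM = "S1", pCRC = "P1")), "common")
  expect_equal(classifyExclusivity(makeEvent(LM = "S1", N = "N1")),
               "normal_present")
  expect_error(classifyExclusivity(makeEvent()), "no sample")
})

test_that("read support thresholds on max spanning reads, inclusive", {
  expect_true(filterReadSupport(makeEvent(LM = "S1", support = 5), 5L))
  expect_false(filterReadSupport(makeEvent(LM = "S1", support = 4), 5L))
  expect_true(filterReadSupport(makeEvent(LM = "S1", support = 8), 5L))
  # max over samples decides
  ev <- makeEvent(LM = c("S1", "S2"), support = c(3, 7))
  expect_true(filterReadSupport(ev, 5L))
})

test_that("coding filter requires exonic breakpoints in coding transcripts", {
  txset <- TranscriptSet(list(
    TranscriptModel("TC", "GENEA", "chr1", "+",
                    cbind(c(101L, 301L), c(200L, 400L)),
                    cdsStartGenomic = 151L, cdsEndGenomic = 350L),
    TranscriptModel("TN", "GENEB", "chr2", "+", cbind(1500L, 2500L))))
  # both ends exonic in coding transcripts -> pass
  okTxset <- TranscriptSet(list(
    getTranscript(txset, "TC"),
    TranscriptModel("TB", "GENEB", "chr2", "+", cbind(1500L, 2500L),
                    cdsStartGenomic = 1600L, cdsEndGenomic = 2399L)))
  expect_true(filterCoding(makeEvent(pos5 = 350L, pos3 = 2000L, LM = "S1"),
                           okTxset))
  # 3' gene only has a noncoding model -> fail
  r <- filterCoding(makeEvent(pos5 = 350L, pos3 = 2000L, LM = "S1"), txset)
  expect_false(as.logical(r))
  # intronic 5' breakpoint -> "not exonic", not an exception
  r2 <- filterCoding(makeEvent(pos5 = 250L, pos3 = 2000L, LM = "S1"), okTxset)
  expect_false(as.logical(r2))
  expect_match(attr(r2, "reason"), "not exonic")
  # unannotated gene -> recorded, not thrown
  r3 <- filterCoding(makeEvent(gene5 = "NOSUCH", pos3 = 2000L, LM = "S1"),
                     okTxset)
  expect_false(as.logical(r3))
  expect_match(attr(r3, "reason"), "unannotated")
})

test_that("cascade applies stages in order and traces the first failure", {
  txset <- TranscriptSet(list(
    TranscriptModel("TA", "GENEA", "chr1", "+", cbind(500L, 1500L),
                    cdsStartGenomic = 600L, cdsEndGenomic = 1399L),
    TranscriptModel("TB", "GENEB", "chr2", "+", cbind(1500L, 2500L),
                    cdsStartGenomic = 1600L, cdsEndGenomic = 2399L)))
  events <- ConsensusEventSet(list(
    makeEvent(LM = "S1", support = 9),                      # passes all
    makeEvent(LM = "S1", support = 4),                      # read support
    makeEvent(LM = "S1", N = "N1", support = 9),            # normal exclusion
    makeEvent(pCRC = "P1", support = 9)))                   # exclusivity
  res <- applyCascade(events, txset,
                      list(min_support = 5L, target_class = "LM_unique"))
  expect_equal(length(res$passing), 1L)
  expect_equal(res$trace$failed_stage,
               c(NA, "read_support", "normal_exclusion", "exclusivity"))
  # the normal-present event fails at normal exclusion despite support 9
  expect_true(res$trace$pass_read_support[3])
  expect_true(res$trace$pass_coding[3])
  expect_error(applyCascade(events, txset, list(target_class = "bogus")),
               "target_class")
})

test_that("exclusivity classes partition the event set", {
  b <- simulateCohort(simulationConfig(seed = 31L, fpRate = 0.4))
  ev <- consensusFromBundle(b)
  cls <- vapply(consensusEvents(ev), classifyExclusivity, character(1))
  expect_equal(length(cls), length(ev))
  expect_true(all(cls %in% c("LM_unique", "pCRC_unique", "common",
                             "normal_present")))
  expect_equal(sum(table(cls)), length(ev))
})

test_that("zero-noise cascade recovers exactly the planted LM-exclusive coding drivers", {
  b <- simulateCohort(zeroNoiseConfig(37L))
  ev <- consensusFromBundle(b)
  res <- applyCascade(ev, b$txset, list(min_support = 5L,
                                        target_class = "LM_unique"))
  # expected from truth: LM-exclusive, both partners coding, visible to >=2
  # callers, planted support reaching the threshold
  truth <- b$truth
  maxSupport <- tapply(truth$support, truth$fusion_id, max)
  cat0 <- b$catalog
  cat0$maxSupport <- as.vector(maxSupport[cat0$fusion_id])
  expected <- cat0[cat0$class_truth == "LM_unique" &
                   cat0$frame_truth != "noncoding" &
                   is.na(cat0$only_caller) &
                   cat0$maxSupport >= 5, ]
  got <- eventTable(res$passing)
  expect_equal(nrow(got), nrow(expected))
  expect_setequal(paste(got$gene5, got$gene3),
                  paste(expected$gene5, expected$gene3))
  # trace attributes every planted failure to the right stage
  tr <- res$trace
  noncodingId <- cat0$fusion_id[cat0$frame_truth == "noncoding"]
  ncPair <- cat0[cat0$fusion_id == noncodingId, c("gene5", "gene3")]
  ncRow <- tr[grepl(paste0(ncPair$gene5, "--", ncPair$gene3), tr$event), ]
  expect_equal(ncRow$failed_stage, "coding")
  normRow <- tr[tr$exclusivity_class == "normal_present", ]
  expect_true(all(normRow$failed_stage == "normal_exclusion"))
})

test_that("removing a stage can only grow the passing set", {
  b <- simulateCohort(simulationConfig(seed = 41L, fpRate = 0.5))
  ev <- consensusFromBundle(b)
  strict <- applyCascade(ev, b$txset, list(min_support = 5L,
                                           target_class = "LM_unique"))
  relaxed <- applyCascade(ev, b$txset, list(min_support = 0L,
                                            target_class = "LM_unique"))
  strictIds <- strict$trace$event[strict$trace$pass_exclusivity]
  relaxedIds <- relaxed$trace$event[relaxed$trace$pass_exclusivity]
  expect_true(all(strictIds %in% relaxedIds))
})
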