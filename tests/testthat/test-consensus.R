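# Cross-caller validation and cross-sample merging.

test_that("matchCalls compares genes, ends and positions symmetrically", {
  a <- makeCall()
  expect_true(matchCalls(a, a, tol = 0L))

  b <- makeCall(pos5 = a$pos5 + 7L)
  expect_true(matchCalls(a, b, tol = 10L))
  expect_true(matchCalls(b, a, tol = 10L))
  expect_false(matchCalls(a, b, tol = 5L))

  swapped <- makeCall(gene5 = "GENEB", gene3 = "GENEA")
  expect_false(matchCalls(a, swapped, tol = 1e6))

  otherStrand <- makeCall(strand5 = "-")
  expect_false(matchCalls(a, otherStrand, tol = 10L))
})

test_that("crossValidate keeps clusters seen by enough distinct callers", {
  calls <- rbind(
    makeCall(caller = "arriba"),
    makeCall(caller = "defuse"),
    makeCall(gene5 = "GENEC", gene3 = "GENED", caller = "soapfuse"))
  v <- crossValidate(FusionCallSet(calls), minTools = 2L, tol = 10L)
  expect_equal(nrow(v), 1L)
  expect_equal(v$gene5, "GENEA")
  expect_setequal(v$callers[[1]], c("arriba", "defuse"))

  # multiple calls from one caller are one vote
  dup <- rbind(makeCall(caller = "arriba"), makeCall(caller = "arriba",
                                                     pos5 = 1003L))
  expect_equal(nrow(crossValidate(FusionCallSet(dup), 2L, 10L)), 0L)
})

test_that("cluster representative is the per-end lower-median", {
  calls <- rbind(
    makeCall(caller = "arriba", pos5 = 100L, pos3 = 2000L),
    makeCall(caller = "defuse", pos5 = 103L, pos3 = 2001L),
    makeCall(caller = "clc", pos5 = 110L, pos3 = 1999L))
  v <- crossValidate(FusionCallSet(calls), 2L, 10L)
  expect_equal(nrow(v), 1L)
  expect_equal(v$pos5, 103L)  # median of 100/103/110
  expect_equal(v$pos3, 2000L)
  expect_equal(v$spanning_reads, 6L)

  # even count: lower of the two middles
  calls4 <- rbind(calls, makeCall(caller = "soapfuse", pos5 = 104L, pos3 = 2000L))
  v4 <- crossValidate(FusionCallSet(calls4), 2L, 10L)
  expect_equal(v4$pos5, 103L)  # sorted 100,103,104,110 -> lower middle
})

test_that("mergeEvents pools carriers by tissue class", {
  lm <- paste0("LM", 1:7)
  sheet <- data.frame(sample_id = c(lm, "P1"),
                      tissue_class = c(rep("LM", 7), "pCRC"),
                      patient_id = c(paste0("pt", 1:7), "pt1"),
                      stringsAsFactors = FALSE)
  calls <- do.call(rbind, lapply(lm, function(s) rbind(
    makeCall(sample_id = s, caller = "arriba"),
    makeCall(sample_id = s, caller = "defuse"))))
  ev <- mergeEvents(crossValidate(FusionCallSet(calls), 2L, 10L), sheet, 10L)
  expect_equal(length(ev), 1L)
  expect_equal(length(consensusEvents(ev)[[1]]$samples_by_class$LM), 7L)

  # same genes, far-apart breakpoints stay distinct
  far <- rbind(makeCall(sample_id = "LM1", caller = "arriba"),
               makeCall(sample_id = "LM1", caller = "defuse"),
               makeCall(sample_id = "LM2", caller = "arriba", pos5 = 1500L),
               makeCall(sample_id = "LM2", caller = "defuse", pos5 = 1500L))
  ev2 <- mergeEvents(crossValidate(FusionCallSet(far), 2L, 10L), sheet, 10L)
  expect_equal(length(ev2), 2L)

  # unknown samples are named in the error
  expect_error(
    mergeEvents(crossValidate(FusionCallSet(
      rbind(makeCall(sample_id = "GHOST", caller = "arriba"),
            makeCall(sample_id = "GHOST", caller = "defuse"))), 2L, 10L),
      sheet, 10L),
    "GHOST")
})

test_that("zero-noise planted cohort reproduces the catalog exactly", {
  b <- simulateCohort(zeroNoiseConfig(17L))
  ev <- consensusFromBundle(b)
  # expected: every catalog entry reported by >= 2 callers
  expected <- b$catalog[is.na(b$catalog$only_caller), ]
  expect_equal(length(ev), nrow(expected))
  tab <- eventTable(ev)
  key <- function(d) sort(paste(d$gene5, d$gene3, d$chrom5, d$pos5,
                                d$chrom3, d$pos3))
  expect_equal(key(tab), key(expected))
  # carrier counts per class match the planted truth
  for (i in seq_len(nrow(tab))) {
    entry <- expected[expected$gene5 == tab$gene5[i] &
                      expected$gene3 == tab$gene3[i], ]
    expect_equal(tab$n_samples_LM[i], entry$n_LM)
    expect_equal(tab$n_samples_pCRC[i], entry$n_pCRC)
    expect_equal(tab$n_samples_N[i], entry$n_N)
  }
})

test_that("tolerance and min_tools act monotonically; order never matters", {
  set.seed(101)
  b <- simulateCohort(simulationConfig(seed = 23L, jitterSd = 3, fpRate = 0.3))
  all <- FusionCallSet(do.call(rbind, lapply(b$callSets, fusionCalls)))

  nClusters <- function(minTools, tol)
    nrow(crossValidate(all, minTools, tol))
  # retained clusters never grow with min_tools, matches never shrink with tol
  for (tol in c(0L, 5L, 20L)) {
    expect_true(nClusters(2L, tol) >= nClusters(3L, tol))
    expect_true(nClusters(3L, tol) >= nClusters(4L, tol))
  }
  cl1 <- nClusters(1L, 0L); cl2 <- nClusters(1L, 10L); cl3 <- nClusters(1L, 50L)
  # with fixed min_tools=1, wider tolerance can only merge clusters
  expect_true(cl1 >= cl2 && cl2 >= cl3)

  # permutation invariance of the final event set
  calls <- fusionCalls(all)
  perm <- calls[sample(nrow(calls)), ]
  e1 <- eventTable(mergeEvents(crossValidate(all, 2L, 10L), b$sheet, 10L))
  e2 <- eventTable(mergeEvents(crossValidate(FusionCallSet(perm), 2L, 10L),
                               b$sheet, 10L))
  expect_equal(e1, e2)
})

test_that("merging merged events is idempotent", {
  b <- simulateCohort(zeroNoiseConfig(29L))
  ev <- consensusFromBundle(b)
  # re-feed representatives as single-caller clusters and merge again
  tab <- eventTable(ev)
  again <- data.frame(sample_id = "LM_P01", tab[, c("gene5", "gene3", "chrom5",
                                                    "pos5", "strand5", "chrom3",
                                                    "pos3", "strand3")],
                      n_callers = 2L, spanning_reads = tab$max_support,
                      crossing_reads = 0L, stringsAsFactors = FALSE)
  again$callers <- rep(list(c("arriba", "defuse")), nrow(again))
  ev2 <- mergeEvents(again, b$sheet, 10L)
  expect_equal(length(ev2), length(ev))
  t2 <- eventTable(ev2)
  expect_equal(t2[, c("gene5", "gene3", "pos5", "pos3")],
               tab[, c("gene5", "gene3", "pos5", "pos3")])
})
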