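# Breakpoint-to-transcript mapping, phase arithmetic, frame status, domain
# retention, nomination.

test_that("breakpoint mapping is strand-aware with cumulative offsets", {
  plus <- TranscriptModel("TP", "G", "chr1", "+",
                          cbind(c(101L, 301L), c(200L, 400L)))
  m <- mapBreakpointToTranscript(list(chrom = "chr1", pos = 350L), plus)
  expect_true(m$exonic)
  expect_equal(m$exon, 2L)
  expect_equal(m$offset, 150L)  # 100 nt exon 1 + 50 nt into exon 2

  minus <- TranscriptModel("TM", "G", "chr1", "-",
                           cbind(c(101L, 301L), c(200L, 400L)))
  m2 <- mapBreakpointToTranscript(list(chrom = "chr1", pos = 350L), minus)
  expect_equal(m2$exon, 1L)     # highest-coordinate exon transcribed first
  expect_equal(m2$offset, 51L)  # 400 - 350 + 1

  m3 <- mapBreakpointToTranscript(list(chrom = "chr1", pos = 250L), plus)
  expect_false(m3$exonic)

  expect_error(mapBreakpointToTranscript(list(chrom = "chr2", pos = 350L),
                                         plus), "chromosome")
})

test_that("junction phases realize the worked 146/233 example", {
  wx <- workedExamplePair()
  ph <- junctionPhases(wx$tx5, wx$bp5, wx$tx3, wx$bp3)
  expect_equal(ph$retained_cds5_nt, 146L)
  expect_equal(ph$skipped_cds3_nt, 233L)
  expect_equal(ph$phase5, 2L)
  expect_equal(ph$phase3, 2L)
  fs <- frameStatus(ph)
  expect_equal(fs$frame_status, "in_frame")
})

test_that("5'UTR junctions and whole-codon junctions are recognized", {
  wx <- workedExamplePair()
  # bp5 upstream of the CDS start -> retained 0, UTR flag
  ph <- junctionPhases(wx$tx5, list(chrom = "chr7", pos = 50L),
                       wx$tx3, list(chrom = "chr12", pos = 150L))
  expect_equal(ph$retained_cds5_nt, 0L)
  expect_equal(ph$phase5, 0L)
  expect_true(ph$utr5)
  fs <- frameStatus(ph)
  expect_equal(fs$frame_status, "five_prime_utr_fusion")
  expect_true(fs$intact_3p_orf)  # bp3 upstream of the 3' CDS start

  # retained 3 nt / skipped 0 nt -> whole codons, phases (0,0)
  ph2 <- junctionPhases(wx$tx5, list(chrom = "chr7", pos = 103L),
                        wx$tx3, list(chrom = "chr12", pos = 201L))
  expect_equal(ph2$retained_cds5_nt, 3L)
  expect_equal(ph2$skipped_cds3_nt, 0L)
  expect_equal(c(ph2$phase5, ph2$phase3), c(0L, 0L))
  expect_equal(frameStatus(ph2)$frame_status, "in_frame")

  # unequal phases -> out of frame
  ph3 <- junctionPhases(wx$tx5, list(chrom = "chr7", pos = 101L),
                        wx$tx3, list(chrom = "chr12", pos = 201L))
  expect_equal(c(ph3$phase5, ph3$phase3), c(1L, 0L))
  expect_equal(frameStatus(ph3)$frame_status, "out_of_frame")
})

test_that("noncoding partners yield frame status noncoding", {
  nc <- TranscriptModel("TNC", "NCG", "chr12", "+", cbind(1L, 1000L))
  wx <- workedExamplePair()
  chim <- chimericTranscript(wx$tx5, wx$bp5, nc,
                             list(chrom = "chr12", pos = 500L))
  expect_equal(chim$frame_status, "noncoding")
})

test_that("domain retention uses the junction amino-acid boundaries", {
  wx <- workedExamplePair()
  chim <- chimericTranscript(wx$tx5, wx$bp5, wx$tx3, wx$bp3)
  # J5 = floor(146/3) = 48, A3 = floor(233/3) + 1 = 78
  domains <- data.frame(
    transcript_id = c("TXA", "TXA", "TXB", "TXB"),
    name = c("kept5", "straddling5", "kept3", "truncated3"),
    aa_start = c(10L, 40L, 80L, 30L),
    aa_end = c(40L, 60L, 120L, 90L),
    oncogenic = c(TRUE, FALSE, TRUE, FALSE), stringsAsFactors = FALSE)
  pres <- preservedDomains(chim, domains)
  expect_setequal(pres$name, c("kept5", "kept3"))
  expect_equal(pres$partner[pres$name == "kept5"], "5p")

  # out-of-frame chimera preserves nothing
  oo <- chim; oo$frame_status <- "out_of_frame"
  pres2 <- preservedDomains(oo, domains)
  expect_equal(nrow(pres2), 0L)
  expect_equal(attr(pres2, "reason"), "no ORF")

  # 5'UTR read-through with intact ORF keeps all 3' domains, no 5' domain
  rt <- chim; rt$frame_status <- "five_prime_utr_fusion"; rt$intact_3p_orf <- TRUE
  pres3 <- preservedDomains(rt, domains)
  expect_setequal(pres3$name, c("kept3", "truncated3"))
  expect_true(all(pres3$partner == "3p"))
})

test_that("moving the junction downstream never loses a preserved 5' domain", {
  wx <- workedExamplePair()
  domains <- data.frame(transcript_id = "TXA", name = "d",
                        aa_start = 5L, aa_end = 30L, oncogenic = TRUE,
                        stringsAsFactors = FALSE)
  preservedAt <- function(pos) {
    chim <- chimericTranscript(wx$tx5, list(chrom = "chr7", pos = pos),
                               wx$tx3, wx$bp3)
    if (chim$frame_status != "in_frame") NA else
      nrow(preservedDomains(chim, domains))
  }
  positions <- seq(200L, 680L, by = 3L)  # same phase at every step
  kept <- vapply(positions, preservedAt, numeric(1))
  kept <- kept[!is.na(kept)]
  expect_true(all(diff(kept) >= 0))
})

test_that("driver nomination needs an oncogenic criterion AND recurrence", {
  ev <- makeEvent(LM = paste0("S", 1:7))
  onc <- data.frame(partner = "5p", transcript_id = "TXA", name = "ArfGAP-like",
                    aa_start = 10L, aa_end = 40L, oncogenic = TRUE,
                    stringsAsFactors = FALSE)
  none <- onc[0, ]
  expect_true(nominateDriver(ev, onc, NA_real_, recurrence = 7L)$nominated)
  expect_true(nominateDriver(ev, none, 0.85, recurrence = 2L)$nominated)
  expect_false(nominateDriver(ev, none, 0.85, recurrence = 1L)$nominated)
  expect_false(nominateDriver(ev, none, 0.8, recurrence = 5L)$nominated)  # > not >=
  expect_false(nominateDriver(ev, transform(onc, oncogenic = FALSE),
                              NA_real_, recurrence = 7L)$nominated)
  expect_error(nominateDriver(ev, none, 1.2, recurrence = 3L), "\\[0,1\\]")
  r <- nominateDriver(ev, onc, 0.9, recurrence = 7L)
  expect_length(r$reasons, 3L)  # domain, score and recurrence all listed
})

test_that("chromosomal type compares chromosomes only", {
  expect_equal(classifyType(list(chrom = "chr7"), list(chrom = "chr12")),
               "interchromosomal")
  expect_equal(classifyType(list(chrom = "chr1"), list(chrom = "chr1")),
               "intrachromosomal")
})

test_that("frame status agrees with the translation oracle on random junctions", {
  ann <- buildToyAnnotation(zeroNoiseConfig(97L))
  coding <- Filter(function(m) m@biotype == "protein_coding", ann$txset@models)
  meta <- ann$meta
  set.seed(1234)
  checked <- 0L
  while (checked < 200L) {
    pick <- sample(names(coding), 2L)
    tx5 <- coding[[pick[1]]]; tx3 <- coding[[pick[2]]]
    m5 <- meta[[tx5@transcriptId]]; m3 <- meta[[tx3@transcriptId]]
    # CDS-internal junctions leaving the 3' native tail intact
    ret <- sample(seq(10L, m5$cdsLen - 10L), 1L)
    skp <- sample(seq(3L, m3$cdsLen - 90L), 1L)
    bp5 <- list(chrom = tx5@chrom,
                pos = fusionCascade:::.genomicPos(tx5, m5$u5 + ret))
    bp3 <- list(chrom = tx3@chrom,
                pos = fusionCascade:::.genomicPos(tx3, m3$u5 + skp + 1L))
    ph <- junctionPhases(tx5, bp5, tx3, bp3)
    status <- frameStatus(ph)$frame_status
    oracle <- translationFrameCheck(tx5, bp5, tx3, bp3, ann$seqs)
    expect_equal(status == "in_frame", oracle,
                 info = sprintf("%s->%s ret=%d skp=%d", pick[1], pick[2],
                                ret, skp))
    checked <- checked + 1L
  }
})

test_that("in-frame chimera length arithmetic closes mod 3", {
  ann <- buildToyAnnotation(zeroNoiseConfig(53L))
  coding <- Filter(function(m) m@biotype == "protein_coding", ann$txset@models)
  meta <- ann$meta
  set.seed(55)
  for (i in 1:50) {
    pick <- sample(names(coding), 2L)
    tx5 <- coding[[pick[1]]]; tx3 <- coding[[pick[2]]]
    m5 <- meta[[tx5@transcriptId]]; m3 <- meta[[tx3@transcriptId]]
    ret <- sample(seq(10L, m5$cdsLen - 10L), 1L)
    skp <- sample(seq(3L, m3$cdsLen - 9L), 1L)
    ph <- junctionPhases(
      tx5, list(chrom = tx5@chrom,
                pos = fusionCascade:::.genomicPos(tx5, m5$u5 + ret)),
      tx3, list(chrom = tx3@chrom,
                pos = fusionCascade:::.genomicPos(tx3, m3$u5 + skp + 1L)))
    if (frameStatus(ph)$frame_status == "in_frame") {
      downstream3 <- m3$cdsLen - ph$skipped_cds3_nt
      expect_equal((ph$retained_cds5_nt + downstream3) %% 3L, 0L)
    }
  }
})
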