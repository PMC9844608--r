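# In-code fixtures shared across test files.

# One-row canonical call record.
makeCall <- function(sample_id = "S1", caller = "generic",
                     gene5 = "GENEA", gene3 = "GENEB",
                     chrom5 = "chr1", pos5 = 1000L, strand5 = "+",
                     chrom3 = "chr2", pos3 = 2000L, strand3 = "+",
                     spanning_reads = 6L, crossing_reads = 0L) {
  data.frame(sample_id = sample_id, caller = caller, gene5 = gene5,
             gene3 = gene3, chrom5 = chrom5, pos5 = pos5, strand5 = strand5,
             chrom3 = chrom3, pos3 = pos3, strand3 = strand3,
             spanning_reads = spanning_reads, crossing_reads = crossing_reads,
             stringsAsFactors = FALSE)
}

# Minimal consensus event record.
makeEvent <- function(gene5 = "GENEA", gene3 = "GENEB",
                      chrom5 = "chr1", pos5 = 1000L, strand5 = "+",
                      chrom3 = "chr2", pos3 = 2000L, strand3 = "+",
                      LM = character(0), pCRC = character(0), N = character(0),
                      support = 6) {
  samples <- c(LM, pCRC, N)
  sup <- lapply(rep(support, length.out = length(samples)),
                function(s) c(spanning = s, crossing = 0))
  names(sup) <- samples
  list(gene5 = gene5, gene3 = gene3, chrom5 = chrom5, pos5 = pos5,
       strand5 = strand5, chrom3 = chrom3, pos3 = pos3, strand3 = strand3,
       callers_by_sample = setNames(rep(list(c("arriba", "defuse")),
                                        length(samples)), samples),
       support_by_sample = sup,
       samples_by_class = list(LM = LM, pCRC = pCRC, N = N))
}

# Single-exon coding transcripts engineered so that a junction at
# bp5 = cds5Start + retained - 1 retains `retained` CDS nt and a junction at
# bp3 = cds3Start + skipped skips `skipped` CDS nt.
makePlusTx <- function(id, gene, chrom, exonEnd = 5000L, cdsStart = 101L,
                       cdsLen = 600L) {
  TranscriptModel(id, gene, chrom, "+", cbind(1L, exonEnd),
                  cdsStartGenomic = cdsStart,
                  cdsEndGenomic = cdsStart + cdsLen - 1L)
}

# The worked-example junction: retained 146 CDS nt from the 5' partner,
# 233 CDS nt skipped on the 3' partner, phases (2, 2).
workedExamplePair <- function() {
  tx5 <- makePlusTx("TXA", "GENEA", "chr7")             # CDS 101..700
  tx3 <- makePlusTx("TXB", "GENEB", "chr12", cdsStart = 201L)  # CDS 201..800
  list(tx5 = tx5, bp5 = list(chrom = "chr7", pos = 101L + 146L - 1L),
       tx3 = tx3, bp3 = list(chrom = "chr12", pos = 201L + 233L))
}

# Two-caller sample sheet used in consensus tests.
toySheet <- function() {
  data.frame(sample_id = c("S1", "S2", "S3", "P1", "N1"),
             tissue_class = c("LM", "LM", "LM", "pCRC", "N"),
             patient_id = c("pt1", "pt2", "pt3", "pt1", "pt1"),
             stringsAsFactors = FALSE)
}

zeroNoiseConfig <- function(seed = 11L) {
  simulationConfig(seed = seed,
                   sensitivities = c(arriba = 1, defuse = 1, soapfuse = 1, clc = 1),
                   jitterSd = 0, fpRate = 0)
}

# Run consensus + merge on a generated bundle.
consensusFromBundle <- function(bundle, minTools = 2L, tol = 10L) {
  all <- FusionCallSet(do.call(rbind, lapply(bundle$callSets, fusionCalls)))
  mergeEvents(crossValidate(all, minTools, tol), bundle$sheet, tol)
}
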