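## Synthetic cohort generator: toy annotation (GTF + transcript FASTA +
## domain table), planted fusion calls in every caller dialect with
## configurable sensitivity / breakpoint jitter / false-positive noise, and
## matched qPCR and survival tables. Every planted attribute is recorded in
## a truth table so downstream results can be checked against ground truth.
## Fully deterministic under a fixed seed.

.STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Simulation configuration with cohort defaults
#'
#' Defaults emulate a paired metastasis cohort: 24 patients with a liver
#' metastasis (LM), primary tumour (pCRC) and normal (N) triple each, plus
#' 7 unpaired LM samples. Caller sensitivities, breakpoint jitter (sd in
#' nt) and per-sample false-positive rates model the disagreement between
#' fusion detection algorithms; expression and survival parameters plant a
#' fold-4 expression difference and a hazard ratio of 3 for carriers of the
#' headline fusion.
#'
#' @param seed integer RNG seed; the whole generated bundle is
#'   byte-identical for a fixed seed.
#' @param nPairedPatients number of LM/pCRC/N triples (default 24)
#' @param nUnpairedLM additional LM-only samples (default 7)
#' @param nCodingGenes,nNoncodingGenes,nChrom toy annotation size
#' @param exonCountRange,exonLenRange,intronLenRange,utr5Range,utr3Range
#'   per-transcript structure ranges (nt)
#' @param sensitivities named per-caller detection probabilities in \[0,1\]
#' @param jitterSd sd (nt) of the rounded-normal breakpoint jitter
#' @param fpRate expected private false positives per sample per caller
#' @param fold planted expression fold change (LM over pCRC) for the
#'   headline fusion
#' @param ctNoiseSd,refCtMean,refCtSd,baselineDeltaCt qPCR noise model
#'   (cycles)
#' @param nQpcrPerGroup qPCR samples per group
#' @param baselineHazard exponential baseline hazard (per month)
#' @param hazardRatio multiplicative hazard for fusion-positive samples
#' @param censoringFraction fraction of samples right-censored
#' @return a `SimulationConfig` list.
#' @export
simulationConfig <- function(seed = 1L,
                             nPairedPatients = 24L, nUnpairedLM = 7L,
                             nCodingGenes = 20L, nNoncodingGenes = 2L,
                             nChrom = 3L,
                             exonCountRange = c(3L, 8L),
                             exonLenRange = c(150L, 300L),
                             intronLenRange = c(60L, 400L),
                             utr5Range = c(60L, 150L),
                             utr3Range = c(60L, 200L),
                             sensitivities = c(arriba = 0.95, defuse = 0.9,
                                               soapfuse = 0.85, clc = 0.9),
                             jitterSd = 2, fpRate = 0.5,
                             fold = 4, ctNoiseSd = 0.3,
                             refCtMean = 20, refCtSd = 0.3,
                             baselineDeltaCt = 5, nQpcrPerGroup = 12L,
                             baselineHazard = 0.03, hazardRatio = 3,
                             censoringFraction = 0.3) {
  sensitivities <- unlist(sensitivities)  # accept YAML-style nested lists
  if (any(sensitivities < 0 | sensitivities > 1))
    .stopf("sensitivities must lie in [0,1]")
  if (fold <= 0) .stopf("expression fold change must be > 0")
  if (censoringFraction < 0 || censoringFraction > 1)
    .stopf("censoringFraction must lie in [0,1]")
  if (exonCountRange[1] < 1L || exonLenRange[1] < 90L)
    .stopf("infeasible exon ranges: need >= 1 exon of >= 90 nt")
  structure(list(
    seed = as.integer(seed), nPairedPatients = as.integer(nPairedPatients),
    nUnpairedLM = as.integer(nUnpairedLM),
    nCodingGenes = as.integer(nCodingGenes),
    nNoncodingGenes = as.integer(nNoncodingGenes), nChrom = as.integer(nChrom),
    exonCountRange = exonCountRange, exonLenRange = exonLenRange,
    intronLenRange = intronLenRange, utr5Range = utr5Range,
    utr3Range = utr3Range, sensitivities = sensitivities,
    jitterSd = jitterSd, fpRate = fpRate, fold = fold,
    ctNoiseSd = ctNoiseSd, refCtMean = refCtMean, refCtSd = refCtSd,
    baselineDeltaCt = baselineDeltaCt, nQpcrPerGroup = as.integer(nQpcrPerGroup),
    baselineHazard = baselineHazard, hazardRatio = hazardRatio,
    censoringFraction = censoringFraction), class = "SimulationConfig")
}

#' Sample sheet implied by a simulation config
#'
#' @param config a [simulationConfig()]
#' @return data.frame with `sample_id`, `tissue_class`, `patient_id`.
#' @export
cohortSampleSheet <- function(config) {
  pid <- sprintf("P%02d", seq_len(config$nPairedPatients))
  paired <- data.frame(
    sample_id = c(paste0("LM_", pid), paste0("PT_", pid), paste0("NO_", pid)),
    tissue_class = rep(c("LM", "pCRC", "N"), each = config$nPairedPatients),
    patient_id = rep(pid, 3L), stringsAsFactors = FALSE)
  uid <- sprintf("U%02d", seq_len(config$nUnpairedLM))
  unpaired <- data.frame(sample_id = paste0("LM_", uid),
                         tissue_class = "LM", patient_id = uid,
                         stringsAsFactors = FALSE)
  rbind(paired, unpaired)
}

.randSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

## CDS of length L (multiple of 3): ATG + non-stop codons + TAA.
.randCds <- function(L) {
  stopifnot(L %% 3 == 0, L >= 9)
  codons <- character(L / 3 - 2L)
  for (i in seq_along(codons)) {
    repeat {
      cd <- .randSeq(3L)
      if (!cd %in% .STOP_CODONS) break
    }
    codons[i] <- cd
  }
  paste0("ATG", paste(codons, collapse = ""), "TAA")
}

.rc <- function(s) as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

#' Build the toy annotation bundle
#'
#' Generates ~20 protein-coding and >= 2 non-coding transcripts across 3
#' toy chromosomes. Every CDS begins with ATG, ends with a stop codon, has
#' length divisible by 3 and no internal in-frame stop. The transcript
#' FASTA holds mature (spliced) transcript sequences consistent with the
#' GTF exon structure. The domain table places oncogenic domains on the
#' planted driver partners (an ArfGAP-like domain upstream of the headline
#' junction on the 5' partner, a CBF-like domain downstream on the 3'
#' partner, an SPT4-like domain on the read-through 3' partner) plus
#' non-oncogenic background domains. The default planted-fusion catalog is
#' derived alongside and returned with the annotation.
#'
#' @param config a [simulationConfig()]
#' @param dir optional directory; when given, writes `annotation.gtf`,
#'   `transcripts.fa` and `domains.tsv` there.
#' @return list with `txset` ([TranscriptSet-class]), `seqs`
#'   (`DNAStringSet` of mature transcript sequences), `domains`
#'   (data.frame), `catalog` (planted-fusion data.frame) and `files`
#'   (paths, when `dir` was given).
#' @export
buildToyAnnotation <- function(config = simulationConfig(), dir = NULL) {
  set.seed(config$seed)
  nCod <- config$nCodingGenes; nNc <- config$nNoncodingGenes
  genes <- c(sprintf("GENE%02d", seq_len(nCod)), sprintf("NC%02d", seq_len(nNc)))
  chroms <- sprintf("chrT%d", ((seq_along(genes) - 1L) %% config$nChrom) + 1L)
  strands <- rep(c("+", "-"), length.out = length(genes))
  nextPos <- setNames(rep(1000L, config$nChrom), sprintf("chrT%d", seq_len(config$nChrom)))

  models <- list(); seqs <- character(0); meta <- list()
  for (i in seq_along(genes)) {
    g <- genes[i]; coding <- i <= nCod
    k <- sample(config$exonCountRange[1]:config$exonCountRange[2], 1L)
    w <- sample(config$exonLenRange[1]:config$exonLenRange[2], k, replace = TRUE)
    ic <- if (k > 1L) sample(config$intronLenRange[1]:config$intronLenRange[2],
                             k - 1L, replace = TRUE) else integer(0)
    start0 <- nextPos[[chroms[i]]]
    st <- integer(k); en <- integer(k)
    p <- start0
    for (j in seq_len(k)) {
      st[j] <- p; en[j] <- p + w[j] - 1L
      p <- en[j] + 1L + if (j < k) ic[j] else 0L
    }
    nextPos[[chroms[i]]] <- en[k] + sample(500:1500, 1L)
    L <- sum(w)
    txid <- paste0("TX_", g)
    if (coding) {
      u5 <- sample(config$utr5Range[1]:config$utr5Range[2], 1L)
      u3 <- sample(config$utr3Range[1]:config$utr3Range[2], 1L)
      cdsLen <- L - u5 - u3
      cdsLen <- cdsLen - (cdsLen %% 3L)
      if (cdsLen < 90L) {  # shrink UTRs for short transcripts
        u5 <- 30L; u3 <- 30L
        cdsLen <- (L - 60L) %/% 3L * 3L
      }
      u3 <- L - u5 - cdsLen
      mature <- paste0(.randSeq(u5), .randCds(cdsLen), .randSeq(u3))
      tx0 <- TranscriptModel(txid, g, chroms[i], strands[i], cbind(st, en))
      g1 <- .genomicPos(tx0, u5 + 1L); g2 <- .genomicPos(tx0, u5 + cdsLen)
      tx <- TranscriptModel(txid, g, chroms[i], strands[i], cbind(st, en),
                            cdsStartGenomic = min(g1, g2),
                            cdsEndGenomic = max(g1, g2))
      meta[[txid]] <- list(u5 = u5, cdsLen = cdsLen)
    } else {
      mature <- .randSeq(L)
      tx <- TranscriptModel(txid, g, chroms[i], strands[i], cbind(st, en))
      meta[[txid]] <- list(u5 = NA_integer_, cdsLen = NA_integer_)
    }
    models[[txid]] <- tx
    seqs[txid] <- mature
  }
  txset <- TranscriptSet(unname(models))
  seqs <- Biostrings::DNAStringSet(seqs)

  catalog <- .defaultCatalog(config, txset, meta)
  domains <- .placeDomains(txset, meta, catalog)

  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    gtf <- file.path(dir, "annotation.gtf")
    fa <- file.path(dir, "transcripts.fa")
    dom <- file.path(dir, "domains.tsv")
    writeGtf(txset, gtf)
    Biostrings::writeXStringSet(seqs, fa)
    write.table(data.frame(transcript_id = domains$transcript_id,
                           domain_name = domains$name,
                           aa_start = domains$aa_start,
                           aa_end = domains$aa_end,
                           oncogenic = as.integer(domains$oncogenic)),
                dom, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(gtf = gtf, fasta = fa, domains = dom)
  }
  list(txset = txset, seqs = seqs, domains = domains, catalog = catalog,
       meta = meta, files = files)
}

## Genomic positions of CDS-internal offsets with a given mod-3 residue of
## the "retained"/"skipped" count, restricted to a safe interior window.
.pickCdsPos <- function(tx, meta, role = c("retained", "skipped"),
                        residue = NULL, lo = 0.2, hi = 0.8) {
  role <- match.arg(role)
  u5 <- meta$u5; cdsLen <- meta$cdsLen
  span <- floor(cdsLen * c(lo, hi))
  counts <- span[1]:span[2]  # candidate retained/skipped counts
  if (!is.null(residue)) counts <- counts[counts %% 3L == residue]
  cnt <- counts[sample(length(counts), 1L)]
  ## retained n  => breakpoint at CDS offset n (last base of 5' segment)
  ## skipped n   => breakpoint at CDS offset n+1 (first base of 3' segment)
  off <- u5 + if (role == "retained") cnt else cnt + 1L
  list(gpos = .genomicPos(tx, off), count = cnt)
}

## The default planted-fusion catalog: one entry per scenario the filter
## cascade and annotation must handle.
.defaultCatalog <- function(config, txset, meta) {
  tx <- function(g) getTranscript(txset, paste0("TX_", g))
  entry <- function(id, g5, g3, frame, class, nLM = 0L, nP = 0L, nN = 0L,
                    support = 8, onlyCaller = NA_character_,
                    driverScore = NA_real_, oncogenic = FALSE) {
    t5 <- tx(g5); t3 <- tx(g3)
    if (frame == "in_frame") {
      p5 <- .pickCdsPos(t5, meta[[t5@transcriptId]], "retained")
      ph <- p5$count %% 3L
      p3 <- .pickCdsPos(t3, meta[[t3@transcriptId]], "skipped", residue = ph,
                        lo = 0.15, hi = 0.6)
      pos5 <- p5$gpos; pos3 <- p3$gpos
    } else if (frame == "out_of_frame") {
      p5 <- .pickCdsPos(t5, meta[[t5@transcriptId]], "retained")
      ph <- (p5$count + 1L) %% 3L
      p3 <- .pickCdsPos(t3, meta[[t3@transcriptId]], "skipped", residue = ph,
                        lo = 0.15, hi = 0.6)
      pos5 <- p5$gpos; pos3 <- p3$gpos
    } else if (frame == "five_prime_utr_fusion") {
      m5 <- meta[[t5@transcriptId]]
      pos5 <- .genomicPos(t5, max(1L, m5$u5 %/% 2L))
      m3 <- meta[[t3@transcriptId]]
      pos3 <- .genomicPos(t3, max(1L, m3$u5 - 4L))  # just upstream of ATG
    } else {  # noncoding partner: mid-transcript positions
      m5 <- meta[[t5@transcriptId]]
      pos5 <- if (!is.na(m5$cdsLen))
        .pickCdsPos(t5, m5, "retained")$gpos
      else .genomicPos(t5, 50L)
      pos3 <- .genomicPos(t3, 50L)
    }
    data.frame(fusion_id = id, gene5 = g5, gene3 = g3,
               tx5 = t5@transcriptId, tx3 = t3@transcriptId,
               chrom5 = t5@chrom, pos5 = pos5, strand5 = t5@strand,
               chrom3 = t3@chrom, pos3 = pos3, strand3 = t3@strand,
               frame_truth = frame, class_truth = class,
               n_LM = nLM, n_pCRC = nP, n_N = nN,
               mean_support = support, only_caller = onlyCaller,
               driver_score = driverScore, oncogenic_truth = oncogenic,
               stringsAsFactors = FALSE)
  }
  rbind(
    ## headline driver: interchromosomal, in-frame, 7 LM carriers,
    ## oncogenic domains preserved on both sides
    entry("FUS01", "GENE01", "GENE02", "in_frame", "LM_unique",
          nLM = 7L, support = 8, oncogenic = TRUE),
    ## read-through: 5'UTR joined to an intact downstream ORF, 8 LM carriers
    entry("FUS02", "GENE03", "GENE06", "five_prime_utr_fusion", "LM_unique",
          nLM = 8L, support = 6, oncogenic = TRUE),
    ## out-of-frame passenger
    entry("FUS03", "GENE04", "GENE05", "out_of_frame", "LM_unique",
          nLM = 3L, support = 7),
    ## primary-tumour-only fusion
    entry("FUS04", "GENE07", "GENE08", "in_frame", "pCRC_unique",
          nP = 4L, support = 6),
    ## shared between LM and pCRC
    entry("FUS05", "GENE09", "GENE10", "in_frame", "common",
          nLM = 3L, nP = 3L, support = 6),
    ## present in normal tissue: excluded by the cascade
    entry("FUS06", "GENE11", "GENE12", "in_frame", "normal_present",
          nLM = 2L, nN = 2L, support = 6),
    ## non-coding 3' partner: fails the coding filter
    entry("FUS07", "GENE13", "NC01", "noncoding", "LM_unique",
          nLM = 2L, support = 6),
    ## below the read-support threshold (on average)
    entry("FUS08", "GENE15", "GENE16", "in_frame", "LM_unique",
          nLM = 2L, support = 3),
    ## reported by a single caller: fails cross-validation
    entry("FUS09", "GENE17", "GENE18", "in_frame", "LM_unique",
          nLM = 3L, support = 6, onlyCaller = "arriba"),
    ## no domain, nominated via external driver score
    entry("FUS10", "GENE19", "GENE20", "in_frame", "LM_unique",
          nLM = 2L, support = 6, driverScore = 0.85))
}

## Domain table consistent with the catalog's oncogenic-domain truth.
.placeDomains <- function(txset, meta, catalog) {
  rows <- list()
  add <- function(txid, name, s, e, onc) {
    rows[[length(rows) + 1L]] <<- data.frame(
      transcript_id = txid, name = name, aa_start = as.integer(s),
      aa_end = as.integer(e), oncogenic = onc, stringsAsFactors = FALSE)
  }
  phaseOf <- function(entry) {
    tx5 <- getTranscript(txset, entry$tx5); tx3 <- getTranscript(txset, entry$tx3)
    junctionPhases(tx5, list(chrom = entry$chrom5, pos = entry$pos5),
                   tx3, list(chrom = entry$chrom3, pos = entry$pos3))
  }
  ## FUS01: ArfGAP-like before the junction on the 5' partner, CBF-like
  ## after it on the 3' partner -> both preserved and oncogenic.
  e1 <- catalog[catalog$fusion_id == "FUS01", ]
  ph1 <- phaseOf(e1)
  J5 <- ph1$retained_cds5_nt %/% 3L
  A3 <- ph1$skipped_cds3_nt %/% 3L + 1L
  aa5 <- meta[[e1$tx5]]$cdsLen / 3L
  aa3 <- meta[[e1$tx3]]$cdsLen / 3L
  add(e1$tx5, "ArfGAP-like", max(1L, J5 %/% 4L), max(2L, J5 - 2L), TRUE)
  add(e1$tx3, "CBF-like", A3 + 1L, min(aa3 - 1L, A3 + 20L), TRUE)
  ## a 5' domain straddling the junction -> truncated, not preserved
  add(e1$tx5, "PH-like", max(1L, J5 - 5L), min(aa5 - 1L, J5 + 10L), FALSE)
  ## FUS02 read-through: SPT4-like anywhere on the intact 3' ORF
  e2 <- catalog[catalog$fusion_id == "FUS02", ]
  aa3 <- meta[[e2$tx3]]$cdsLen / 3L
  add(e2$tx3, "SPT4-like", 5L, min(aa3 - 1L, 40L), TRUE)
  ## FUS04: a preserved but non-oncogenic domain on the 3' partner
  e4 <- catalog[catalog$fusion_id == "FUS04", ]
  ph4 <- phaseOf(e4)
  A3 <- ph4$skipped_cds3_nt %/% 3L + 1L
  aa3 <- meta[[e4$tx3]]$cdsLen / 3L
  add(e4$tx3, "WD-repeat-like", A3 + 1L, min(aa3 - 1L, A3 + 15L), FALSE)
  ## background domains on otherwise uninvolved genes
  add("TX_GENE14", "Kinase-like", 10L, 60L, TRUE)
  add("TX_GENE18", "Zinc-finger-like", 8L, 30L, FALSE)
  do.call(rbind, rows)
}

#' Plant fusions and emit per-caller call files
#'
#' For each planted fusion and each carrier sample, each caller reports the
#' junction with its configured sensitivity; reported breakpoints are
#' jittered by a rounded normal (`jitterSd`), and spanning-read support is
#' drawn once per fusion per sample as `5 + Poisson(mean - 5)` when the
#' planted mean is at least 5 (keeping values at the acceptance-threshold
#' boundary common) or a zero-truncated `Poisson(mean)` otherwise. Private
#' false positives are added per caller per sample at rate `fpRate`. The
#' truth table records every planted attribute, the support actually drawn
#' per sample, and how many callers reported each carrier.
#'
#' @param config a [simulationConfig()]
#' @param annotation output of [buildToyAnnotation()]
#' @param dir optional directory; when given, writes one dialect TSV per
#'   caller (`calls_<caller>.tsv`), `sample_sheet.tsv` and `truth.tsv`.
#' @return list with `callSets` (named list of [FusionCallSet-class], one
#'   per caller), `sheet`, `truth` (data.frame), `driverScores` (named
#'   vector) and `files`.
#' @export
plantAndEmitCalls <- function(config, annotation, dir = NULL) {
  set.seed(config$seed + 1L)
  catalog <- annotation$catalog
  txset <- annotation$txset
  sheet <- cohortSampleSheet(config)
  byClass <- split(sheet$sample_id, sheet$tissue_class)
  callers <- names(config$sensitivities)

  rows <- list()   # canonical call rows per caller
  truth <- list()
  emitCall <- function(caller, sample, entry, support, jitter = TRUE) {
    j <- function() if (jitter && config$jitterSd > 0)
      as.integer(round(rnorm(1, 0, config$jitterSd))) else 0L
    data.frame(sample_id = sample, caller = caller,
               gene5 = entry$gene5, gene3 = entry$gene3,
               chrom5 = entry$chrom5, pos5 = max(1L, entry$pos5 + j()),
               strand5 = entry$strand5,
               chrom3 = entry$chrom3, pos3 = max(1L, entry$pos3 + j()),
               strand3 = entry$strand3,
               spanning_reads = support, crossing_reads = rpois(1, 2),
               stringsAsFactors = FALSE)
  }

  for (i in seq_len(nrow(catalog))) {
    entry <- catalog[i, ]
    carriers <- c(
      if (entry$n_LM > 0) sample(byClass$LM, entry$n_LM),
      if (entry$n_pCRC > 0) sample(byClass$pCRC, entry$n_pCRC),
      if (entry$n_N > 0) sample(byClass$N, entry$n_N))
    reporting <- if (is.na(entry$only_caller)) callers else entry$only_caller
    for (s in carriers) {
      support <- if (entry$mean_support >= 5)
        5L + rpois(1, entry$mean_support - 5) else
        max(1L, rpois(1, entry$mean_support))
      nRep <- 0L
      for (cl in reporting) {
        if (runif(1) <= config$sensitivities[[cl]]) {
          rows[[length(rows) + 1L]] <- emitCall(cl, s, entry, support)
          nRep <- nRep + 1L
        }
      }
      truth[[length(truth) + 1L]] <- cbind(
        entry[, c("fusion_id", "gene5", "gene3", "chrom5", "pos5", "strand5",
                  "chrom3", "pos3", "strand3", "frame_truth", "class_truth",
                  "oncogenic_truth", "driver_score")],
        data.frame(sample_id = s,
                   tissue_class = sheet$tissue_class[sheet$sample_id == s],
                   support = support, n_callers = nRep,
                   stringsAsFactors = FALSE))
    }
  }

  ## private false positives: random coding gene pairs at exonic positions
  codingIds <- names(Filter(function(m) m@biotype == "protein_coding",
                            annotation$txset@models))
  if (config$fpRate > 0) {
    for (s in sheet$sample_id) {
      for (cl in callers) {
        nFP <- rpois(1, config$fpRate)
        plantedPairs <- paste(catalog$gene5, catalog$gene3)
        for (f in seq_len(nFP)) {
          repeat {  # private noise: never alias a planted gene pair
            pick <- sample(codingIds, 2L)
            g <- vapply(pick, function(p) getTranscript(txset, p)@gene,
                        character(1))
            if (!paste(g[1], g[2]) %in% plantedPairs) break
          }
          t5 <- getTranscript(txset, pick[1]); t3 <- getTranscript(txset, pick[2])
          off5 <- sample(sum(IRanges::width(t5@exons)), 1L)
          off3 <- sample(sum(IRanges::width(t3@exons)), 1L)
          fp <- data.frame(fusion_id = "FP", gene5 = t5@gene, gene3 = t3@gene,
                           chrom5 = t5@chrom, pos5 = .genomicPos(t5, off5),
                           strand5 = t5@strand, chrom3 = t3@chrom,
                           pos3 = .genomicPos(t3, off3), strand3 = t3@strand,
                           stringsAsFactors = FALSE)
          rows[[length(rows) + 1L]] <- emitCall(cl, s, fp,
                                                support = sample(1:6, 1L),
                                                jitter = FALSE)
        }
      }
    }
  }

  calls <- if (length(rows)) do.call(rbind, rows) else .emptyCallTable()
  callSets <- lapply(setNames(callers, callers), function(cl)
    FusionCallSet(calls[calls$caller == cl, , drop = FALSE]))
  truth <- if (length(truth)) do.call(rbind, truth) else NULL
  scores <- catalog$driver_score
  names(scores) <- paste0(catalog$gene5, "--", catalog$gene3)
  scores <- scores[!is.na(scores)]

  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- c(sheet = file.path(dir, "sample_sheet.tsv"),
               truth = file.path(dir, "truth.tsv"))
    write.table(sheet, files[["sheet"]], sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(truth, files[["truth"]], sep = "\t", quote = FALSE,
                row.names = FALSE)
    for (cl in callers) {
      path <- file.path(dir, sprintf("calls_%s.tsv", cl))
      .writeDialect(callSets[[cl]], path, cl)
      files[[paste0("calls_", cl)]] <- path
    }
  }
  list(callSets = callSets, sheet = sheet, truth = truth,
       driverScores = scores, files = files)
}

## Write a FusionCallSet in a caller's dialect layout (inverse of
## readCallerCalls for round-trip testing and realistic inputs).
.writeDialect <- function(x, path, dialect) {
  df <- fusionCalls(x)
  out <- switch(dialect,
    generic = data.frame(
      sample_id = df$sample_id, gene5 = df$gene5, gene3 = df$gene3,
      breakpoint5 = sprintf("%s:%d:%s", df$chrom5, df$pos5, df$strand5),
      breakpoint3 = sprintf("%s:%d:%s", df$chrom3, df$pos3, df$strand3),
      spanning_reads = df$spanning_reads, crossing_reads = df$crossing_reads),
    arriba = data.frame(
      sample_id = df$sample_id, gene1 = df$gene5, gene2 = df$gene3,
      breakpoint1 = sprintf("%s:%d", df$chrom5, df$pos5),
      breakpoint2 = sprintf("%s:%d", df$chrom3, df$pos3),
      strand1 = df$strand5, strand2 = df$strand3,
      split_reads = df$spanning_reads, discordant_mates = df$crossing_reads),
    defuse = data.frame(
      sample_id = df$sample_id, gene_name1 = df$gene5, gene_name2 = df$gene3,
      genomic_break_pos1 = sprintf("%s:%d", df$chrom5, df$pos5),
      genomic_break_pos2 = sprintf("%s:%d", df$chrom3, df$pos3),
      genomic_strand1 = df$strand5, genomic_strand2 = df$strand3,
      span_count = df$crossing_reads, splitr_count = df$spanning_reads),
    soapfuse = data.frame(
      sample_id = df$sample_id, up_gene = df$gene5, up_chr = df$chrom5,
      up_hit_pos = df$pos5, up_strand = df$strand5, dw_gene = df$gene3,
      dw_chr = df$chrom3, dw_hit_pos = df$pos3, dw_strand = df$strand3,
      junc_reads = df$spanning_reads, span_reads = df$crossing_reads),
    clc = data.frame(
      sample_id = df$sample_id, five_gene = df$gene5, three_gene = df$gene3,
      five_breakpoint = sprintf("%s:%d:%s", df$chrom5, df$pos5, df$strand5),
      three_breakpoint = sprintf("%s:%d:%s", df$chrom3, df$pos3, df$strand3),
      fusion_reads = df$spanning_reads),
    .stopf("unknown dialect: %s", dialect))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Emit matched qPCR and survival tables
#'
#' qPCR: reference Ct ~ Normal(refCtMean, refCtSd); target Ct = reference +
#' baseline delta Ct - log2(fold) for metastatic (mCRC) samples, plus
#' Normal(0, ctNoiseSd) noise, for `nQpcrPerGroup` samples per group.
#' Survival: times exponential with hazard `baselineHazard *
#' hazardRatio^fusion_positive` over the LM samples, where positivity is
#' carriage of the headline planted fusion; a `censoringFraction` of
#' samples is right-censored uniformly on (0, t).
#'
#' @param config a [simulationConfig()]
#' @param truth truth table from [plantAndEmitCalls()]
#' @param dir optional directory; writes `ct_table.csv` and `survival.csv`.
#' @return list with `ct` and `surv` data.frames and `files`.
#' @export
emitExpressionAndSurvival <- function(config, truth, dir = NULL) {
  set.seed(config$seed + 2L)
  sheet <- cohortSampleSheet(config)
  lm <- sheet$sample_id[sheet$tissue_class == "LM"]
  pt <- sheet$sample_id[sheet$tissue_class == "pCRC"]
  carriers <- unique(truth$sample_id[truth$fusion_id == "FUS01"])

  nQ <- config$nQpcrPerGroup
  qs <- c(head(c(intersect(lm, carriers), setdiff(lm, carriers)), nQ),
          head(pt, nQ))
  grp <- rep(c("mCRC", "pCRC"), each = nQ)
  refCt <- rnorm(2 * nQ, config$refCtMean, config$refCtSd)
  target <- refCt + config$baselineDeltaCt -
    log2(config$fold) * (grp == "mCRC") + rnorm(2 * nQ, 0, config$ctNoiseSd)
  ct <- data.frame(sample_id = qs, group = grp,
                   target_ct = target, reference_ct = refCt,
                   stringsAsFactors = FALSE)

  pos <- lm %in% carriers
  rate <- config$baselineHazard * config$hazardRatio^pos
  t <- rexp(length(lm), rate)
  cens <- runif(length(lm)) < config$censoringFraction
  time <- ifelse(cens, runif(length(lm), 0, t), t)
  surv <- data.frame(sample_id = lm, time_months = time,
                     event = as.integer(!cens), fusion_positive = pos,
                     stringsAsFactors = FALSE)

  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- c(ct = file.path(dir, "ct_table.csv"),
               surv = file.path(dir, "survival.csv"))
    write.csv(ct, files[["ct"]], row.names = FALSE, quote = FALSE)
    write.csv(surv, files[["surv"]], row.names = FALSE, quote = FALSE)
  }
  list(ct = ct, surv = surv, files = files)
}

#' Translation oracle for junction frame status
#'
#' Sequence-level check that the 5' open reading frame continues into the
#' 3' partner's native frame: the chimeric cDNA (5' transcript through the
#' breakpoint, then the 3' transcript from its breakpoint to its end) is
#' translated from the 5' CDS start, and the chimera is called in-frame iff
#' the native C-terminal peptide of the 3' protein appears in that
#' translation. A frame shift makes this astronomically unlikely for
#' random coding sequence, so the check is independent of the phase
#' arithmetic in [junctionPhases()].
#'
#' Preconditions: both partners protein-coding, `bp5` inside the 5' CDS and
#' `bp3` inside the 3' CDS upstream of its final ~20 codons (so the native
#' tail is retained).
#'
#' @param tx5,tx3 [TranscriptModel-class] partners
#' @param bp5,bp3 breakpoint lists (`chrom`, `pos`)
#' @param seqs `DNAStringSet` of mature transcript sequences
#' @return `TRUE` iff the translation continues the 5' ORF into the 3' CDS
#'   without frameshift.
#' @export
translationFrameCheck <- function(tx5, bp5, tx3, bp3, seqs) {
  off5 <- .txOffset(tx5, bp5$pos)
  off3 <- .txOffset(tx3, bp3$pos)
  s5 <- as.character(seqs[[tx5@transcriptId]])
  s3 <- as.character(seqs[[tx3@transcriptId]])
  chim <- paste0(substr(s5, 1L, off5), substr(s3, off3, nchar(s3)))
  c5 <- .cdsOffsets(tx5); c3 <- .cdsOffsets(tx3)
  orf <- substr(chim, c5[["first"]], nchar(chim))
  orf <- substr(orf, 1L, 3L * (nchar(orf) %/% 3L))
  prot <- suppressWarnings(as.character(
    Biostrings::translate(Biostrings::DNAString(orf), if.fuzzy.codon = "X")))
  native <- substr(s3, c3[["first"]], c3[["last"]])
  natProt <- suppressWarnings(as.character(
    Biostrings::translate(Biostrings::DNAString(native))))
  ## native C-terminal peptide, excluding the stop
  tailPep <- substr(natProt, max(1L, nchar(natProt) - 11L), nchar(natProt) - 1L)
  grepl(tailPep, prot, fixed = TRUE)
}

#' Generate the complete synthetic input bundle
#'
#' Convenience wrapper running [buildToyAnnotation()],
#' [plantAndEmitCalls()] and [emitExpressionAndSurvival()] under one
#' config, optionally writing every file the pipeline consumes.
#'
#' @param config a [simulationConfig()]
#' @param dir optional output directory
#' @return list combining all three generators' outputs.
#' @export
simulateCohort <- function(config = simulationConfig(), dir = NULL) {
  ann <- buildToyAnnotation(config, dir)
  calls <- plantAndEmitCalls(config, ann, dir)
  quant <- emitExpressionAndSurvival(config, calls$truth, dir)
  c(ann[c("txset", "seqs", "domains", "catalog")],
    calls[c("callSets", "sheet", "truth", "driverScores")],
    quant[c("ct", "surv")],
    list(files = c(ann$files, calls$files, quant$files)))
}
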