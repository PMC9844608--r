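## Junction-to-transcript mapping, reading-frame phase arithmetic, domain
## retention and driver nomination.
##
## Coordinates are 1-based closed throughout. A breakpoint is the last
## transcribed base of the 5' segment / the first transcribed base of the 3'
## segment. Exon ordinals and transcript offsets are counted in transcript
## orientation: for '-' strand transcripts the first exon is the one with the
## highest genomic coordinates and offsets run high -> low.

## Transcript-orientation exon list: IRanges rows ordered as transcribed.
.orientedExons <- function(tx) {
  ex <- tx@exons
  if (tx@strand == "-") ex <- rev(ex)
  ex
}

#' Map a genomic breakpoint onto a transcript
#'
#' @param bp list with `chrom`, `pos`, and optionally `strand`
#' @param tx a [TranscriptModel-class]
#' @return For an exonic position, a list with `exonic = TRUE`, `exon`
#'   (1-based ordinal in transcript orientation) and `offset` (1-based
#'   cumulative transcribed position within the mature transcript).
#'   For an intronic/intergenic position, `list(exonic = FALSE)`.
#'   A chromosome mismatch is an error.
#' @export
mapBreakpointToTranscript <- function(bp, tx) {
  stopifnot(is(tx, "TranscriptModel"))
  if (!identical(bp$chrom, tx@chrom))
    .stopf("breakpoint chromosome %s does not match transcript %s on %s",
           bp$chrom, tx@transcriptId, tx@chrom)
  ex <- .orientedExons(tx)
  st <- IRanges::start(ex); en <- IRanges::end(ex)
  w <- IRanges::width(ex)
  cum <- c(0L, cumsum(w))
  pos <- as.integer(bp$pos)
  for (i in seq_along(ex)) {
    if (pos >= st[i] && pos <= en[i]) {
      within <- if (tx@strand == "+") pos - st[i] + 1L else en[i] - pos + 1L
      return(list(exonic = TRUE, exon = i, offset = cum[i] + within))
    }
  }
  list(exonic = FALSE)
}

## Transcript offset of a genomic position; errors if not exonic.
.txOffset <- function(tx, gpos) {
  m <- mapBreakpointToTranscript(list(chrom = tx@chrom, pos = gpos), tx)
  if (!m$exonic)
    .stopf("position %s:%d is not exonic in %s", tx@chrom, gpos, tx@transcriptId)
  m$offset
}

## Genomic position at a transcript offset (inverse of .txOffset).
.genomicPos <- function(tx, offset) {
  ex <- .orientedExons(tx)
  w <- IRanges::width(ex)
  cum <- c(0L, cumsum(w))
  i <- findInterval(offset - 1L, cum)
  if (offset < 1L || offset > sum(w)) .stopf("offset %d outside transcript", offset)
  within <- offset - cum[i]
  if (tx@strand == "+") IRanges::start(ex)[i] + within - 1L
  else IRanges::end(ex)[i] - within + 1L
}

## CDS first/last offsets in transcript coordinates (NA for noncoding).
.cdsOffsets <- function(tx) {
  if (tx@biotype != "protein_coding") return(c(first = NA_integer_, last = NA_integer_))
  if (tx@strand == "+") {
    c(first = .txOffset(tx, tx@cdsStartGenomic), last = .txOffset(tx, tx@cdsEndGenomic))
  } else {
    c(first = .txOffset(tx, tx@cdsEndGenomic), last = .txOffset(tx, tx@cdsStartGenomic))
  }
}

#' Reading-frame phases at a fusion junction
#'
#' For a junction joining `bp5` (last base of the 5' segment on `tx5`) to
#' `bp3` (first base of the 3' segment on `tx3`):
#' `retained_cds5_nt` counts the CDS nucleotides of `tx5` from its CDS start
#' through `bp5` inclusive (0 when `bp5` lies in the 5'UTR), and
#' `skipped_cds3_nt` counts the CDS nucleotides of `tx3` strictly upstream
#' of `bp3` (0 when `bp3` is at or upstream of the CDS start). The phases
#' are the mod-3 residues; the 3' coding sequence continues in its native
#' frame exactly when the phases are equal.
#'
#' @param tx5,tx3 [TranscriptModel-class] partners (must be protein_coding)
#' @param bp5,bp3 breakpoint lists (`chrom`, `pos`)
#' @return list with `retained_cds5_nt`, `skipped_cds3_nt`, `phase5`,
#'   `phase3`, `utr5` (bp5 upstream of the tx5 CDS start) and `utr3` (bp3 at
#'   or upstream of the tx3 CDS start, i.e. the downstream ORF is intact).
#' @export
junctionPhases <- function(tx5, bp5, tx3, bp3) {
  if (tx5@biotype != "protein_coding" || tx3@biotype != "protein_coding")
    .stopf("junctionPhases requires protein_coding partners")
  m5 <- mapBreakpointToTranscript(bp5, tx5)
  m3 <- mapBreakpointToTranscript(bp3, tx3)
  if (!m5$exonic || !m3$exonic) .stopf("breakpoint not exonic")
  c5 <- .cdsOffsets(tx5); c3 <- .cdsOffsets(tx3)
  utr5 <- m5$offset < c5[["first"]]
  retained <- if (utr5) 0L else
    min(m5$offset, c5[["last"]]) - c5[["first"]] + 1L
  utr3 <- m3$offset <= c3[["first"]]
  skipped <- if (utr3) 0L else
    min(m3$offset - 1L, c3[["last"]]) - c3[["first"]] + 1L
  list(retained_cds5_nt = as.integer(retained),
       skipped_cds3_nt = as.integer(skipped),
       phase5 = as.integer(retained %% 3L), phase3 = as.integer(skipped %% 3L),
       utr5 = utr5, utr3 = utr3,
       exon5 = m5$exon, exon3 = m3$exon,
       offset5 = m5$offset, offset3 = m3$offset)
}

#' Frame status of a chimeric transcript
#'
#' `noncoding` when either partner lacks a CDS; `five_prime_utr_fusion`
#' when the 5' breakpoint lies upstream of the 5' partner's CDS start (a
#' read-through-like junction), with `intact_3p_orf` true when the 3'
#' breakpoint is at or upstream of the 3' partner's CDS start so the
#' downstream ORF is complete; otherwise `in_frame` iff the two phases are
#' equal, `out_of_frame` otherwise.
#'
#' @param phases output of [junctionPhases()], or `NULL` with
#'   `coding5`/`coding3` set to `FALSE` for a non-coding partner
#' @param coding5,coding3 are the partners protein-coding?
#' @return list with `frame_status` and `intact_3p_orf` (NA unless
#'   `five_prime_utr_fusion`).
#' @export
frameStatus <- function(phases, coding5 = TRUE, coding3 = TRUE) {
  if (!coding5 || !coding3)
    return(list(frame_status = "noncoding", intact_3p_orf = NA))
  if (phases$utr5)
    return(list(frame_status = "five_prime_utr_fusion",
                intact_3p_orf = isTRUE(phases$utr3)))
  st <- if (phases$phase5 == phases$phase3) "in_frame" else "out_of_frame"
  list(frame_status = st, intact_3p_orf = NA)
}

#' Build a ChimericTranscript annotation for a junction
#'
#' Convenience wrapper joining [junctionPhases()] and [frameStatus()].
#'
#' @inheritParams junctionPhases
#' @return list with transcript ids, junction exon ordinals, phase fields
#'   and frame status (a "ChimericTranscript" record).
#' @export
chimericTranscript <- function(tx5, bp5, tx3, bp3) {
  coding5 <- tx5@biotype == "protein_coding"
  coding3 <- tx3@biotype == "protein_coding"
  if (!coding5 || !coding3) {
    m5 <- mapBreakpointToTranscript(bp5, tx5)
    m3 <- mapBreakpointToTranscript(bp3, tx3)
    return(list(tx5 = tx5@transcriptId, tx3 = tx3@transcriptId,
                junction_exon5 = if (m5$exonic) m5$exon else NA_integer_,
                junction_exon3 = if (m3$exonic) m3$exon else NA_integer_,
                retained_cds5_nt = NA_integer_, skipped_cds3_nt = NA_integer_,
                phase5 = NA_integer_, phase3 = NA_integer_,
                frame_status = "noncoding", intact_3p_orf = NA))
  }
  ph <- junctionPhases(tx5, bp5, tx3, bp3)
  fs <- frameStatus(ph, coding5, coding3)
  list(tx5 = tx5@transcriptId, tx3 = tx3@transcriptId,
       junction_exon5 = ph$exon5, junction_exon3 = ph$exon3,
       retained_cds5_nt = ph$retained_cds5_nt,
       skipped_cds3_nt = ph$skipped_cds3_nt,
       phase5 = ph$phase5, phase3 = ph$phase3,
       frame_status = fs$frame_status, intact_3p_orf = fs$intact_3p_orf)
}

#' Domains preserved in a chimeric protein
#'
#' The junction amino acid on the 5' partner is `J5 = floor(retained/3)`
#' (the last complete codon retained) and the first retained amino acid on
#' the 3' partner is `A3 = floor(skipped/3) + 1`. A 5'-partner domain is
#' preserved iff `aa_end <= J5`; a 3'-partner domain iff `aa_start >= A3`.
#' For a 5'UTR read-through with an intact downstream ORF, all 3'-partner
#' domains are preserved and no 5'-partner domain is. An out-of-frame
#' chimera preserves nothing (no ORF).
#'
#' @param chimera a record from [chimericTranscript()]
#' @param domains domain table as from [readDomainTable()]
#' @return data.frame of preserved domains with columns `partner`
#'   ("5p"/"3p"), `transcript_id`, `name`, `aa_start`, `aa_end`,
#'   `oncogenic`; empty with attribute `reason = "no ORF"` for
#'   out-of-frame/noncoding input.
#' @export
preservedDomains <- function(chimera, domains) {
  empty <- data.frame(partner = character(), transcript_id = character(),
                      name = character(), aa_start = integer(),
                      aa_end = integer(), oncogenic = logical(),
                      stringsAsFactors = FALSE)
  if (!chimera$frame_status %in% c("in_frame", "five_prime_utr_fusion"))
    return(structure(empty, reason = "no ORF"))
  d5 <- domains[domains$transcript_id == chimera$tx5, , drop = FALSE]
  d3 <- domains[domains$transcript_id == chimera$tx3, , drop = FALSE]
  if (chimera$frame_status == "five_prime_utr_fusion") {
    if (!isTRUE(chimera$intact_3p_orf)) return(structure(empty, reason = "no ORF"))
    keep3 <- d3
    keep5 <- d5[0, , drop = FALSE]
  } else {
    J5 <- chimera$retained_cds5_nt %/% 3L
    A3 <- chimera$skipped_cds3_nt %/% 3L + 1L
    keep5 <- d5[d5$aa_end <= J5, , drop = FALSE]
    keep3 <- d3[d3$aa_start >= A3, , drop = FALSE]
  }
  addPartner <- function(d, p)
    cbind(data.frame(partner = rep(p, nrow(d)), stringsAsFactors = FALSE), d)
  out <- rbind(addPartner(keep5, "5p"), addPartner(keep3, "3p"))
  rownames(out) <- NULL
  out
}

#' Nominate a driver fusion
#'
#' An event is nominated iff it has at least one preserved domain flagged
#' oncogenic OR an external driver score above `score_threshold`, AND its
#' recurrence (number of distinct metastatic carrier samples) reaches
#' `min_recurrence`. The external score (e.g. from a Bayesian driver
#' classifier) is consumed as an input, never recomputed.
#'
#' @param ev event record (used for identity only)
#' @param preserved preserved-domain data.frame from [preservedDomains()]
#' @param driverScore optional number in \[0,1\], or `NA`
#' @param recurrence number of distinct metastatic (LM) carrier samples
#' @param config list with `score_threshold` (default 0.8) and
#'   `min_recurrence` (default 2)
#' @return list: `nominated` (logical) and `reasons` (character vector of
#'   every satisfied criterion).
#' @export
nominateDriver <- function(ev, preserved, driverScore = NA_real_,
                           recurrence, config = list()) {
  thr <- config$score_threshold %||% 0.8
  minRec <- config$min_recurrence %||% 2L
  if (!is.na(driverScore) && (driverScore < 0 || driverScore > 1))
    .stopf("driver score must lie in [0,1], got %g", driverScore)
  hasOnc <- nrow(preserved) > 0 && any(preserved$oncogenic)
  hasScore <- !is.na(driverScore) && driverScore > thr
  recOk <- recurrence >= minRec
  reasons <- character(0)
  if (hasOnc)
    reasons <- c(reasons, sprintf("preserved oncogenic domain(s): %s",
                                  paste(preserved$name[preserved$oncogenic],
                                        collapse = ", ")))
  if (hasScore)
    reasons <- c(reasons, sprintf("driver score %.3g > %.3g", driverScore, thr))
  if (recOk)
    reasons <- c(reasons, sprintf("recurrent in %d mCRC sample(s)", recurrence))
  list(nominated = (hasOnc || hasScore) && recOk, reasons = reasons)
}

#' Intra- vs interchromosomal classification
#'
#' @param bp5,bp3 breakpoint lists with `chrom`
#' @return `"interchromosomal"` iff the chromosomes differ, else
#'   `"intrachromosomal"`.
#' @export
classifyType <- function(bp5, bp3) {
  if (identical(bp5$chrom, bp3$chrom)) "intrachromosomal" else "interchromosomal"
}

## Pick the annotation transcript for a gene: the one named in `txHint`
## when given, else the longest CDS, else the longest transcript.
.pickTranscript <- function(txset, gene, txHint = NULL) {
  models <- transcriptsByGene(txset, gene)
  if (!length(models)) return(NULL)
  if (!is.null(txHint) && txHint %in% names(models)) return(models[[txHint]])
  coding <- Filter(function(m) m@biotype == "protein_coding", models)
  pool <- if (length(coding)) coding else models
  lens <- vapply(pool, function(m) {
    if (m@biotype == "protein_coding") {
      c3 <- .cdsOffsets(m); c3[["last"]] - c3[["first"]] + 1L
    } else sum(IRanges::width(m@exons))
  }, numeric(1))
  pool[[which.max(lens)]]
}

#' Annotate consensus events with frame status, domains and nomination
#'
#' Drives [chimericTranscript()], [preservedDomains()], [classifyType()] and
#' [nominateDriver()] over a set of events. One transcript per gene is used
#' (the longest CDS unless a specific id is supplied via `txHints`).
#'
#' @param x a [ConsensusEventSet-class]
#' @param txset a [TranscriptSet-class]
#' @param domains domain table (as [readDomainTable()])
#' @param driverScores optional named numeric vector of external driver
#'   scores keyed by "gene5--gene3"
#' @param txHints optional named character vector gene -> transcript id
#' @param config nomination config (see [nominateDriver()])
#' @return data.frame annotation report: one row per event with columns
#'   `event`, `gene5`, `gene3`, `tx5`, `tx3`, `type`, `exon5`, `exon3`,
#'   `phase5`, `phase3`, `frame_status`, `coding`, `preserved_domains`,
#'   `n_oncogenic_preserved`, `driver_score`, `recurrence`, `nominated`,
#'   `reasons`.
#' @export
annotateEvents <- function(x, txset, domains, driverScores = NULL,
                           txHints = NULL, config = list()) {
  stopifnot(is(x, "ConsensusEventSet"))
  evs <- consensusEvents(x)
  rows <- lapply(evs, function(ev) {
    bp5 <- list(chrom = ev$chrom5, pos = ev$pos5)
    bp3 <- list(chrom = ev$chrom3, pos = ev$pos3)
    tx5 <- .pickTranscript(txset, ev$gene5, txHints[[ev$gene5]])
    tx3 <- .pickTranscript(txset, ev$gene3, txHints[[ev$gene3]])
    pair <- paste0(ev$gene5, "--", ev$gene3)
    score <- if (!is.null(driverScores) && pair %in% names(driverScores))
      unname(driverScores[[pair]]) else NA_real_
    recurrence <- length(ev$samples_by_class$LM)
    coding <- isTRUE(as.logical(filterCoding(ev, txset)))
    stub <- list(tx5 = if (is.null(tx5)) NA_character_ else tx5@transcriptId,
                 tx3 = if (is.null(tx3)) NA_character_ else tx3@transcriptId,
                 junction_exon5 = NA_integer_, junction_exon3 = NA_integer_,
                 retained_cds5_nt = NA_integer_, skipped_cds3_nt = NA_integer_,
                 phase5 = NA_integer_, phase3 = NA_integer_,
                 frame_status = "noncoding", intact_3p_orf = NA)
    chim <- if (is.null(tx5) || is.null(tx3)) stub else
      tryCatch(chimericTranscript(tx5, bp5, tx3, bp3),
               error = function(e) { stub$frame_status <- NA_character_; stub })
    pres <- preservedDomains(chim, domains)
    nom <- nominateDriver(ev, pres, score, recurrence, config)
    data.frame(
      event = eventId(ev), gene5 = ev$gene5, gene3 = ev$gene3,
      tx5 = chim$tx5, tx3 = chim$tx3,
      type = classifyType(bp5, bp3),
      exon5 = chim$junction_exon5, exon3 = chim$junction_exon3,
      phase5 = chim$phase5, phase3 = chim$phase3,
      frame_status = chim$frame_status,
      coding = coding,
      preserved_domains = paste(sprintf("%s:%s", pres$partner, pres$name),
                                collapse = ";"),
      n_oncogenic_preserved = sum(pres$oncogenic),
      driver_score = score, recurrence = recurrence,
      nominated = nom$nominated,
      reasons = paste(nom$reasons, collapse = "; "),
      exclusivity_class = classifyExclusivity(ev),
      stringsAsFactors = FALSE)
  })
  if (!length(rows)) {
    return(data.frame(event = character(), gene5 = character(),
                      gene3 = character(), tx5 = character(),
                      tx3 = character(), type = character(),
                      exon5 = integer(), exon3 = integer(),
                      phase5 = integer(), phase3 = integer(),
                      frame_status = character(), coding = logical(),
                      preserved_domains = character(),
                      n_oncogenic_preserved = integer(),
                      driver_score = numeric(), recurrence = integer(),
                      nominated = logical(), reasons = character(),
                      exclusivity_class = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
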