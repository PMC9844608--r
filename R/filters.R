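## The cohort filter cascade: read support -> coding mapping -> normal
## exclusion -> tissue exclusivity. Cross-caller validation happens upstream
## in crossValidate(); events entering the cascade have already passed it.

#' Classify an event's tissue exclusivity
#'
#' An event seen in any normal sample is `normal_present` (and excluded
#' downstream); otherwise it is `LM_unique` (liver metastasis only),
#' `pCRC_unique` (primary tumour only) or `common` (both).
#'
#' @param ev an event record from a [ConsensusEventSet-class]
#' @return one of `"LM_unique"`, `"pCRC_unique"`, `"common"`,
#'   `"normal_present"`.
#' @export
classifyExclusivity <- function(ev) {
  nLM <- length(ev$samples_by_class$LM)
  nP <- length(ev$samples_by_class$pCRC)
  nN <- length(ev$samples_by_class$N)
  if (nLM + nP + nN == 0L)
    .stopf("event %s is present in no sample", eventId(ev))
  if (nN > 0L) return("normal_present")
  if (nLM > 0L && nP == 0L) return("LM_unique")
  if (nP > 0L && nLM == 0L) return("pCRC_unique")
  "common"
}

#' Read-support filter
#'
#' Passes iff the maximum spanning-read count over carrier samples reaches
#' `minSupport`. Crossing reads are reported but not thresholded: junction
#' support counts spanning reads with or without crossing reads.
#'
#' @param ev an event record
#' @param minSupport minimum spanning reads (default 5)
#' @return logical
#' @export
filterReadSupport <- function(ev, minSupport = 5L) {
  stopifnot(minSupport >= 0)
  maxSpan <- max(vapply(ev$support_by_sample, function(s) s[["spanning"]],
                        numeric(1)))
  maxSpan >= minSupport
}

#' Coding-sequence filter
#'
#' Passes iff both partner genes have at least one protein-coding transcript
#' whose exon union contains the respective breakpoint. A gene absent from
#' the annotation fails with reason `"unannotated"`; an exon-missing
#' breakpoint fails with reason `"not exonic"`.
#'
#' @param ev an event record
#' @param txset a [TranscriptSet-class]
#' @return logical with attribute `reason` set when `FALSE`.
#' @export
filterCoding <- function(ev, txset) {
  checkEnd <- function(gene, chrom, pos) {
    models <- transcriptsByGene(txset, gene)
    if (!length(models)) return("unannotated")
    coding <- Filter(function(m) m@biotype == "protein_coding" &&
                                 m@chrom == chrom, models)
    if (!length(coding)) return("not coding")
    hit <- any(vapply(coding, function(m) {
      any(pos >= IRanges::start(m@exons) & pos <= IRanges::end(m@exons))
    }, logical(1)))
    if (hit) NA_character_ else "not exonic"
  }
  r5 <- checkEnd(ev$gene5, ev$chrom5, ev$pos5)
  r3 <- checkEnd(ev$gene3, ev$chrom3, ev$pos3)
  if (is.na(r5) && is.na(r3)) return(TRUE)
  structure(FALSE, reason = paste(stats::na.omit(c(
    if (!is.na(r5)) paste0("5p ", r5), if (!is.na(r3)) paste0("3p ", r3))),
    collapse = "; "))
}

#' Apply the filter cascade to consensus events
#'
#' Stage order is fixed: cross-validation (performed upstream, recorded as
#' passed) -> read support -> coding -> normal exclusion -> exclusivity
#' equals `targetClass`. Every input event receives a trace row recording
#' its exclusivity class, per-stage pass flags and the first failing stage.
#'
#' @param x a [ConsensusEventSet-class]
#' @param txset a [TranscriptSet-class] for the coding filter
#' @param config list with `min_support` (default 5) and `target_class`
#'   (default `"LM_unique"`).
#' @return list with `passing` (a `ConsensusEventSet`) and `trace`
#'   (data.frame with columns `event`, `exclusivity_class`,
#'   `pass_read_support`, `pass_coding`, `pass_normal_exclusion`,
#'   `pass_exclusivity`, `failed_stage`, `reason`).
#' @export
applyCascade <- function(x, txset, config = list()) {
  stopifnot(is(x, "ConsensusEventSet"))
  minSupport <- config$min_support %||% 5L
  targetClass <- config$target_class %||% "LM_unique"
  if (!targetClass %in% setdiff(EXCLUSIVITY_CLASSES, "normal_present"))
    .stopf("unknown target_class: %s", targetClass)
  evs <- consensusEvents(x)
  trace <- vector("list", length(evs))
  keep <- logical(length(evs))
  for (i in seq_along(evs)) {
    ev <- evs[[i]]
    excl <- classifyExclusivity(ev)
    pSupport <- isTRUE(filterReadSupport(ev, minSupport))
    cod <- if (pSupport) filterCoding(ev, txset) else NA
    pCoding <- isTRUE(as.logical(cod))
    pNormal <- pCoding && excl != "normal_present"
    pExcl <- pNormal && excl == targetClass
    failed <- if (!pSupport) "read_support"
      else if (!pCoding) "coding"
      else if (!pNormal) "normal_exclusion"
      else if (!pExcl) "exclusivity"
      else NA_character_
    reason <- if (!pSupport || pCoding || is.na(failed)) NA_character_
      else attr(cod, "reason") %||% NA_character_
    trace[[i]] <- data.frame(
      event = eventId(ev), exclusivity_class = excl,
      pass_cross_validation = TRUE,
      pass_read_support = pSupport,
      pass_coding = pSupport && pCoding,
      pass_normal_exclusion = pNormal,
      pass_exclusivity = pExcl,
      failed_stage = failed, reason = reason, stringsAsFactors = FALSE)
    keep[i] <- pExcl
  }
  trace <- if (length(trace)) do.call(rbind, trace) else data.frame(
    event = character(), exclusivity_class = character(),
    pass_cross_validation = logical(), pass_read_support = logical(),
    pass_coding = logical(), pass_normal_exclusion = logical(),
    pass_exclusivity = logical(), failed_stage = character(),
    reason = character(), stringsAsFactors = FALSE)
  list(passing = ConsensusEventSet(evs[keep]), trace = trace)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
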