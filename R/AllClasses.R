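#' Container for normalized fusion calls
#'
#' A `FusionCallSet` holds caller reports after normalization into the
#' canonical layout: one row per reported candidate fusion per sample per
#' caller, with both breakpoints in 1-based coordinates and the strand of
#' each fused segment. Rows whose coordinates could not be parsed are not
#' kept; their number is available through [skippedRows()].
#'
#' @slot calls data.frame with the canonical columns (`sample_id`, `caller`,
#'   `gene5`, `gene3`, `chrom5`, `pos5`, `strand5`, `chrom3`, `pos3`,
#'   `strand3`, `spanning_reads`, `crossing_reads`).
#' @slot skipped integer count of dropped unparseable rows.
#'
#' @seealso [readCallerCalls()], [writeCanonicalCalls()]
#' @export
setClass("FusionCallSet",
         representation(calls = "data.frame", skipped = "integer"),
         prototype(calls = .emptyCallTable(), skipped = 0L))

setValidity("FusionCallSet", function(object) {
  df <- object@calls
  missing <- setdiff(CANONICAL_CALL_COLS, names(df))
  if (length(missing))
    return(paste("missing call columns:", paste(missing, collapse = ", ")))
  if (nrow(df)) {
    if (any(df$gene5 == "" | df$gene3 == ""))
      return("gene symbols must be non-empty")
    if (any(df$pos5 < 1L) || any(df$pos3 < 1L))
      return("breakpoint positions must be >= 1")
    if (!all(df$strand5 %in% c("+", "-")) || !all(df$strand3 %in% c("+", "-")))
      return("strands must be '+' or '-'")
    if (any(df$spanning_reads < 0L) || any(df$crossing_reads < 0L))
      return("read counts must be non-negative")
    if (!all(df$caller %in% CALLER_NAMES))
      return(paste("unknown caller:",
                   paste(setdiff(unique(df$caller), CALLER_NAMES), collapse = ", ")))
  }
  if (length(object@skipped) != 1L || is.na(object@skipped) || object@skipped < 0L)
    return("skipped must be a single non-negative integer")
  TRUE
})

#' Construct a FusionCallSet from a canonical calls data.frame
#'
#' @param calls data.frame with the canonical call columns.
#' @param skipped number of unparseable rows dropped upstream.
#' @return A [FusionCallSet-class] object.
#' @export
FusionCallSet <- function(calls = .emptyCallTable(), skipped = 0L) {
  calls <- as.data.frame(calls, stringsAsFactors = FALSE)
  if (nrow(calls)) {
    calls$strand5 <- .normStrand(calls$strand5)
    calls$strand3 <- .normStrand(calls$strand3)
    calls$pos5 <- as.integer(calls$pos5)
    calls$pos3 <- as.integer(calls$pos3)
    calls$spanning_reads <- as.integer(calls$spanning_reads)
    calls$crossing_reads <- as.integer(calls$crossing_reads)
    calls$gene5 <- trimws(calls$gene5)
    calls$gene3 <- trimws(calls$gene3)
  }
  rownames(calls) <- NULL
  new("FusionCallSet", calls = calls[, CANONICAL_CALL_COLS, drop = FALSE],
      skipped = as.integer(skipped))
}

#' @describeIn FusionCallSet-class number of calls
#' @param object,x a `FusionCallSet`
#' @export
setMethod("length", "FusionCallSet", function(x) nrow(x@calls))

#' Accessors for FusionCallSet
#'
#' `fusionCalls()` returns the canonical calls table; `skippedRows()` the
#' tally of rows dropped because their coordinates could not be parsed.
#'
#' @param x a [FusionCallSet-class]
#' @return `fusionCalls()`: a data.frame; `skippedRows()`: an integer.
#' @export
fusionCalls <- function(x) {
  stopifnot(is(x, "FusionCallSet"))
  x@calls
}

#' @rdname fusionCalls
#' @export
skippedRows <- function(x) {
  stopifnot(is(x, "FusionCallSet"))
  x@skipped
}

setMethod("show", "FusionCallSet", function(object) {
  cat(sprintf("FusionCallSet with %d call(s) from %d sample(s); %d row(s) skipped\n",
              nrow(object@calls), length(unique(object@calls$sample_id)),
              object@skipped))
  if (nrow(object@calls)) {
    print(head(object@calls, 5L))
    if (nrow(object@calls) > 5L) cat("...\n")
  }
})

#' Transcript model
#'
#' One transcript: ordered exons on a chromosome, optional CDS bounds, and a
#' biotype inferred from the presence of a CDS. Exons are stored as an
#' [IRanges::IRanges] in genomic (ascending) order; transcript-orientation
#' arithmetic (exon ordinals, cumulative offsets) is strand-aware.
#'
#' @slot transcriptId,gene,chrom character scalars.
#' @slot strand "+" or "-".
#' @slot exons IRanges of 1-based closed exon intervals, sorted, disjoint.
#' @slot cdsStartGenomic,cdsEndGenomic genomic CDS bounds (low/high ends,
#'   irrespective of strand); `NA` for non-coding transcripts.
#' @slot biotype "protein_coding" or "noncoding".
#' @export
setClass("TranscriptModel",
         representation(transcriptId = "character", gene = "character",
                        chrom = "character", strand = "character",
                        exons = "IRanges",
                        cdsStartGenomic = "integer", cdsEndGenomic = "integer",
                        biotype = "character"))

setValidity("TranscriptModel", function(object) {
  if (!object@strand %in% c("+", "-")) return("strand must be '+' or '-'")
  ex <- object@exons
  if (length(ex) == 0L) return("transcript needs at least one exon")
  st <- IRanges::start(ex); en <- IRanges::end(ex)
  if (is.unsorted(st, strictly = TRUE)) return("exons must be sorted by genomic start")
  if (length(ex) > 1L && any(st[-1L] <= en[-length(ex)]))
    return("exons must be non-overlapping")
  if (object@biotype == "protein_coding") {
    cs <- object@cdsStartGenomic; ce <- object@cdsEndGenomic
    if (is.na(cs) || is.na(ce)) return("protein_coding transcript needs CDS bounds")
    if (cs > ce) return("cdsStartGenomic must be <= cdsEndGenomic")
    inExon <- function(p) any(p >= st & p <= en)
    if (!inExon(cs) || !inExon(ce)) return("CDS bounds must fall inside exons")
  } else if (object@biotype != "noncoding") {
    return("biotype must be protein_coding or noncoding")
  }
  TRUE
})

## allow tx$slot shorthand internally
setMethod("$", "TranscriptModel", function(x, name) slot(x, name))

#' Construct a TranscriptModel
#'
#' @param transcriptId,gene,chrom,strand scalars describing the transcript.
#' @param exons an `IRanges` or a 2-column matrix/data.frame of 1-based
#'   closed `start`,`end` intervals (any order; they are sorted).
#' @param cdsStartGenomic,cdsEndGenomic genomic CDS bounds, or `NA` for a
#'   non-coding transcript.
#' @return A [TranscriptModel-class] object.
#' @export
TranscriptModel <- function(transcriptId, gene, chrom, strand, exons,
                            cdsStartGenomic = NA_integer_,
                            cdsEndGenomic = NA_integer_) {
  if (!is(exons, "IRanges")) {
    exons <- as.data.frame(exons)
    exons <- IRanges::IRanges(start = as.integer(exons[[1]]),
                              end = as.integer(exons[[2]]))
  }
  exons <- exons[order(IRanges::start(exons))]
  biotype <- if (is.na(cdsStartGenomic) || is.na(cdsEndGenomic))
    "noncoding" else "protein_coding"
  new("TranscriptModel", transcriptId = as.character(transcriptId),
      gene = as.character(gene), chrom = as.character(chrom),
      strand = .checkStrand(strand), exons = exons,
      cdsStartGenomic = as.integer(cdsStartGenomic),
      cdsEndGenomic = as.integer(cdsEndGenomic), biotype = biotype)
}

setMethod("show", "TranscriptModel", function(object) {
  cat(sprintf("TranscriptModel %s (%s) %s:%s exons=%d biotype=%s\n",
              object@transcriptId, object@gene, object@chrom, object@strand,
              length(object@exons), object@biotype))
})

#' Set of transcript models with gene/id lookup
#'
#' @slot models named list of [TranscriptModel-class] (names = transcript ids).
#' @export
setClass("TranscriptSet", representation(models = "list"))

setValidity("TranscriptSet", function(object) {
  if (length(object@models)) {
    ok <- vapply(object@models, is, logical(1), "TranscriptModel")
    if (!all(ok)) return("all elements must be TranscriptModel")
    ids <- unname(vapply(object@models, function(m) m@transcriptId, character(1)))
    if (anyDuplicated(ids)) return("duplicate transcript ids")
    if (!identical(names(object@models), ids))
      return("models must be named by transcript id")
  }
  TRUE
})

#' @rdname TranscriptSet-class
#' @param models list of `TranscriptModel`
#' @export
TranscriptSet <- function(models = list()) {
  if (length(models))
    names(models) <- vapply(models, function(m) m@transcriptId, character(1))
  new("TranscriptSet", models = models)
}

#' @describeIn TranscriptSet-class number of transcripts
#' @param x,object a `TranscriptSet`
#' @export
setMethod("length", "TranscriptSet", function(x) length(x@models))

setMethod("show", "TranscriptSet", function(object) {
  bt <- vapply(object@models, function(m) m@biotype, character(1))
  cat(sprintf("TranscriptSet with %d transcript(s) (%d protein_coding, %d noncoding)\n",
              length(object@models), sum(bt == "protein_coding"),
              sum(bt == "noncoding")))
})

#' Look up transcripts
#'
#' `getTranscript()` fetches one model by transcript id; `transcriptsByGene()`
#' returns the (possibly empty) list of models for a gene symbol, matched
#' case-sensitively after whitespace trimming.
#'
#' @param x a [TranscriptSet-class]
#' @param id,gene character scalar.
#' @export
getTranscript <- function(x, id) {
  stopifnot(is(x, "TranscriptSet"))
  m <- x@models[[id]]
  if (is.null(m)) .stopf("unknown transcript id: %s", id)
  m
}

#' @rdname getTranscript
#' @export
transcriptsByGene <- function(x, gene) {
  stopifnot(is(x, "TranscriptSet"))
  gene <- trimws(gene)
  Filter(function(m) m@gene == gene, x@models)
}

#' Cohort-level consensus fusion events
#'
#' After cross-caller validation within samples and merging across samples,
#' each event carries a representative breakpoint pair, the callers and read
#' support observed per sample, and the tissue classes of its carriers.
#'
#' @slot events list of event records; each has `gene5`, `gene3`, `chrom5`,
#'   `pos5`, `strand5`, `chrom3`, `pos3`, `strand3`, `callers_by_sample`
#'   (named list sample -> character vector), `support_by_sample` (named list
#'   sample -> c(spanning, crossing)), `samples_by_class` (list LM/pCRC/N ->
#'   character vector).
#' @export
setClass("ConsensusEventSet", representation(events = "list"),
         prototype(events = list()))

setValidity("ConsensusEventSet", function(object) {
  for (ev in object@events) {
    need <- c("gene5", "gene3", "chrom5", "pos5", "strand5", "chrom3",
              "pos3", "strand3", "callers_by_sample", "support_by_sample",
              "samples_by_class")
    if (!all(need %in% names(ev))) return("event record missing fields")
    if (!setequal(names(ev$callers_by_sample), names(ev$support_by_sample)))
      return("callers_by_sample and support_by_sample must cover the same samples")
  }
  TRUE
})

#' @rdname ConsensusEventSet-class
#' @param events list of event records
#' @export
ConsensusEventSet <- function(events = list()) {
  new("ConsensusEventSet", events = events)
}

#' @describeIn ConsensusEventSet-class number of events
#' @param x,object a `ConsensusEventSet`
#' @export
setMethod("length", "ConsensusEventSet", function(x) length(x@events))

#' @rdname ConsensusEventSet-class
#' @export
consensusEvents <- function(x) {
  stopifnot(is(x, "ConsensusEventSet"))
  x@events
}

#' Summarize consensus events as a table
#'
#' One row per event with representative breakpoints, the maximum number of
#' agreeing callers in any one sample, carrier counts per tissue class and
#' the maximum spanning-read support.
#'
#' @param x a [ConsensusEventSet-class]
#' @return data.frame with columns `gene5`, `gene3`, `chrom5`, `pos5`,
#'   `strand5`, `chrom3`, `pos3`, `strand3`, `n_callers_max`,
#'   `n_samples_LM`, `n_samples_pCRC`, `n_samples_N`, `max_support`.
#' @export
eventTable <- function(x) {
  stopifnot(is(x, "ConsensusEventSet"))
  evs <- x@events
  if (!length(evs)) {
    return(data.frame(gene5 = character(), gene3 = character(),
                      chrom5 = character(), pos5 = integer(),
                      strand5 = character(), chrom3 = character(),
                      pos3 = integer(), strand3 = character(),
                      n_callers_max = integer(), n_samples_LM = integer(),
                      n_samples_pCRC = integer(), n_samples_N = integer(),
                      max_support = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(evs, function(ev) {
    data.frame(gene5 = ev$gene5, gene3 = ev$gene3,
               chrom5 = ev$chrom5, pos5 = ev$pos5, strand5 = ev$strand5,
               chrom3 = ev$chrom3, pos3 = ev$pos3, strand3 = ev$strand3,
               n_callers_max = max(vapply(ev$callers_by_sample, length, integer(1))),
               n_samples_LM = length(ev$samples_by_class$LM),
               n_samples_pCRC = length(ev$samples_by_class$pCRC),
               n_samples_N = length(ev$samples_by_class$N),
               max_support = max(vapply(ev$support_by_sample,
                                        function(s) s[["spanning"]], numeric(1))),
               stringsAsFactors = FALSE)
  }))
}

setMethod("show", "ConsensusEventSet", function(object) {
  cat(sprintf("ConsensusEventSet with %d event(s)\n", length(object@events)))
  if (length(object@events)) print(head(eventTable(object), 5L))
})

#' Event identity label used in traces and reports
#' @param ev an event record from a [ConsensusEventSet-class]
#' @return character scalar like "GENEA--GENEB@chr1:100/chr2:200"
#' @export
eventId <- function(ev) {
  sprintf("%s--%s@%s:%d/%s:%d", ev$gene5, ev$gene3,
          ev$chrom5, ev$pos5, ev$chrom3, ev$pos3)
}
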