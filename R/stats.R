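## Cohort category tallies (intra/inter x coding/non-coding x in/out of
## frame per exclusivity class) and recurrence summaries.

#' Percentage with half-away-from-zero rounding
#'
#' @param count,total non-negative integers with `0 <= count <= total`,
#'   `total > 0`
#' @param dp decimal places (default 1)
#' @return `100 * count / total` rounded half away from zero to `dp`
#'   decimals.
#' @export
percentOf <- function(count, total, dp = 1L) {
  if (length(total) != 1L || is.na(total) || total <= 0)
    .stopf("percentOf: total must be > 0")
  if (any(count < 0) || any(count > total))
    .stopf("percentOf: need 0 <= count <= total")
  roundHalfAway(100 * count / total, dp)
}

#' Tabulate annotated events by exclusivity class
#'
#' Cohort-level category tallies: for each exclusivity class (`LM_unique`,
#' `pCRC_unique`, `common`) the intrachromosomal/interchromosomal,
#' coding/non-coding and in-frame/out-of-frame dichotomies. The denominator
#' of every dichotomy is the class total; events that are non-coding or
#' unmappable count on the non-coding and out-of-frame sides. Read-through
#' 5'UTR junctions do not count as in-frame (no junction-spanning ORF is
#' asserted for them).
#'
#' @param annotated annotation report from [annotateEvents()] (needs columns
#'   `event`, `exclusivity_class`, `type`, `coding`, `frame_status`)
#' @param dp decimal places for percentages
#' @return data.frame with columns `class`, `dichotomy`, `category`,
#'   `count`, `percent`, plus class totals as dichotomy `"total"`.
#' @export
tabulateCohort <- function(annotated, dp = 1L) {
  need <- c("event", "exclusivity_class", "type", "coding", "frame_status")
  missing <- setdiff(need, names(annotated))
  if (length(missing))
    .stopf("tabulateCohort: annotation lacks column(s): %s",
           paste(missing, collapse = ", "))
  bad <- is.na(annotated$type) | is.na(annotated$coding) |
    is.na(annotated$exclusivity_class)
  if (any(bad))
    .stopf("unannotated event(s): %s",
           paste(annotated$event[bad], collapse = ", "))
  classes <- c("LM_unique", "pCRC_unique", "common")
  rows <- list()
  for (cls in classes) {
    d <- annotated[annotated$exclusivity_class == cls, , drop = FALSE]
    n <- nrow(d)
    addRow <- function(dich, cat, cnt) {
      rows[[length(rows) + 1L]] <<- data.frame(
        class = cls, dichotomy = dich, category = cat, count = cnt,
        percent = if (n > 0) percentOf(cnt, n, dp) else NA_real_,
        stringsAsFactors = FALSE)
    }
    addRow("total", "total", n)
    addRow("chromosomal", "intrachromosomal", sum(d$type == "intrachromosomal"))
    addRow("chromosomal", "interchromosomal", sum(d$type == "interchromosomal"))
    addRow("coding", "coding", sum(d$coding))
    addRow("coding", "noncoding", sum(!d$coding))
    inframe <- sum(!is.na(d$frame_status) & d$frame_status == "in_frame")
    addRow("frame", "in_frame", inframe)
    addRow("frame", "out_of_frame", n - inframe)
  }
  do.call(rbind, rows)
}

#' Per-event metastatic recurrence
#'
#' Counts, for every event, its distinct liver-metastasis carrier samples;
#' sorted by descending count, ties broken by gene pair lexicographically.
#'
#' @param x a [ConsensusEventSet-class]
#' @return data.frame with columns `gene5`, `gene3`, `n_mCRC`.
#' @export
recurrenceTable <- function(x) {
  stopifnot(is(x, "ConsensusEventSet"))
  evs <- consensusEvents(x)
  if (!length(evs)) {
    return(data.frame(gene5 = character(), gene3 = character(),
                      n_mCRC = integer(), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, lapply(evs, function(ev) {
    data.frame(gene5 = ev$gene5, gene3 = ev$gene3,
               n_mCRC = length(unique(ev$samples_by_class$LM)),
               stringsAsFactors = FALSE)
  }))
  df <- df[order(-df$n_mCRC, df$gene5, df$gene3), , drop = FALSE]
  rownames(df) <- NULL
  df
}
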