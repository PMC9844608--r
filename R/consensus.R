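## Cross-caller validation within samples and cross-sample merging into
## cohort-level consensus events.
##
## Matching is by identical ordered gene pair, chromosome and strand at both
## ends, with breakpoint positions allowed to differ by at most `tol`
## nucleotides (callers disagree by a few bases at exon boundaries).
## Clustering is transitive (single linkage), which makes the result
## independent of input order; cluster representatives are the per-end
## lower-median position.

#' Do two fusion calls describe the same junction?
#'
#' @param a,b single call records: lists or one-row data.frames with
#'   `gene5`, `gene3`, `chrom5`, `pos5`, `strand5`, `chrom3`, `pos3`,
#'   `strand3`.
#' @param tol non-negative breakpoint tolerance in nucleotides.
#' @return `TRUE` iff the ordered gene pairs, chromosomes and strands agree
#'   at both ends and both position differences are at most `tol`.
#'   Symmetric in `a` and `b`.
#' @export
matchCalls <- function(a, b, tol = 10L) {
  stopifnot(tol >= 0)
  a <- as.list(a); b <- as.list(b)
  identical(trimws(a$gene5), trimws(b$gene5)) &&
    identical(trimws(a$gene3), trimws(b$gene3)) &&
    identical(a$chrom5, b$chrom5) && identical(a$chrom3, b$chrom3) &&
    identical(.normStrand(a$strand5), .normStrand(b$strand5)) &&
    identical(.normStrand(a$strand3), .normStrand(b$strand3)) &&
    abs(a$pos5 - b$pos5) <= tol && abs(a$pos3 - b$pos3) <= tol
}

## Transitive clustering of rows that already share gene pair, chromosomes
## and strands, linking rows whose positions agree within tol at both ends.
## Returns an integer cluster id per row. Union-find keeps it order-free.
.clusterPositions <- function(pos5, pos3, tol) {
  n <- length(pos5)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  ord <- order(pos5, pos3)
  for (ii in seq_len(n - 1L)) {
    for (jj in (ii + 1L):n) {
      i <- ord[ii]; j <- ord[jj]
      if (pos5[j] - pos5[i] > tol) break
      if (abs(pos3[i] - pos3[j]) <= tol) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Cross-validate calls between callers within each sample
#'
#' Within each sample, calls are clustered transitively under
#' [matchCalls()]; clusters reported by at least `minTools` distinct
#' callers are retained (multiple calls from one caller count as one vote).
#' Each retained cluster's representative breakpoints are the per-end
#' lower-median position over member calls, and its support is the maximum
#' spanning (and crossing) read count over members.
#'
#' @param x a [FusionCallSet-class] (or canonical calls data.frame)
#' @param minTools minimum number of distinct callers (>= 1)
#' @param tol breakpoint tolerance in nucleotides
#' @return data.frame of validated per-sample clusters with columns
#'   `sample_id`, `gene5`, `gene3`, `chrom5`, `pos5`, `strand5`, `chrom3`,
#'   `pos3`, `strand3`, `n_callers`, `spanning_reads`, `crossing_reads` and
#'   a list-column `callers`.
#' @export
crossValidate <- function(x, minTools = 2L, tol = 10L) {
  stopifnot(minTools >= 1L, tol >= 0)
  calls <- if (is(x, "FusionCallSet")) fusionCalls(x) else FusionCallSet(x)@calls
  empty <- data.frame(sample_id = character(), gene5 = character(),
                      gene3 = character(), chrom5 = character(),
                      pos5 = integer(), strand5 = character(),
                      chrom3 = character(), pos3 = integer(),
                      strand3 = character(), n_callers = integer(),
                      spanning_reads = integer(), crossing_reads = integer(),
                      stringsAsFactors = FALSE)
  if (!nrow(calls)) { empty$callers <- list(); return(empty) }
  key <- paste(calls$sample_id, calls$gene5, calls$gene3, calls$chrom5,
               calls$strand5, calls$chrom3, calls$strand3, sep = "\r")
  out <- list()
  for (grp in split(calls, key)) {
    cl <- .clusterPositions(grp$pos5, grp$pos3, tol)
    for (members in split(grp, cl)) {
      callers <- sort(unique(members$caller))
      if (length(callers) < minTools) next
      out[[length(out) + 1L]] <- data.frame(
        sample_id = members$sample_id[1],
        gene5 = members$gene5[1], gene3 = members$gene3[1],
        chrom5 = members$chrom5[1], pos5 = lowerMedian(members$pos5),
        strand5 = members$strand5[1],
        chrom3 = members$chrom3[1], pos3 = lowerMedian(members$pos3),
        strand3 = members$strand3[1],
        n_callers = length(callers),
        spanning_reads = max(members$spanning_reads),
        crossing_reads = max(members$crossing_reads),
        stringsAsFactors = FALSE)
      out[[length(out)]]$callers <- list(callers)
    }
  }
  if (!length(out)) { empty$callers <- list(); return(empty) }
  res <- do.call(rbind, out)
  res <- res[order(res$sample_id, res$gene5, res$gene3, res$pos5, res$pos3), ]
  rownames(res) <- NULL
  res
}

#' Merge validated per-sample clusters into cohort-level events
#'
#' Clusters sharing the ordered gene pair, chromosomes and strands, with
#' breakpoints within `tol` (transitively), merge into one
#' [ConsensusEventSet-class] event. Carrier samples are classified with the
#' sample sheet; representative breakpoints are the per-end lower-median
#' over member clusters.
#'
#' @param validated output of [crossValidate()]
#' @param sheet sample sheet data.frame (`sample_id`, `tissue_class`,
#'   `patient_id`)
#' @param tol breakpoint tolerance in nucleotides
#' @return A [ConsensusEventSet-class].
#' @export
mergeEvents <- function(validated, sheet, tol = 10L) {
  sheet <- validateSampleSheet(sheet)
  if (!nrow(validated)) return(ConsensusEventSet())
  unknown <- setdiff(unique(validated$sample_id), sheet$sample_id)
  if (length(unknown))
    .stopf("sample(s) absent from sample sheet: %s",
           paste(unknown, collapse = ", "))
  classOf <- setNames(sheet$tissue_class, sheet$sample_id)
  key <- paste(validated$gene5, validated$gene3, validated$chrom5,
               validated$strand5, validated$chrom3, validated$strand3,
               sep = "\r")
  events <- list()
  for (grp in split(validated, key)) {
    cl <- .clusterPositions(grp$pos5, grp$pos3, tol)
    for (members in split(grp, cl)) {
      callers_by_sample <- list()
      support_by_sample <- list()
      for (i in seq_len(nrow(members))) {
        s <- members$sample_id[i]
        callers_by_sample[[s]] <- sort(unique(c(callers_by_sample[[s]],
                                                members$callers[[i]])))
        prev <- support_by_sample[[s]]
        if (is.null(prev)) prev <- c(spanning = 0, crossing = 0)
        support_by_sample[[s]] <- c(
          spanning = max(prev[["spanning"]], members$spanning_reads[i]),
          crossing = max(prev[["crossing"]], members$crossing_reads[i]))
      }
      samples <- sort(names(callers_by_sample))
      samples_by_class <- lapply(setNames(TISSUE_CLASSES, TISSUE_CLASSES),
                                 function(cls) samples[classOf[samples] == cls])
      events[[length(events) + 1L]] <- list(
        gene5 = members$gene5[1], gene3 = members$gene3[1],
        chrom5 = members$chrom5[1], pos5 = lowerMedian(members$pos5),
        strand5 = members$strand5[1],
        chrom3 = members$chrom3[1], pos3 = lowerMedian(members$pos3),
        strand3 = members$strand3[1],
        callers_by_sample = callers_by_sample[samples],
        support_by_sample = support_by_sample[samples],
        samples_by_class = samples_by_class)
    }
  }
  ord <- order(vapply(events, function(e) paste(e$gene5, e$gene3), character(1)),
               vapply(events, function(e) e$pos5, integer(1)),
               vapply(events, function(e) e$pos3, integer(1)))
  ConsensusEventSet(events[ord])
}
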