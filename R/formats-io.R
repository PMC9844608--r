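## Reading/writing the external formats: GTF transcript models, caller
## report dialects, the canonical calls TSV, BEDPE export, domain tables
## and sample sheets.

#' Read transcript models from a GTF file
#'
#' Parses `exon` and `CDS` features (via \pkg{rtracklayer}) into
#' [TranscriptModel-class] objects. Exons are merged and sorted per
#' transcript; the biotype is `protein_coding` when the transcript carries
#' at least one CDS feature, `noncoding` otherwise. CDS bounds are the
#' genomic minimum/maximum over CDS features.
#'
#' @param path GTF file. Every exon/CDS feature must carry a
#'   `transcript_id` attribute; the gene symbol is taken from `gene_name`,
#'   falling back to `gene_id`.
#' @return A [TranscriptSet-class].
#' @export
readGtf <- function(path) {
  if (!file.exists(path)) .stopf("GTF file not found: %s", path)
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type %in% c("exon", "CDS")]
  txid <- as.character(gr$transcript_id)
  if (length(gr) && (anyNA(txid) || any(txid == ""))) {
    ## name the offending line for the user
    lines <- readLines(path)
    feat <- grep("\t(exon|CDS)\t", lines)
    bad <- feat[!grepl("transcript_id", lines[feat])]
    .stopf("GTF feature without transcript_id attribute at line %s",
           if (length(bad)) bad[1] else "?")
  }
  if (!length(gr)) return(TranscriptSet())
  gene <- as.character(if (!is.null(gr$gene_name)) gr$gene_name else gr$gene_id)
  gene[is.na(gene)] <- as.character(gr$gene_id)[is.na(gene)]
  df <- data.frame(tx = txid, gene = gene,
                   chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   type = as.character(gr$type), stringsAsFactors = FALSE)
  models <- lapply(split(df, df$tx), function(d) {
    ex <- d[d$type == "exon", , drop = FALSE]
    cds <- d[d$type == "CDS", , drop = FALSE]
    if (!nrow(ex)) ex <- cds  # degenerate GTFs with CDS only
    exons <- IRanges::reduce(IRanges::IRanges(ex$start, ex$end))
    cs <- if (nrow(cds)) min(cds$start) else NA_integer_
    ce <- if (nrow(cds)) max(cds$end) else NA_integer_
    if (!is.na(cs)) {
      st <- IRanges::start(exons); en <- IRanges::end(exons)
      if (!any(cs >= st & cs <= en) || !any(ce >= st & ce <= en))
        .stopf("transcript %s: CDS bounds outside exons", d$tx[1])
    }
    TranscriptModel(d$tx[1], d$gene[1], d$chrom[1], d$strand[1], exons,
                    cdsStartGenomic = cs, cdsEndGenomic = ce)
  })
  TranscriptSet(unname(models))
}

#' Write transcript models as GTF
#'
#' Emits one `exon` line per exon and, for coding transcripts, one `CDS`
#' line per exon/CDS intersection. Round-trips through [readGtf()].
#'
#' @param txset a [TranscriptSet-class]
#' @param path output file
#' @return `path`, invisibly.
#' @export
writeGtf <- function(txset, path) {
  stopifnot(is(txset, "TranscriptSet"))
  lines <- character(0)
  for (m in txset@models) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s"; gene_name "%s";',
                     m@gene, m@transcriptId, m@gene)
    st <- IRanges::start(m@exons); en <- IRanges::end(m@exons)
    lines <- c(lines, sprintf("%s\ttoy\texon\t%d\t%d\t.\t%s\t.\t%s",
                              m@chrom, st, en, m@strand, attrs))
    if (m@biotype == "protein_coding") {
      cs <- pmax(st, m@cdsStartGenomic); ce <- pmin(en, m@cdsEndGenomic)
      keep <- cs <= ce
      lines <- c(lines, sprintf("%s\ttoy\tCDS\t%d\t%d\t.\t%s\t0\t%s",
                                m@chrom, cs[keep], ce[keep], m@strand, attrs))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

## Column layouts of the supported caller dialects. The `generic` dialect is
## the reference; the others are deterministic re-mappings of the same
## information. All dialects carry sample_id as the first column so that a
## single file can hold a cohort.
.DIALECTS <- list(
  generic = list(cols = c("sample_id", "gene5", "gene3", "breakpoint5",
                          "breakpoint3", "spanning_reads", "crossing_reads")),
  arriba = list(cols = c("sample_id", "gene1", "gene2", "breakpoint1",
                         "breakpoint2", "strand1", "strand2", "split_reads",
                         "discordant_mates")),
  defuse = list(cols = c("sample_id", "gene_name1", "gene_name2",
                         "genomic_break_pos1", "genomic_break_pos2",
                         "genomic_strand1", "genomic_strand2",
                         "span_count", "splitr_count")),
  soapfuse = list(cols = c("sample_id", "up_gene", "up_chr", "up_hit_pos",
                           "up_strand", "dw_gene", "dw_chr", "dw_hit_pos",
                           "dw_strand", "junc_reads", "span_reads")),
  clc = list(cols = c("sample_id", "five_gene", "three_gene",
                      "five_breakpoint", "three_breakpoint", "fusion_reads"))
)

#' Read a caller report in one of the supported dialects
#'
#' Normalizes a tab-separated caller report into canonical
#' [FusionCallSet-class] records: 1-based breakpoints, strands of the fused
#' segments, spanning (junction) and crossing (encompassing) read counts.
#' Rows whose coordinates cannot be parsed are dropped and tallied in the
#' returned object's skip count.
#'
#' Dialect column layouts (all tab-separated, with header):
#' \itemize{
#' \item `generic`: sample_id, gene5, gene3, breakpoint5 ("chr:pos:strand"),
#'   breakpoint3, spanning_reads, crossing_reads
#' \item `arriba`: sample_id, gene1, gene2, breakpoint1 ("chr:pos"),
#'   breakpoint2, strand1, strand2, split_reads, discordant_mates
#' \item `defuse`: sample_id, gene_name1, gene_name2, genomic_break_pos1
#'   ("chr:pos"), genomic_break_pos2, genomic_strand1, genomic_strand2,
#'   span_count, splitr_count (splitr_count maps to spanning_reads)
#' \item `soapfuse`: sample_id, up_gene, up_chr, up_hit_pos, up_strand,
#'   dw_gene, dw_chr, dw_hit_pos, dw_strand, junc_reads, span_reads
#' \item `clc`: sample_id, five_gene, three_gene, five_breakpoint
#'   ("chr:pos:strand"), three_breakpoint, fusion_reads (no crossing count;
#'   it is reported as 0)
#' }
#'
#' @param path tab-separated report file
#' @param dialect one of `"arriba"`, `"defuse"`, `"soapfuse"`, `"clc"`,
#'   `"generic"`
#' @return A [FusionCallSet-class] with caller set to `dialect`.
#' @export
readCallerCalls <- function(path, dialect) {
  if (!dialect %in% names(.DIALECTS))
    .stopf("unknown caller dialect: %s (known: %s)", dialect,
           paste(names(.DIALECTS), collapse = ", "))
  if (!file.exists(path)) .stopf("call file not found: %s", path)
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = "character")
  need <- .DIALECTS[[dialect]]$cols
  missing <- setdiff(need, names(df))
  if (length(missing))
    .stopf("dialect '%s': required column(s) absent: %s", dialect,
           paste(missing, collapse = ", "))
  if (!nrow(df)) return(FusionCallSet(skipped = 0L))

  parseRow <- switch(dialect,
    generic = function(r) {
      b5 <- .parseBreakpoint(r[["breakpoint5"]])
      b3 <- .parseBreakpoint(r[["breakpoint3"]])
      list(b5 = b5, b3 = b3, g5 = r[["gene5"]], g3 = r[["gene3"]],
           span = r[["spanning_reads"]], cross = r[["crossing_reads"]])
    },
    arriba = function(r) {
      b5 <- .parseBreakpoint(r[["breakpoint1"]], r[["strand1"]])
      b3 <- .parseBreakpoint(r[["breakpoint2"]], r[["strand2"]])
      list(b5 = b5, b3 = b3, g5 = r[["gene1"]], g3 = r[["gene2"]],
           span = r[["split_reads"]], cross = r[["discordant_mates"]])
    },
    defuse = function(r) {
      b5 <- .parseBreakpoint(r[["genomic_break_pos1"]], r[["genomic_strand1"]])
      b3 <- .parseBreakpoint(r[["genomic_break_pos2"]], r[["genomic_strand2"]])
      list(b5 = b5, b3 = b3, g5 = r[["gene_name1"]], g3 = r[["gene_name2"]],
           span = r[["splitr_count"]], cross = r[["span_count"]])
    },
    soapfuse = function(r) {
      b5 <- .parseBreakpoint(paste(r[["up_chr"]], r[["up_hit_pos"]], sep = ":"),
                             r[["up_strand"]])
      b3 <- .parseBreakpoint(paste(r[["dw_chr"]], r[["dw_hit_pos"]], sep = ":"),
                             r[["dw_strand"]])
      list(b5 = b5, b3 = b3, g5 = r[["up_gene"]], g3 = r[["dw_gene"]],
           span = r[["junc_reads"]], cross = r[["span_reads"]])
    },
    clc = function(r) {
      b5 <- .parseBreakpoint(r[["five_breakpoint"]])
      b3 <- .parseBreakpoint(r[["three_breakpoint"]])
      list(b5 = b5, b3 = b3, g5 = r[["five_gene"]], g3 = r[["three_gene"]],
           span = r[["fusion_reads"]], cross = "0")
    })

  rows <- vector("list", nrow(df))
  skipped <- 0L
  for (i in seq_len(nrow(df))) {
    p <- parseRow(as.list(df[i, , drop = FALSE]))
    span <- suppressWarnings(as.integer(p$span))
    cross <- suppressWarnings(as.integer(p$cross))
    if (is.null(p$b5) || is.null(p$b3) || is.na(span)) {
      skipped <- skipped + 1L
      next
    }
    if (is.na(cross)) cross <- 0L
    rows[[i]] <- data.frame(
      sample_id = df$sample_id[i], caller = dialect,
      gene5 = trimws(p$g5), gene3 = trimws(p$g3),
      chrom5 = p$b5$chrom, pos5 = p$b5$pos, strand5 = p$b5$strand,
      chrom3 = p$b3$chrom, pos3 = p$b3$pos, strand3 = p$b3$strand,
      spanning_reads = span, crossing_reads = cross,
      stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  calls <- if (length(rows)) do.call(rbind, rows) else .emptyCallTable()
  FusionCallSet(calls, skipped = skipped)
}

#' Write / read the canonical calls TSV
#'
#' The canonical layout is the package's reference exchange format:
#' tab-separated with header `sample_id, caller, gene5, gene3, chrom5, pos5,
#' strand5, chrom3, pos3, strand3, spanning_reads, crossing_reads`.
#' `writeCanonicalCalls()` then `readCanonicalCalls()` round-trips
#' field-by-field.
#'
#' @param x a [FusionCallSet-class]
#' @param path file path
#' @return `writeCanonicalCalls()`: the number of rows written;
#'   `readCanonicalCalls()`: a `FusionCallSet`.
#' @export
writeCanonicalCalls <- function(x, path) {
  stopifnot(is(x, "FusionCallSet"))
  write.table(x@calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  nrow(x@calls)
}

#' @rdname writeCanonicalCalls
#' @export
readCanonicalCalls <- function(path) {
  if (!file.exists(path)) .stopf("calls file not found: %s", path)
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  missing <- setdiff(CANONICAL_CALL_COLS, names(df))
  if (length(missing))
    .stopf("canonical calls: required column(s) absent: %s",
           paste(missing, collapse = ", "))
  FusionCallSet(df)
}

#' Export consensus events as BEDPE
#'
#' Standard BEDPE: 0-based half-open single-base intervals for each
#' breakpoint, `name = gene5--gene3`, `score` = maximum spanning-read
#' support, strands in columns 9-10. Internal coordinates are 1-based
#' closed, so a breakpoint at position p becomes the interval [p-1, p).
#'
#' @param x a [ConsensusEventSet-class]
#' @param path output file
#' @return Number of rows written.
#' @export
writeBedpe <- function(x, path) {
  stopifnot(is(x, "ConsensusEventSet"))
  evs <- x@events
  con <- file(path, "w")
  on.exit(close(con))
  if (!length(evs)) return(0L)
  for (ev in evs) {
    score <- max(vapply(ev$support_by_sample, function(s) s[["spanning"]],
                        numeric(1)))
    writeLines(paste(ev$chrom5, ev$pos5 - 1L, ev$pos5,
                     ev$chrom3, ev$pos3 - 1L, ev$pos3,
                     paste0(ev$gene5, "--", ev$gene3), score,
                     ev$strand5, ev$strand3, sep = "\t"), con)
  }
  length(evs)
}

#' Read a protein-domain table
#'
#' Tab-separated with header `transcript_id, domain_name, aa_start, aa_end,
#' oncogenic` (0/1 or TRUE/FALSE). Amino-acid coordinates are 1-based
#' inclusive.
#'
#' @param path file path
#' @return data.frame with columns `transcript_id`, `name`, `aa_start`,
#'   `aa_end`, `oncogenic`.
#' @export
readDomainTable <- function(path) {
  if (!file.exists(path)) .stopf("domain table not found: %s", path)
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("transcript_id", "domain_name", "aa_start", "aa_end", "oncogenic")
  missing <- setdiff(need, names(df))
  if (length(missing))
    .stopf("domain table: required column(s) absent: %s",
           paste(missing, collapse = ", "))
  onc <- df$oncogenic
  onc <- if (is.numeric(onc) || is.logical(onc)) as.numeric(onc) != 0 else
    toupper(trimws(onc)) %in% c("1", "TRUE", "T", "YES")
  out <- data.frame(transcript_id = df$transcript_id, name = df$domain_name,
                    aa_start = as.integer(df$aa_start),
                    aa_end = as.integer(df$aa_end),
                    oncogenic = onc, stringsAsFactors = FALSE)
  if (any(out$aa_start < 1L) || any(out$aa_end < out$aa_start))
    .stopf("domain table: need 1 <= aa_start <= aa_end")
  out
}

#' Read a cohort sample sheet
#'
#' Tab-separated with header `sample_id, tissue_class, patient_id`;
#' `tissue_class` must be one of LM (liver metastasis), pCRC (primary
#' tumour), N (normal).
#'
#' @param path file path
#' @return data.frame with unique `sample_id` rows.
#' @export
readSampleSheet <- function(path) {
  if (!file.exists(path)) .stopf("sample sheet not found: %s", path)
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("sample_id", "tissue_class", "patient_id")
  missing <- setdiff(need, names(df))
  if (length(missing))
    .stopf("sample sheet: required column(s) absent: %s",
           paste(missing, collapse = ", "))
  validateSampleSheet(df)
}

#' Validate a sample sheet data.frame
#' @param df data.frame with `sample_id`, `tissue_class`, `patient_id`
#' @return the validated data.frame
#' @export
validateSampleSheet <- function(df) {
  if (anyDuplicated(df$sample_id))
    .stopf("sample sheet: duplicate sample_id(s): %s",
           paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  bad <- setdiff(unique(df$tissue_class), TISSUE_CLASSES)
  if (length(bad))
    .stopf("sample sheet: tissue_class must be one of %s (got %s)",
           paste(TISSUE_CLASSES, collapse = "/"), paste(bad, collapse = ", "))
  df[, c("sample_id", "tissue_class", "patient_id"), drop = FALSE]
}
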