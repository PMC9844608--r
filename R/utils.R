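#' @importFrom methods new validObject is slot show
#' @importClassesFrom IRanges IRanges
#' @importMethodsFrom IRanges start end width
#' @importMethodsFrom S4Vectors "[" length rev
#' @importFrom stats median pnorm pchisq rnorm rpois rexp runif setNames na.omit
#' @importFrom utils read.delim write.table read.csv write.csv combn head tail
#'   packageVersion
NULL

## Strand glyphs seen in published tables include the typographic minus;
## normalize everything to "+"/"-" once, at the boundary.
.normStrand <- function(s) {
  s <- gsub("−|–", "-", trimws(s))
  s
}

.checkStrand <- function(s, what = "strand") {
  s <- .normStrand(s)
  bad <- !s %in% c("+", "-")
  if (any(bad)) {
    stop(sprintf("invalid %s value(s): %s", what,
                 paste(unique(s[bad]), collapse = ", ")), call. = FALSE)
  }
  s
}

## Round half away from zero (base round() rounds half to even).
roundHalfAway <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

## Lower-median: for an even number of values take the lower of the two
## middles, keeping representatives at observed coordinates.
lowerMedian <- function(x) {
  x <- sort(x)
  x[(length(x) + 1L) %/% 2L]
}

.isCount <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == as.integer(x)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

## Parse "chr:pos" or "chr:pos:strand"; returns NULL when pos is not an
## integer so callers can drop and tally the row.
.parseBreakpoint <- function(txt, strand = NA_character_) {
  parts <- strsplit(trimws(txt), ":", fixed = TRUE)[[1]]
  if (length(parts) < 2L) return(NULL)
  pos <- suppressWarnings(as.integer(parts[2]))
  if (is.na(pos) || pos < 1L) return(NULL)
  if (length(parts) >= 3L) strand <- parts[3]
  strand <- .normStrand(strand)
  if (!strand %in% c("+", "-")) return(NULL)
  list(chrom = parts[1], pos = pos, strand = strand)
}

TISSUE_CLASSES <- c("LM", "pCRC", "N")
CALLER_NAMES <- c("arriba", "defuse", "soapfuse", "clc", "generic")
EXCLUSIVITY_CLASSES <- c("LM_unique", "pCRC_unique", "common", "normal_present")
FRAME_STATUSES <- c("in_frame", "out_of_frame", "five_prime_utr_fusion", "noncoding")

## Canonical calls table column order (the reference TSV layout).
CANONICAL_CALL_COLS <- c("sample_id", "caller", "gene5", "gene3",
                         "chrom5", "pos5", "strand5",
                         "chrom3", "pos3", "strand3",
                         "spanning_reads", "crossing_reads")

.emptyCallTable <- function() {
  data.frame(sample_id = character(), caller = character(),
             gene5 = character(), gene3 = character(),
             chrom5 = character(), pos5 = integer(), strand5 = character(),
             chrom3 = character(), pos3 = integer(), strand3 = character(),
             spanning_reads = integer(), crossing_reads = integer(),
             stringsAsFactors = FALSE)
}
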