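## End-to-end orchestration: simulate (optional) -> ingest -> consensus ->
## cascade -> annotate -> nominate -> stats -> quant/survival -> report,
## plus the packaged worked-example fixtures.

#' Load a packaged worked-example fixture
#'
#' `"table1"`: the curated set of fourteen recurrent in-frame driver fusion
#' transcripts from a published metastatic colorectal cancer cohort, with
#' gene pairs, breakpoints, strands, printed frame labels, functional
#' domain names, chromosomal type, carrier sample lists and per-sample
#' junction read counts. The printed frame labels are stored verbatim and
#' all fourteen rows are treated as frame-passing drivers.
#' `"table2_counts"`: the published cohort-level category tallies
#' (intra/interchromosomal, coding/non-coding, in-frame/out-of-frame per
#' exclusivity class) with the printed percentages.
#'
#' @param name `"table1"` or `"table2_counts"`
#' @return data.frame; for `"table1"` the `samples` and `read_counts`
#'   columns are list-columns.
#' @export
loadFixture <- function(name) {
  known <- c("table1", "table2_counts")
  if (!name %in% known)
    .stopf("unknown fixture '%s'; available: %s", name,
           paste(known, collapse = ", "))
  if (name == "table2_counts") {
    path <- system.file("extdata", "table2_counts.tsv",
                        package = "fusionCascade", mustWork = TRUE)
    return(read.delim(path, stringsAsFactors = FALSE))
  }
  path <- system.file("extdata", "table1_fusions.tsv",
                      package = "fusionCascade", mustWork = TRUE)
  df <- read.delim(path, stringsAsFactors = FALSE)
  df$samples <- strsplit(df$samples, ";", fixed = TRUE)
  df$read_counts <- lapply(strsplit(df$read_counts, ";", fixed = TRUE),
                           as.integer)
  bp5 <- lapply(df$breakpoint5, .parseBreakpoint, strand = "+")
  bp3 <- lapply(df$breakpoint3, .parseBreakpoint, strand = "+")
  df$chrom5 <- vapply(bp5, `[[`, character(1), "chrom")
  df$pos5 <- vapply(bp5, `[[`, integer(1), "pos")
  df$chrom3 <- vapply(bp3, `[[`, character(1), "chrom")
  df$pos3 <- vapply(bp3, `[[`, integer(1), "pos")
  df
}

#' Consensus events from the table1 fixture
#'
#' Rebuilds the curated driver set as a [ConsensusEventSet-class] (all
#' carrier samples are liver metastases) so cohort operations --
#' recurrence, BEDPE export, exclusivity -- run on it directly.
#'
#' @param tab1 output of `loadFixture("table1")`
#' @return A [ConsensusEventSet-class] with one event per fixture row.
#' @export
fixtureAsEvents <- function(tab1 = loadFixture("table1")) {
  events <- lapply(seq_len(nrow(tab1)), function(i) {
    samples <- tab1$samples[[i]]
    counts <- tab1$read_counts[[i]]
    support <- lapply(counts, function(cc) c(spanning = cc, crossing = 0))
    names(support) <- samples
    list(gene5 = tab1$gene5[i], gene3 = tab1$gene3[i],
         chrom5 = tab1$chrom5[i], pos5 = tab1$pos5[i],
         strand5 = .normStrand(tab1$strand5[i]),
         chrom3 = tab1$chrom3[i], pos3 = tab1$pos3[i],
         strand3 = .normStrand(tab1$strand3[i]),
         callers_by_sample = setNames(rep(list("generic"), length(samples)),
                                      samples),
         support_by_sample = support,
         samples_by_class = list(LM = samples, pCRC = character(0),
                                 N = character(0)))
  })
  ConsensusEventSet(events)
}

.readPipelineConfig <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) .stopf("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) .stopf("config must be a list or a YAML file path")
  known <- c("seed", "simulate", "inputs", "consensus", "filters",
             "nomination", "quant", "survival")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    .stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  config
}

#' Run the full fusion-discovery pipeline
#'
#' Executes simulate (optional) -> ingest -> consensus -> filter cascade ->
#' annotate -> nominate -> cohort stats -> expression/survival -> report.
#' With `simulate: yes` (the default) the synthetic cohort generator
#' produces every input under `outDir/inputs`; otherwise `inputs` must name
#' the call files (with dialects), sample sheet, GTF, domain table and,
#' optionally, Ct and survival tables. All randomness derives from
#' `config$seed`; a rerun with the same seed reproduces every report
#' byte-for-byte.
#'
#' Config keys (all optional): `seed`; `simulate` (logical or a list of
#' [simulationConfig()] arguments); `inputs` (list: `calls` = named list
#' dialect -> path, `sheet`, `gtf`, `domains`, `ct`, `survival`);
#' `consensus` (`min_tools`, `breakpoint_tol`); `filters` (`min_support`,
#' `target_class`); `nomination` (`score_threshold`, `min_recurrence`);
#' `quant` (`calibrator`).
#'
#' @param config list or path to a YAML file
#' @param outDir output directory (created)
#' @return The run manifest (config echo, seed, per-stage row counts,
#'   output paths), invisibly; also written as `manifest.json`.
#' @export
runPipeline <- function(config = list(), outDir) {
  config <- .readPipelineConfig(config)
  seed <- config$seed %||% 1L
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  counts <- list()

  simulate <- config$simulate %||% TRUE
  if (!identical(simulate, FALSE)) {
    simArgs <- if (is.list(simulate)) simulate else list()
    simArgs$seed <- seed
    simConfig <- do.call(simulationConfig, simArgs)
    bundle <- simulateCohort(simConfig, dir = file.path(outDir, "inputs"))
    callSets <- bundle$callSets
    sheet <- bundle$sheet
    txset <- bundle$txset
    domains <- bundle$domains
    driverScores <- bundle$driverScores
    ct <- bundle$ct
    surv <- bundle$surv
  } else {
    inputs <- config$inputs
    if (is.null(inputs)) .stopf("config key 'inputs' required when simulate: no")
    for (key in c("calls", "sheet", "gtf", "domains")) {
      if (is.null(inputs[[key]])) .stopf("config inputs lacks key '%s'", key)
    }
    callSets <- lapply(setNames(names(inputs$calls), names(inputs$calls)),
                       function(d) readCallerCalls(inputs$calls[[d]], d))
    sheet <- readSampleSheet(inputs$sheet)
    txset <- readGtf(inputs$gtf)
    domains <- readDomainTable(inputs$domains)
    driverScores <- NULL
    ct <- if (!is.null(inputs$ct))
      read.csv(inputs$ct, stringsAsFactors = FALSE) else NULL
    surv <- if (!is.null(inputs$survival))
      read.csv(inputs$survival, stringsAsFactors = FALSE) else NULL
  }

  allCalls <- FusionCallSet(do.call(rbind, lapply(callSets, fusionCalls)))
  counts$calls <- length(allCalls)

  tol <- config$consensus$breakpoint_tol %||% 10L
  minTools <- config$consensus$min_tools %||% 2L
  validated <- crossValidate(allCalls, minTools = minTools, tol = tol)
  counts$validated_clusters <- nrow(validated)

  events <- mergeEvents(validated, sheet, tol = tol)
  counts$events <- length(events)
  writeBedpe(events, file.path(outDir, "events.bedpe"))
  write.table(eventTable(events), file.path(outDir, "events.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  cascade <- applyCascade(events, txset, config$filters %||% list())
  counts$passing_events <- length(cascade$passing)
  write.table(cascade$trace, file.path(outDir, "filter_trace.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE, na = "")

  annAll <- annotateEvents(events, txset, domains, driverScores,
                           config = config$nomination %||% list())
  annPassing <- annAll[annAll$event %in%
                         vapply(consensusEvents(cascade$passing), eventId,
                                character(1)), , drop = FALSE]
  write.table(annAll, file.path(outDir, "annotation.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  nominated <- annPassing[annPassing$nominated, , drop = FALSE]
  counts$nominated <- nrow(nominated)
  write.table(nominated, file.path(outDir, "nominated.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE, na = "")

  cohort <- tabulateCohort(annAll)
  write.table(cohort, file.path(outDir, "cohort_counts.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  recur <- recurrenceTable(events)
  write.table(recur, file.path(outDir, "recurrence.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  testReport <- list()
  if (!is.null(ct)) {
    rq <- ddct(ct, config$quant$calibrator %||% "group:pCRC")
    write.csv(rq, file.path(outDir, "relative_expression.csv"),
              row.names = FALSE, quote = FALSE)
    groups <- split(rq$rq, rq$group)
    if (length(groups) == 2L) {
      rs <- rankSumTest(groups[[1]], groups[[2]])
      testReport$rank_sum <- list(groups = names(groups), U = rs$U, p = rs$p,
                                  method = rs$method)
    }
  }
  if (!is.null(surv)) {
    sdf <- data.frame(time = surv$time_months, event = surv$event,
                      fusion_positive = as.logical(surv$fusion_positive))
    kmPos <- kmEstimate(sdf, sdf$fusion_positive)
    kmNeg <- kmEstimate(sdf, !sdf$fusion_positive)
    write.table(kmPos, file.path(outDir, "km_fusion_positive.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(kmNeg, file.path(outDir, "km_fusion_negative.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    lr <- logrankTest(sdf)
    testReport$log_rank <- list(chisq = lr$chisq, p = lr$p)
  }
  if (length(testReport))
    jsonlite::write_json(testReport, file.path(outDir, "test_report.json"),
                         auto_unbox = TRUE, digits = NA)

  manifest <- list(
    package_version = as.character(utils::packageVersion("fusionCascade")),
    seed = seed, config = config, stage_counts = counts,
    stage_order = c("simulate", "ingest", "consensus", "cascade",
                    "annotate", "nominate", "stats", "quant_survival",
                    "report"))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
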