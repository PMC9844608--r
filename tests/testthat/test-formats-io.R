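# Format ingestion: GTF transcript models, caller dialects, canonical TSV
# round-trip, BEDPE export.

test_that("readGtf builds models from a minimal file and infers biotype", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id "G1"; transcript_id "T1"; gene_name "G1";',
    'chr1\tsrc\texon\t301\t400\t.\t+\t.\tgene_id "G1"; transcript_id "T1"; gene_name "G1";',
    'chr1\tsrc\tCDS\t151\t350\t.\t+\t0\tgene_id "G1"; transcript_id "T1"; gene_name "G1";',
    'chr2\tsrc\texon\t501\t700\t.\t-\t.\tgene_id "G2"; transcript_id "T2"; gene_name "G2";'),
    gtf)
  txset <- readGtf(gtf)
  expect_equal(length(txset), 2L)
  t1 <- getTranscript(txset, "T1")
  expect_equal(t1@biotype, "protein_coding")
  expect_equal(length(t1@exons), 2L)
  expect_equal(t1@cdsStartGenomic, 151L)
  expect_equal(t1@cdsEndGenomic, 350L)
  t2 <- getTranscript(txset, "T2")
  expect_equal(t2@biotype, "noncoding")
  expect_true(is.na(t2@cdsStartGenomic))
})

test_that("readGtf names the line of a feature lacking transcript_id", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id "G1"; transcript_id "T1";',
    'chr1\tsrc\texon\t301\t400\t.\t+\t.\tgene_id "G1";'), gtf)
  expect_error(readGtf(gtf), "transcript_id.*line 2")
})

test_that("generated toy annotation round-trips through GTF", {
  ann <- buildToyAnnotation(zeroNoiseConfig(3L))
  gtf <- tempfile(fileext = ".gtf")
  writeGtf(ann$txset, gtf)
  back <- readGtf(gtf)
  expect_equal(length(back), length(ann$txset))
  for (id in names(ann$txset@models)) {
    a <- getTranscript(ann$txset, id); b <- getTranscript(back, id)
    expect_equal(IRanges::start(a@exons), IRanges::start(b@exons))
    expect_equal(IRanges::end(a@exons), IRanges::end(b@exons))
    expect_equal(a@cdsStartGenomic, b@cdsStartGenomic)
    expect_equal(a@cdsEndGenomic, b@cdsEndGenomic)
    expect_equal(a@strand, b@strand)
    expect_equal(a@gene, b@gene)
    expect_equal(a@biotype, b@biotype)
  }
})

test_that("generic dialect parses the worked ADAP1-NOC4L row", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c(
    paste(c("sample_id", "gene5", "gene3", "breakpoint5", "breakpoint3",
            "spanning_reads", "crossing_reads"), collapse = "\t"),
    "S1\tADAP1\tNOC4L\tchr7:959605:-\tchr12:132635526:+\t6\t0"), f)
  cs <- readCallerCalls(f, "generic")
  expect_equal(length(cs), 1L)
  expect_equal(skippedRows(cs), 0L)
  call <- fusionCalls(cs)
  expect_equal(call$chrom5, "chr7")
  expect_equal(call$pos5, 959605L)
  expect_equal(call$strand5, "-")
  expect_equal(call$chrom3, "chr12")
  expect_equal(call$pos3, 132635526L)
  expect_equal(call$strand3, "+")
  expect_equal(call$spanning_reads, 6L)
})

test_that("header-only files and unparseable coordinates are handled", {
  f <- tempfile(fileext = ".tsv")
  hdr <- paste(c("sample_id", "gene5", "gene3", "breakpoint5", "breakpoint3",
                 "spanning_reads", "crossing_reads"), collapse = "\t")
  writeLines(hdr, f)
  cs <- readCallerCalls(f, "generic")
  expect_equal(length(cs), 0L)
  expect_equal(skippedRows(cs), 0L)

  writeLines(c(hdr,
               "S1\tA\tB\tchrX:abc:+\tchr1:100:+\t5\t0",
               "S1\tA\tB\tchr2:50:+\tchr1:100:+\t5\t0"), f)
  cs <- readCallerCalls(f, "generic")
  expect_equal(length(cs), 1L)
  expect_equal(skippedRows(cs), 1L)
})

test_that("unknown dialects and missing columns are named errors", {
  f <- tempfile(fileext = ".tsv")
  writeLines("a\tb", f)
  expect_error(readCallerCalls(f, "starfusion"), "unknown caller dialect")
  expect_error(readCallerCalls(f, "arriba"), "column")
})

test_that("the same fusion normalizes identically from every dialect", {
  base <- makeCall(pos5 = 959605L, strand5 = "-", chrom5 = "chr7",
                   pos3 = 132635526L, strand3 = "+", chrom3 = "chr12",
                   spanning_reads = 6L, crossing_reads = 2L)
  for (dialect in c("generic", "arriba", "defuse", "soapfuse", "clc")) {
    cs <- FusionCallSet(transform(base, caller = dialect))
    f <- tempfile(fileext = ".tsv")
    fusionCascade:::.writeDialect(cs, f, dialect)
    back <- fusionCalls(readCallerCalls(f, dialect))
    cols <- setdiff(names(back), c("caller", "crossing_reads"))
    expect_equal(back[, cols], fusionCalls(cs)[, cols],
                 ignore_attr = TRUE)
    # clc carries no crossing count; everything else round-trips it
    if (dialect != "clc") expect_equal(back$crossing_reads, 2L)
  }
})

test_that("canonical calls TSV round-trips field-by-field", {
  calls <- rbind(makeCall(), makeCall(sample_id = "S2", caller = "arriba",
                                      pos5 = 42L, strand5 = "-"))
  cs <- FusionCallSet(calls)
  f <- tempfile(fileext = ".tsv")
  expect_equal(writeCanonicalCalls(cs, f), 2L)
  back <- readCanonicalCalls(f)
  expect_equal(fusionCalls(back), fusionCalls(cs))
})

test_that("BEDPE export converts 1-based closed to 0-based half-open", {
  ev <- makeEvent(pos5 = 959605L, chrom5 = "chr7",
                  pos3 = 132635526L, chrom3 = "chr12", LM = "S1",
                  support = 6)
  f <- tempfile(fileext = ".bedpe")
  n <- writeBedpe(ConsensusEventSet(list(ev)), f)
  expect_equal(n, 1L)
  fields <- strsplit(readLines(f), "\t")[[1]]
  # independent conversion: the single base p maps to [p-1, p)
  expect_equal(as.integer(fields[2:3]), c(959605L - 1L, 959605L))
  expect_equal(as.integer(fields[5:6]), c(132635526L - 1L, 132635526L))
  expect_equal(fields[7], "GENEA--GENEB")

  expect_equal(writeBedpe(ConsensusEventSet(), f), 0L)
  expect_length(readLines(f), 0L)
})

test_that("the fourteen curated driver fusions export as fourteen BEDPE rows", {
  ev <- fixtureAsEvents()
  f <- tempfile(fileext = ".bedpe")
  expect_equal(writeBedpe(ev, f), 14L)
  expect_length(readLines(f), 14L)
})

test_that("sample sheet validation rejects duplicates and bad classes", {
  expect_silent(validateSampleSheet(toySheet()))
  bad <- toySheet(); bad$sample_id[2] <- "S1"
  expect_error(validateSampleSheet(bad), "duplicate")
  bad2 <- toySheet(); bad2$tissue_class[1] <- "tumour"
  expect_error(validateSampleSheet(bad2), "tissue_class")
})
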