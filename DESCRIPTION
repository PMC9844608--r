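Package: fusionCascade
Title: Consensus Filtering and Driver Nomination for Fusion Transcripts in
    Metastatic Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-processing of RNA-seq gene-fusion caller output for paired
    tumour/metastasis/normal cohorts. Normalizes caller-specific report
    dialects into canonical fusion calls, cross-validates calls between
    callers within a sample, merges them into cohort-level consensus events,
    and applies a filter cascade (read support, coding mapping, normal-tissue
    exclusion, metastasis exclusivity). Mapped junctions are annotated for
    reading-frame status and retained protein domains, and candidate driver
    fusions are nominated by oncogenic-domain retention, external driver
    score and recurrence. Includes cohort category tabulation, relative
    expression quantification by the 2^-ddCt method with rank-sum
    comparison, Kaplan-Meier survival stratification with the log-rank test,
    and a fully deterministic synthetic-cohort generator with planted ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'formats-io.R'
    'consensus.R'
    'filters.R'
    'annotation.R'
    'stats.R'
    'quant.R'
    'survival.R'
    'synthetic.R'
    'pipeline.R'
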