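---
title: "Methods: consensus filtering, frame annotation and driver nomination for fusion transcripts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus filtering, frame annotation and driver nomination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fusionCascade)
```

# Scope and model

`fusionCascade` post-processes RNA-seq fusion-caller output for cohorts of
paired liver-metastasis (LM), primary colorectal tumour (pCRC) and normal
(N) samples. It does not call fusions from reads; its inputs are the
tabular reports of upstream callers, transcript models, a protein-domain
table, a sample sheet, and optionally qPCR Ct and survival tables. Its
outputs are cohort-level consensus events, a filter trace, frame and
domain annotations, driver nominations, category tallies, relative
expression estimates and survival stratifications.

## Coordinate conventions

All genomic coordinates are 1-based and closed. A fusion breakpoint pair
is (last transcribed base of the 5′ segment, first transcribed base of
the 3′ segment) — the convention that makes a published single-position
breakpoint notation unambiguous. BEDPE export converts to 0-based
half-open single-base intervals. Transcript-orientation arithmetic is
strand-aware: on a `-` transcript the first exon is the one with the
highest genomic coordinates and offsets run high to low.

## Consensus across callers and samples

Two calls match iff their ordered gene pairs, chromosomes and strands
agree at both ends and both position differences are at most `tol`
nucleotides. Clustering is transitive (single linkage), which makes the
event set independent of input order; a cluster's representative
breakpoint is the per-end lower-median of its members (the lower of the
two middle values for even counts), a deterministic tie-break that keeps
representatives at observed coordinates. Distinct-caller counting treats
multiple calls from one caller as a single vote. Within each sample,
clusters reported by at least `min_tools` distinct callers survive; the
requirement is applied per sample, since a caller's support for a fusion
in one sample says nothing about its evidence in another. Validated
per-sample clusters sharing gene pair, chromosomes and strands then merge
across samples under the same tolerance.

**Defaults.** `tol = 10` nt: callers that place a junction at slightly
different exon-boundary coordinates (alignment clipping, one-off
conventions) typically differ by a few bases, while distinct junctions of
the same gene pair are usually hundreds of bases apart, so any value in
the 5–50 nt range behaves identically on realistic data. `min_tools = 2`:
the cross-validation standard for consensus fusion discovery.

## The filter cascade

Stage order is fixed: cross-validation (performed during consensus) →
read support → coding mapping → normal exclusion → tissue exclusivity.
Order matters only for attributing a failure to its first failing stage
in the trace; the surviving set is order-independent because the stages
are independent predicates.

* **Read support**: maximum spanning-read count over carrier samples
  must reach `min_support` (default 5, inclusive — values of exactly 5
  are common in curated driver tables, so the boundary is exercised).
  Crossing (encompassing) read counts are carried through and reported
  but not thresholded: junction support counts spanning reads with or
  without crossing reads.
* **Coding**: both partner genes need at least one protein-coding
  transcript whose exon union contains the respective breakpoint. An
  unannotated gene or an intronic breakpoint is a recorded failure
  (reasons `"unannotated"`, `"not exonic"`), never an exception, so one
  bad record cannot abort a cohort run.
* **Normal exclusion**: any event carried by an N sample is removed.
* **Exclusivity**: presence/absence over tissue classes. `LM_unique`
  (metastasis-only) is the default target. Metastasis-specific
  upregulation is operationalized as exclusivity rather than as a
  count-based differential test: per-event junction read counts are far
  too sparse for a calibrated test, and presence/absence is what a
  cohort's exclusivity tallies actually measure. The four classes
  (`LM_unique`, `pCRC_unique`, `common`, `normal_present`) partition the
  event set.

## Reading-frame annotation

For a junction mapped to transcript coordinates, let *r* be the count of
CDS nucleotides of the 5′ partner from its CDS start through the
breakpoint inclusive, and *s* the count of 3′-partner CDS nucleotides
strictly upstream of its breakpoint. The chimeric coding sequence is the
first *r* coding bases of the 5′ partner followed by the 3′ CDS from
position *s*+1, so the 3′ portion is translated in its native frame iff
*r* ≡ *s* (mod 3): `in_frame` is phase equality, `out_of_frame` is
inequality. Two special cases precede the phase test: if either partner
lacks a CDS the chimera is `noncoding`; if the 5′ breakpoint lies
upstream of the 5′ CDS start the junction is a `five_prime_utr_fusion`
(read-through-like), with `intact_3p_orf` true when the 3′ breakpoint is
at or upstream of the 3′ CDS start — such chimeras translate only the
downstream ORF and are therefore not counted as in-frame in cohort
tallies, but their 3′ domains are fully retained.

Phase equality is a purely arithmetic criterion; it does not scan the
junction codon for a chance stop. The package therefore also provides a
sequence-level translation oracle (`translationFrameCheck`): the chimeric
cDNA is translated from the 5′ CDS start and the chimera is in frame iff
the native C-terminal peptide of the 3′ protein appears in the
translation. A frameshift makes that match astronomically improbable for
random coding sequence, so the oracle is independent of the phase
arithmetic; the test suite asserts their agreement on 200 random planted
junctions, and the acceptance script re-measures it.

**Transcript choice.** One transcript per gene is used for annotation:
the id supplied with the calls when available, otherwise the longest CDS.
Curated driver tables pin specific transcript ids, so the hint path is
the primary one.

## Domain retention and nomination

With junction amino acids J5 = ⌊r/3⌋ (last complete retained codon) and
A3 = ⌊s/3⌋ + 1 (first retained 3′ residue), a 5′ domain [a, b] is
preserved iff b ≤ J5 and a 3′ domain iff a ≥ A3 — conservative
inequalities: a domain straddling the junction is treated as lost. For a
read-through with intact 3′ ORF, all 3′ domains and no 5′ domain are
preserved. Out-of-frame chimeras preserve nothing (`"no ORF"`).

Nomination requires an oncogenic criterion AND recurrence: (≥ 1 preserved
domain flagged oncogenic OR external driver score > `score_threshold`,
default 0.8, strict) AND ≥ `min_recurrence` distinct metastatic carrier
samples (default 2). The driver score is an external input column (e.g.
from a Bayesian fusion classifier); it is consumed, never recomputed.
The oncogenic flag on domains is data, not a hard-coded vocabulary: the
domain table's `oncogenic` column decides, so a user's domain curation
(kinase, zinc finger, ArfGAP, CBF, SPT4, proteasome activator, SMAD/FHA,
RING, ...) is respected as given.

## Cohort tallies

Per exclusivity class, three dichotomies are tabulated over the same
denominator (the class total): intra/interchromosomal, coding/non-coding,
in-frame/out-of-frame. Non-coding or unmappable events count on the
non-coding and out-of-frame sides, which is what makes the published
tallies' dichotomies share one denominator. Percentages are rounded half
away from zero to one decimal; published tables of this kind are not
always internally consistent in their rounding, so only self-consistent
cells are used as reference values in tests.

## Expression and survival

Relative expression follows 2^−ΔΔCt: ΔCt = target − reference Ct per
sample, ΔΔCt = ΔCt − ΔCt(calibrator), RQ = 2^−ΔΔCt. The default
calibrator is the mean ΔCt of the pCRC group, so RQ directly expresses
metastatic over primary fold change; a named sample can be used instead
(its RQ is then exactly 1, an identity the tests assert for every
calibrator choice). Group comparison uses the Mann–Whitney U with
mid-ranks for ties; the two-sided p is exact by complete enumeration of
all labelings when the pooled size is ≤ 12 (exact even under ties, since
the permutation distribution of the mid-rank U is enumerated directly)
and a normal approximation with tie and continuity corrections
otherwise. This differs from the common implementation choice of
abandoning exactness whenever ties occur, which is why the statistic is
implemented here and cross-checked against `wilcox.test` on tie-free
data.

Survival stratification is by binary fusion positivity (no expression
cut-point search): Kaplan–Meier product-limit curves per stratum and the
log-rank test (observed − expected with hypergeometric variance, 1 df),
computed via the `survival` package behind the module interface and
verified in tests against an independent brute-force risk-table
computation. Degenerate inputs are defined, not exceptional: a cohort
with no events in either stratum yields statistic 0 and p = 1; an empty
stratum is an error. Tests are two-sided at α = 0.05 with no
multiple-testing correction by default (matching common practice for a
handful of candidate fusions); Benjamini–Hochberg can be applied by the
user via `p.adjust` on the reported p-values.

One property worth stating precisely: appending a subject censored after
the last event does *not* leave the Kaplan–Meier step values unchanged —
the extra subject enlarges every risk set, changing each (1 − d/n)
factor. What is true, and what the tests assert, is that no new step is
introduced: the drop times are unchanged and the addition appears only as
a trailing censoring mark.

# The synthetic cohort generator

The generator exists so the full pipeline can be validated against
planted ground truth. Its defaults are the study conditions, not tuning
knobs.

* **Cohort structure**: 24 patients with LM/pCRC/N triples plus 7
  unpaired LM samples (79 samples), mirroring the paired-cohort design
  the pipeline targets.
* **Annotation**: 20 protein-coding and 2 non-coding transcripts on 3
  toy chromosomes; 3–8 exons of 150–300 nt, introns of 60–400 nt, UTRs
  of 60–200 nt. Every CDS starts ATG, ends with a stop, is divisible by
  3 and has no internal in-frame stop. The transcript FASTA stores
  mature (spliced) sequences consistent with the GTF exon structure —
  that is the input the translation oracle needs; no genome FASTA is
  emitted.
* **Planted catalog** (10 entries): a headline interchromosomal in-frame
  driver in 7 LM samples with oncogenic domains preserved on both sides
  of the junction; a 5′UTR read-through in 8 LM samples with an intact
  downstream ORF and a preserved 3′ oncogenic domain; an out-of-frame
  passenger; a primary-only fusion; a shared (LM+pCRC) fusion; a
  normal-present fusion; a non-coding-partner fusion; a
  below-threshold-support fusion; a single-caller fusion; and a
  no-domain fusion nominated via an external driver score of 0.85. Each
  entry exercises exactly one decision point of the cascade.
* **Caller noise**: per-caller sensitivities (0.85–0.95), breakpoint
  jitter as a rounded Normal(0, 2 nt), and ~0.5 private false positives
  per sample per caller. False positives never reuse a planted gene pair
  — they model *private* noise, and aliasing a planted fusion would
  silently contaminate truth comparisons. Support per fusion per carrier
  is 5 + Poisson(mean − 5) when the planted mean is ≥ 5, putting many
  values exactly at the read-support boundary so the inclusive ≥ 5
  comparison is genuinely exercised; sub-threshold plants draw a
  zero-truncated Poisson.
* **Expression**: reference Ct ~ Normal(20, 0.3); target Ct = reference
  + 5 − log2(fold) for metastatic carriers plus Normal(0, 0.3) noise;
  fold 4, 12 samples per group.
* **Survival**: exponential times with baseline hazard 0.03/month and
  hazard ratio 3 for carriers of the headline fusion; 30% of samples
  censored uniformly on (0, t).

Determinism: every generator function seeds the RNG from the single
config seed (with fixed small offsets per stage), so the entire emitted
bundle — annotation, call files, truth table, Ct and survival tables —
is byte-identical under a fixed seed.

**What the generator does not emulate**: read-level data (no FASTQ, no
alignment artifacts), realistic splice-motif sequence content, caller-
specific systematic biases (only symmetric jitter), expression variation
between carriers beyond Gaussian Ct noise, and genomic-vs-transcriptomic
origin of junctions. Passing the planted-truth suites therefore
demonstrates the correctness of the post-processing arithmetic and
bookkeeping, not robustness to upstream alignment pathology.

# Numerical choices and degenerate inputs

* Rounding of percentages: half away from zero (base `round` is
  half-to-even, which printed tables do not use).
* Median tie-break: lower of two middles, keeping representatives at
  observed coordinates.
* Unparseable caller rows are dropped and tallied, never fatal;
  header-only files yield empty call sets.
* `percentOf` with a zero denominator, a calibrator group with no
  samples, an empty KM stratum, and an event carried by no sample are
  errors; all-identical rank-sum input degenerates to p = 1 with a
  warning.
* Strand glyphs: typographic minus signs in published tables are
  normalized to ASCII `-` at the parsing boundary.

# Validation problem sizes

The test suite validates on: 200 random junctions for the
frame-vs-translation-oracle agreement; a zero-noise 79-sample cohort for
exact planted-truth recovery; 2000 simulated null cohorts (n = 30 per
arm) for log-rank type-I calibration (5% ± 2%); 500 cohorts at hazard
ratio 3 for power (≥ 90%); 200 replicates of the fold-4 expression plant
for fold recovery; and byte-level comparison of complete rerun outputs
for determinism. These sizes give stable pass/fail behaviour at
negligible runtime on a single CPU.

# Known limitations

* One transcript per gene; alternative isoforms of the same gene are not
  annotated jointly.
* The frame rule is arithmetic; a chance stop codon created at the
  junction is not detected unless the translation oracle is consulted
  with sequences.
* Exclusivity is presence/absence; low-coverage samples can masquerade
  as non-carriers, and no attempt is made to model detection sensitivity
  at the cohort-classification stage.
* The per-sample two-tool rule (rather than per-cohort) is a design
  choice; a fusion seen by one caller in each of two samples is
  discarded. `min_tools = 1` relaxes this.
* Published cohort-scale discovery counts from real sequencing runs are
  not reproducible here by construction: they depend on the raw
  sequencing data and the upstream callers, which are out of scope.
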