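---
title: "Detecting extrachromosomal circular DNA from circle-enriched libraries"
author: "eccpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting extrachromosomal circular DNA from circle-enriched libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eccpipe)
```

## The problem

Extrachromosomal circular DNA (eccDNA) consists of small circular DNA
elements, typically hundreds of bases to a few kilobases, excised from
chromosomal sequence. Circle-enriched sequencing libraries (circle-seq /
cirSeq) remove linear DNA by exonuclease digestion, amplify the surviving
circles by rolling-circle amplification (RCA), and sequence the product as
standard paired-end Illumina reads. The circles themselves are never
observed directly: they are inferred from three alignment signatures that a
circular template leaves on a linear reference:

1. **Split reads.** RCA produces a tandem concatemer of the circle, so a
   read can run off the circle's end and continue at its start. The aligner
   reports this as a right-clipped primary alignment near the circle end
   plus a left-clipped supplementary alignment at the circle start, on the
   same chromosome and strand, with the leading read segment mapping
   *downstream* of the trailing one. This geometry is the precise,
   base-resolution evidence: the trailing segment's start and the leading
   segment's end are the two breakpoints.
2. **Outward-facing (RF) discordant pairs.** A sequenced fragment spanning
   the junction leaves its two mates pointing away from each other in
   linear coordinates. The pair brackets the junction only to insert-size
   resolution, so it corroborates rather than places breakpoints.
3. **Coverage enrichment.** Reads pile up on circle intervals relative to
   the (nearly empty) rest of the genome.

`eccpipe` implements the full path from alignments to cohort statistics:
evidence extraction, breakpoint clustering and calling, catalog
characterization (length histograms, chromosome of origin, gene content),
and the cohort layer (group tests, median stratification, correlation with
expression). A seeded simulator generates every input — reference, gene
models, reads with known circle ground truth — so the whole pipeline is
testable without downloads.

## Coordinate convention

All intervals are 0-based half-open internally, so `length = end - start`
everywhere; a call printed as chr1:57,239,706–57,240,822 has length 1116
bp. GFF3 files are converted to and from their native 1-based inclusive
convention at the I/O boundary, BED output is natively 0-based half-open,
and SAM positions are converted from 1-based on parse.

## The simulator

`sim_config()` collects every tunable. The generator models:

* **Circle lengths** as a log-normal truncated to `[200, 10000]` bp with
  `meanlog = log(1200)`, `sdlog = 0.8`. These defaults place about 91% of
  the mass in the 400–6000 bp window that dominates observed liver eccDNA
  catalogs; `length_dist_mass()` evaluates the analytic mass so tests can
  compare simulated catalogs against their target distribution.
* **Origin classes** with default weights 0.597 intergenic, 0.400 partial
  gene, 0.003 full gene — circle catalogs are overwhelmingly intergenic or
  partial-gene, with full genes rare (a few per thousand). A full-gene
  circle must contain a gene, so its length is redrawn from the same
  distribution conditioned on exceeding the shortest gene span; placement
  is class-targeted rejection sampling verified by the content classifier.
* **RCA** as tandem concatemerization: a geometric copy number with
  minimum 2 and mean `rca_fold = 10`, followed by uniform fragmentation.
  This reproduces both diagnostic signatures (split reads at the junction,
  RF pairs) without the unidentifiable branching structure of real
  strand-displacement amplification. The effective fold amplification and
  the insert geometry (normal, mean 350 bp, sd 50, truncated to
  `[200, 1000]`) are assumptions, stated here and exposed in the config,
  since library protocols do not pin them down.
* **Sequencing** as 150-bp FR (innie) paired-end reads with
  substitution-only errors (default 0.001/base) and flat Q30 qualities.
  The caller's evidence logic is clip- and orientation-based, so indel and
  quality realism would add parameters without exercising any additional
  code path.
* **Linear background** (default 1% of pairs; incomplete exonuclease
  digestion) as uniform random genomic fragments in proper FR orientation.

The simulator emits the alignments itself (a "truth SAM") because every
template position is known exactly; no external aligner is required, and
FASTQ output is available for users who want to run one. A supplementary
record is emitted only when both junction segments are at least 20 bp,
mirroring aligners' refusal to seed very short segments; shorter overhangs
stay as soft clips on the primary record. Substitution errors are applied
per read, so a primary and its supplementary record carry the same
sequence.

## The caller

`call_circles()` runs four stages, each exposed separately:

1. `parse_alignments()` — SAM/BAM via Rsamtools, retaining unmapped
   records and reporting the mapped fraction as QC.
2. `extract_split_junctions()` / `extract_discordant_pairs()` — the two
   evidence classes above; non-circular split geometry, cross-chromosome
   or cross-strand splits, proper FR pairs and over-long spans are tallied,
   never silently dropped.
3. `coverage_profile()` — per-base depth from reference-consuming CIGAR
   ops, summarized in 50-bp bins; the background is the genome-wide median
   bin depth plus a pseudocount (0.01 reads/bp) so enrichment stays
   defined when most of the genome is empty, as it is in circle-enriched
   data.
4. `cluster_and_call()` — single-linkage clustering of split junctions
   with tolerance `epsilon` on *both* breakpoints (verified against a
   brute-force transitive closure in the tests); per-cluster median
   breakpoints; discordant corroboration; thresholding; merging.

The published evidence classes come without thresholds, so the defaults
are design choices tuned for precision and all configurable
(`caller_config()`): `epsilon = 5` bp, a call needs `min_split = 2` split
reads or 1 split read plus `min_discordant_rescue = 2` outward-facing
pairs, `min_enrichment = 2` over background, and a length in
`[200, 1e7]` bp. Two decisions deserve emphasis:

* **Discordant pairs never call on their own.** Their breakpoints are only
  insert-size accurate; letting them call would inflate "unique eccDNA"
  counts with poorly localized duplicates.
* **Counting is per merged call, per sample.** A unique eccDNA is a
  distinct merged (start, end) cluster within one sample; no cross-sample
  deduplication is applied, matching per-sample catalog counting. Whether
  upstream duplicate-read removal should further deflate support is left
  to the user's aligner/dedup choice; the caller counts the records it is
  given.

Degenerate inputs are defined: empty evidence yields an empty catalog;
zero mapped reads yield an all-zero profile with pseudocount background;
ties in the subtype vote and in cluster medians resolve deterministically
(medians round half away from zero via `round()`; support-weighted means
for merged depth).

## Catalog characterization

`summarize_catalog()` reproduces the standard catalog descriptors: a
half-open 200-bp length histogram, the fraction of calls in
`[400, 6000)` bp (half-open, consistent with the binning; the boundary
convention is declared rather than inherited), per-chromosome counts and
mean lengths, and gene content. The content trichotomy is:

* `full_gene` — at least one entire gene span inside the call
  (containment wins over any other overlap);
* `intergenic` — no overlap with any gene span (gene span means
  UTR-to-UTR, not exons only);
* `partial_gene` otherwise, subtyped by the feature kind with the largest
  overlapped base count, ties broken intron > exon > 5'UTR > 3'UTR. A
  single-label rule is needed because catalogs report one subtype per
  circle; dominant base-pair overlap is the least arbitrary such rule, and
  the tie order favours the empirically dominant intronic class. The
  classifier is verified against a per-base brute force in the tests.

Percentages render at two significant figures (`0.31%`, `0.075%`), the
precision at which such fractions are conventionally reported.
`chromosome_distribution()` adds the chi-square goodness-of-fit test of
counts against chromosome length, flagging cells with expected counts
below 1 rather than failing.

## Cohort layer

`per_sample_summary()` rolls catalogs into one row per sample. Group
comparisons use the classical unpaired two-sided pooled-variance Student's
t test for two groups (Welch behind a flag; two groups that are both
constant return the degenerate t = 0, p = 1 rather than an error) and
one-way ANOVA for more than two; both are delegated to `stats` and checked
against hand-written closed forms, including the F = t² identity, in the
tests. Fold changes are ratios of arithmetic group means of raw counts.
No multiple-testing correction is applied at this layer — per-test
p-values are reported, and correction is the caller's prerogative.

`stratify_high_low()` splits at the median; the tie rule (median-valued
samples fill whichever group is currently smaller, low first, in table
order) is an invention of this package — published analyses rarely state
one — and is documented as such. The cutpoint itself is configurable by
stratifying on any column. `correlate()` reports Pearson's r, R², and the
two-sided p-value from the t transform of r, refusing zero-variance input
rather than returning NaN. `cosimulate_expression()` closes the loop for
validation: markers generated as `alpha + beta * burden + N(0, sigma²)`
have a known population correlation with burden, so the cohort layer's
estimates can be checked against truth (noiseless r = 1 exactly; recovery
within Fisher-z bounds otherwise).

## Problem sizes and what the tests show

The validation suite runs entirely on simulated data at deliberately
modest scale, chosen to exercise every code path with comfortable
statistical margins: recovery runs use a 3 Mb two-chromosome genome with
50 circles at roughly 60x coverage (15,000 read pairs); oracle-agreement
checks use 100 random clustering instances (up to 200 junctions) and
1000 random classification instances; statistical recovery uses
n = 1000 samples with 20 replicate seeds. Under clean conditions the
caller recovers simulations essentially perfectly (recall and precision
above 0.95 at ±5 bp), and recovery stays above 0.90 at a 0.005/base error
rate with 5% linear background.

Passing these tests shows the implementation is faithful to its own model
of the data. Real libraries differ in ways the simulator deliberately
omits: repeats and mappability (the synthetic genome is i.i.d. sequence,
so alignment is unambiguous), PCR duplicates, GC-coverage bias, chimeric
artifacts between circles, branching RCA structure, indels, and quality
variation. On real data, recall and precision depend on the upstream
aligner producing supplementary alignments (SA-tag-style) and will be
lower than on simulations; the thresholds in `caller_config()` are the
levers to trade precision against sensitivity.

## Known limitations

* Multi-fragment circles (junctions joining distant loci,
  chromothripsis-style) are out of scope; such splits are tallied, not
  called.
* Genes in the synthetic annotation are non-overlapping and
  single-transcript; content classes are defined per gene, so isoform
  ambiguity is not modelled.
* The caller does not realign soft-clipped tails; it consumes the split
  alignments it is given.
* Copy-number estimation of amplified circles is not attempted; coverage
  is used only as an enrichment filter.

## A worked example

```{r example, eval = FALSE}
asm <- make_reference(2, c(1e6, 2e6), gc = 0.41, seed = 7)
ann <- make_annotation(asm, 40, c(2000, 8000), c(2, 5), seed = 8)
cfg <- sim_config(n_circles = 20, n_read_pairs = 8000, seed = 9)
circles <- sample_circles(asm, ann, cfg)
truth <- simulate_reads(asm, circles, cfg, out_prefix = tempfile())
catalog <- call_circles(truth$sam_path, chrom_lengths(asm),
                        caller_config(), sample_id = "demo")
summary(catalog, ann)
evaluate_calls(circles, catalog)
```
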