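---
title: "coopdeg: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{coopdeg: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coopdeg)
```

# The analysis this package implements

`coopdeg` targets a recurring design in regulatory genomics: a mutant
is compared with its control by replicated bulk RNA-seq, and the
resulting differential-expression profile is then related to *other*
contrasts — a second mutant in the same pathway, or the transcriptome
change between two developmental stages — to ask whether the two
regulators act on a shared gene program and whether the misregulated
genes are the ones that should have been switched at that stage. The
package implements each analytical step as a small, separately testable
operation, and ships a synthetic-data generator whose ground truth
exercises every step end to end.

# Differential expression

## Expression scale and the test

Counts are converted to RPKM, `counts * 1e9 / (length_bp *
total_mapped)`. Significance comes from a two-tailed two-sample
t-test with pooled variance, computed by default on `log2(RPKM + 1)`.
The log transform is a variance-stabilization choice: at three
replicates per condition a raw-scale t-test is dominated by the
mean-variance coupling of expression data, while on the log scale the
per-gene replicate spread is roughly comparable across the expression
range. Welch's test and a raw-RPKM mode are available by flag; none of
the modes claims bit-compatibility with any particular commercial
pipeline, whose internal test is generally not documented.

When the per-sample total of mapped reads is known (a `total_mapped`
column in the design), RPKM uses it. This is the preferred source: a
real library's mapped total is a genome-wide quantity, not the sum of
whichever gene panel is in the table. Falling back to column sums is
supported but couples every gene's RPKM to the composition of the
panel — with strongly asymmetric differential expression that coupling
biases all null genes in the opposite direction, a standard failure
mode of per-panel normalization.

## Signed fold changes

Fold changes follow the negative-reciprocal convention used in
differential-expression reporting: with pseudocount-stabilized means,
`FC = m_b / m_a` when the ratio is at least 1 and `-m_a / m_b`
otherwise, so `|FC| >= 1` always and a 40-fold drop reads as -40.
`log2FC` is the plain log ratio and shares the sign. The pseudocount
(default 0.01 RPKM) exists because genes that fall to near-zero
expression in one condition otherwise produce arbitrarily large
ratios; it leaves moderately expressed genes essentially untouched.
The fully degenerate case — both means zero with a zero pseudocount —
returns an `NA` sentinel rather than an error, since a single silent
gene should not abort a whole contrast.

## DEG status

A gene is `up` when `FC >= 2` and `q < 0.05` (Benjamini-Hochberg over
all tested genes), `down` symmetrically, and `filtered` when its mean
RPKM is at most 1 in *both* conditions — the filter reads "mean RPKM
above 1 in at least one condition" with a strict inequality, and it
overrides significance. Zero-variance degeneracies have an explicit
policy: equal means give p = 1, unequal means give the smallest
representable positive p, and either case is flagged in the output
instead of silently dropped. Developmental (stage-to-stage) calls are
threshold-only — `|FC| > 2`, no test — because public stage
compendia usually provide fold changes without usable replicate
structure.

# Six-way expression-level classification

For classification only, each DEG's condition mean is divided by the
arithmetic mean over the *expressed* genes of that condition
(expression threshold: mean RPKM strictly above 0; configurable), so
normalized expression averages exactly 1 per condition. Direction plus
below/above-average level in each condition defines six clusters,
C1-C6. Two sign/level combinations are logically possible but not part
of the six definitions (a down-DEG below average in control yet above
it in the mutant, and the mirror case), and exact ties at 1 are
likewise undefined; all of these are reported as `unclassified` rather
than forced into a neighboring cluster, so the partition property
(every DEG gets exactly one label; odd clusters sum to the down count,
even to the up count when nothing is unclassified) stays checkable. A
gene silent in one condition has normalized expression 0, which is
simply "below average". The normalization is scale-free per condition,
so unit changes cannot move labels.

# Cross-contrast concordance

Two contrasts are compared on genes present in both tables, optionally
restricted to the DEGs of either side or to the common DEGs. The
correlation is the sample Pearson coefficient with the classical
t-distribution p-value on n-2 degrees of freedom. Quadrant counts
classify each gene by the signs of its two log2 fold changes; exact
zeros lie on an axis, are excluded from all quadrants, and are reported
separately (conservation: quadrants + axis genes = n). Per-direction
percentages — of the genes moving one way in contrast x, the share
moving each way in contrast y — are rounded half away from zero to one
decimal, the convention of printed summaries (646/707 prints as 91.4).
Companion tables produced externally (e.g. a microarray contrast) are
accepted as plain `gene_id`/`log2_fc`/`status` tables and are never
recomputed.

qPCR validation uses delta-delta-Ct against a reference gene
(`fold = 2^(-ddCt)`), and its agreement with RNA-seq is computed on
the log2 scale. The signed-FC scale has a jump discontinuity across
1/-1 that would distort a correlation; log2 is the natural common
scale.

# Genomic proximity of a gene set

The clustering statistic is the median (mean by flag) of consecutive
TSS-to-TSS distances within the member set, per chromosome;
cross-chromosome pairs contribute nothing. The null keeps every real
gene position fixed and redraws which genes carry the member label —
this preserves the gene-density landscape of the genome, which a
coordinate-randomizing null would destroy, and is therefore the
conservative implementation of "randomized positions". The median was
chosen over the mean because inter-gene spacing is heavy-tailed to the
right. The test is one-sided toward clustering, with the add-one
empirical p `(1 + #[null <= observed]) / (N + 1)`, so p is never zero
and is exactly calibrated under exchangeability. N = 1000 permutations
by default; fewer than 100 records a warning in the result object. A
Wilcoxon rank-sum comparison of the observed distances against pooled
null distances is attached as a clearly secondary, non-canonical
readout.

# Overrepresentation and promoter motifs

Term overrepresentation is the standard one-sided hypergeometric upper
tail with BH correction across tested terms, against a background that
defaults to the expressed (unfiltered) genes — the natural universe
for a DE study. This is a generic overrepresentation stage; it makes
no attempt to reproduce any specific annotation service's network
machinery.

Promoters are 600-bp windows: 500 bp upstream of the TSS and 100 bp
downstream, in transcription orientation (for a minus-strand gene, the
reverse complement of the mirrored forward-strand window; the TSS base
itself is offset 0). Windows that run off a chromosome end are
truncated and flagged. Motif counting is exact string matching on the
sense strand only, with overlapping occurrences counted by default;
IUPAC ambiguity codes are rejected rather than silently expanded.
Copy-number summaries report the 0/1/2/3+ fractions as one-decimal
percentages.

# The synthetic-data generator

The generator is first-class, tested code, and its defaults *are* the
study conditions the package is designed around:

* **Counts.** Negative-binomial with log-normal per-gene baselines
  (median 50 counts, sdlog 1.2) and dispersion 0.05, three replicates
  per condition — the standard overdispersed model for bulk RNA-seq at
  this replicate number. A `frac_deg` fraction of genes (default 0.1)
  carries planted effects: uniform `|log2FC|` in [1.5, 6] with a 5%
  extreme tail in [6, 10], 80% of effects positive, emulating a
  predominantly upregulated DEG set whose largest fold changes come
  from genes driven to near-zero expression on one side. Mutant means
  are `baseline * 2^effect`. Libraries are "sequenced" to a fixed
  nominal depth of 1e6 mapped reads recorded in the design, so with
  1-kb genes RPKM equals the raw count and the simulated panel cannot
  distort its own depth.
* **Companion and developmental contrasts.** A shared-signal plus
  independent-noise construction: the planted effect vector is
  standardized and mixed as `y = r x + sqrt(1 - r^2) e`, giving an
  expected Pearson correlation of exactly the target (default 0.65
  for the companion mutant; -0.7 among DEGs for the stage
  transition, with mild N(0, 0.8) noise for non-DEGs). Companion DEG
  status is thresholded at `|log2FC| >= 1`, as for an external result
  table that arrives without p-values.
* **Loci.** Genes of fixed 1-kb length on four chromosomes, spacing at
  least 1.1 kb and a 600-bp margin at each end, so promoter windows
  never collide or truncate; a `cluster_fraction` of the DEG labels
  (default 0.5) is laid down in tandem runs of 3-8 adjacent genes and
  the rest scattered.
* **Promoters and genome.** Promoter backgrounds are rejection-sampled
  free of the motif, planted copies are inserted non-overlapping and
  re-verified, and the optional synthetic genome stamps each promoter
  into exactly the window the extractor reads, so extraction
  round-trips byte-for-byte. The default copy plan puts the motif in
  66.6% of up-DEG promoters with 65/20/15% carrying 1/2/3 copies.
* **Terms and qPCR.** Enriched terms sample members with 15:1 odds in
  favor of the up-DEGs; the qPCR table is generated so that
  delta-delta-Ct reproduces a 7-gene panel's log2 fold changes up to
  0.1-cycle per-well noise.

What the generator does *not* emulate, and what passing tests
therefore do not show: GC and length biases, batch effects,
between-replicate library-size variation beyond a scaling factor,
isoform structure, correlated gene-gene noise, and annotation
hierarchies. Conclusions about real data still require the usual
diagnostics on that data.

# Numerical choices and problem sizes

Determinism is a contract throughout: every stochastic operation takes
a seed, the pipeline fans a single global seed out to fixed per-stage
seeds (`(seed mod 1000003) * 1009 + stage`), and output files carry no
timestamps, so a re-run reproduces identical checksums. Ties in the
permutation null count against clustering (`<=` in the empirical p),
the conservative direction. Percentages round half away from zero —
base R's banker's rounding would turn 0.25 into 0.2.

The bundled checks run at desk scale, sizes chosen to keep Monte-Carlo
error comfortably inside the asserted tolerances: 2,000 genes for
null-calibration and recovery of the DE caller (sensitivity and
empirical FDR against the truth table), 5,000 for generator
correlation targets (±0.05), 2,000 genes/200 members/1,000
permutations for the planted-cluster proximity test, and 200
repetitions of a 500-gene null for its type-I calibration. Oracle
equivalence is checked against independent implementations: BH against
the brute-force step-up definition, t-test p against numerical
integration of the t density, hypergeometric p against explicit
binomial-coefficient summation on small universes, and the Pearson p
against a 10^5-shuffle permutation null.

# Known limitations

* The t-test on three replicates has limited power for effects below
  about 1.5 log2 units at moderate expression; the DEG criteria are
  deliberately those of threshold-based reporting, not of count-model
  inference (negative-binomial GLMs are out of scope by design).
* The expression filter and BH correction interact: q-values are
  computed over all tested genes, filtered genes included, which is
  slightly conservative.
* One TSS per gene is taken as given; alternative promoters are not
  modeled.
* The proximity null conditions on the real position set; it cannot
  detect clustering that is a property of the position set itself
  rather than of the label assignment.
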