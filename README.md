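# coopdeg

Comparative differential-expression analysis for paired mutant
contrasts in bulk RNA-seq, built for studies that ask whether two
regulators (for example, a writer and an eraser of the same chromatin
mark) control a common gene program. The package takes a replicated
two-condition count or RPKM table, calls differentially expressed genes
(DEGs) under classical fold-change/FDR/expression criteria, classifies
them by expression level, and then quantifies how the contrast relates
to companion contrasts (a second mutant, a developmental stage
transition), whether the DEG loci cluster along the genome, which
annotation terms they overrepresent, what motif copies their promoters
carry, and how well qPCR fold changes agree with the sequencing
estimates. A fully specified synthetic-data generator with a recorded
truth table makes the entire chain testable without any external data.

## Methods at a glance

* **DEG calling** (`call_degs`). Per gene: condition means of
  RPKM = counts x 10^9 / (gene length x total mapped reads); signed
  fold change under the negative-reciprocal convention
  (FC = m_b/m_a if >= 1, else -m_a/m_b, so |FC| >= 1 always and a
  40-fold drop prints as -40); a two-tailed two-sample t-test (pooled
  variance on log2(RPKM + 1) by default, Welch and raw-scale modes by
  flag); Benjamini-Hochberg q-values. A gene is `up` when FC >= 2 and
  q < 0.05, `down` symmetrically, `filtered` when mean RPKM <= 1 in
  both conditions. Stage-transition calls (`call_developmental_degs`)
  use the FC +/-2 threshold alone, with no test.
* **Six-way classification** (`assign_clusters`). Each DEG's condition
  means are divided by the average over expressed genes of that
  condition; direction plus below/above-average level in each condition
  yields clusters C1-C6, with undefined combinations surfaced as
  `unclassified` instead of being forced.
* **Cross-contrast concordance** (`subset_compare`,
  `quadrant_summary`). Pearson r with the p-value from
  t = r sqrt((n-2)/(1-r^2)) on n-2 df, sign-quadrant counts of the
  paired log2FCs, and one-decimal per-direction percentages.
* **Genomic proximity** (`proximity_permutation_test`). Median of
  consecutive TSS-to-TSS distances within the DEG set, compared with a
  null that redraws equally many genes from the real loci (positions
  fixed, labels shuffled); one-sided, add-one-corrected empirical p.
* **Overrepresentation** (`hypergeometric_enrichment`). One-sided
  hypergeometric tail per term against an expressed-gene background,
  BH-corrected.
* **Promoter motifs** (`extract_promoter`, `count_motif`). 600-bp
  windows (500 bp upstream of the TSS, 100 bp downstream), in
  transcription orientation; exact-match copy counting with overlap
  semantics and TSS-relative offsets.
* **qPCR validation** (`qpcr_fold_change`, `validate_qpcr`).
  Delta-delta-Ct against a reference gene, fold change 2^(-ddCt), and
  Pearson agreement with the RNA-seq log2 fold changes.

## Worked example

```r
library(coopdeg)

cfg <- sim_config(n_genes = 1000, frac_deg = 0.1, seed = 4)
dat <- simulate_dataset(cfg)          # counts + truth + all side tables
de  <- call_degs(dat$matrix, "control", "mutant")
table(de$status)
#>     down filtered       ns       up
#>       16        1      906       77

cluster_counts(assign_clusters(de))$sizes
#>   C1   C2   C3   C4   C5   C6 unclassified
#>   11   26    5   26    0   25            0

subset_compare(de, dat$companion, "common_degs")
#> concordance over 85 genes (0 on an axis): r = 0.924, p = 2e-36
#> quadrants: up_up=71, up_down=0, down_up=0, down_down=14
#> percent by x-direction: up_up=100.0, up_down=0.0, down_up=0.0, down_down=100.0

proximity_permutation_test(dat$loci,
                           de$gene_id[de$status %in% c("up", "down")],
                           n_permutations = 1000, seed = 99)
#> proximity test (median_nn_distance): observed = 18088 bp over 93 members
#> empirical p = 0.01698 (1000 permutations, seed 99)
```

The 93 called DEGs (77 up, 16 down) recover the planted effects; the
85 genes also flagged in the companion contrast change in the same
direction in both (every x-up gene is y-up, every x-down gene is
y-down), and their loci sit closer together than label-shuffled nulls
(p ≈ 0.017 with half of the planted DEGs laid down in tandem runs).

An end-to-end run from a single YAML config, writing every stage's
table plus a checksummed manifest:

```r
run_pipeline(system.file("extdata", "demo_config.yaml",
                         package = "coopdeg"), "demo_out")
```

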