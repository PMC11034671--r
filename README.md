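# smoltomics

Multi-omics integration of liver gene regulation across Atlantic salmon
smoltification — the parr→smolt transformation that prepares a juvenile
fish for seawater — as a tested, reusable R pipeline. The package
implements the analysis layers of a four-timepoint design (weeks 1, 10,
19, 25; a short-photoperiod time course with long-photoperiod and
freshwater-control arms) over three molecular layers:

* **Expression** — an ANOVA-like per-gene F test on log2 CPM across
  weeks (DEGs at BH FDR < 0.05), hierarchical co-expression clustering
  of z-scored TPM profiles cut at k = 7 with a correlation > 0.5
  membership gate, Welch pairwise contrasts (photoperiod at weeks
  10/19, salinity at week 25; logFC = first arm − second), and
  hypergeometric pathway over-representation.
* **Chromatin** — union-merged ATAC peak sets across weeks,
  coverage-integral read counting, differential accessibility (DA)
  between key periods with direction = sign(log2 FC later/earlier),
  nearest-TSS peak→gene links (midpoint rule, lexicographic
  tie-break), promoter/exon/intron/intergenic annotation, and a
  per-cluster Fisher 2×2 of (up vs down DA peaks) × (linked gene in
  cluster c vs other clusters).
* **TF footprints** — occupancy scored as the dip in coverage at a
  motif site within a peak, `score = log2((flank+1)/(center+1))`,
  bound when score > 0.5; genome-wide per-motif binding change
  `log2((mean_B+1)/(mean_A+1))` with a seeded paired-permutation p;
  environment classification with the conjunction rule at |log2 FC| >
  0.1 (sea/fresh from weeks 1,19 vs 25; short/long from weeks 1,19 vs
  10); and Fisher enrichment of every (motif × 4-week binding pattern ×
  expression cluster) combination over the motif's DEG-linked sites
  (14 informative patterns).
* **Methylation** — Bismark-coverage CpGs filtered at ≥ 10 reads and
  the 99.9th coverage percentile, a 3-of-4 replicate consensus
  intersected across weeks, DMCs from a logit-proportion F test gated
  at FDR < 0.05 **and** max pairwise week-mean difference > 25
  percentage points, context annotation, and DMC–gene correlation over
  per-week means (significant at p < 0.05, |r| > 0.95) against a
  seeded random-pair null compared by a two-sample KS test.

A first-class synthetic-data generator (`sim_design()`,
`plant_truth()`, `simulate_annotation()`, `simulate_expression()`,
`simulate_atac()`, `simulate_methylation()`) emulates the study design
with planted, machine-readable ground truth — seven expression
archetypes, accessibility folds, footprint dips following planted
4-week binding patterns, methylation shifts — so recovery and
calibration are always measured against truth. See
`vignettes/smoltomics-methods.Rmd` for the full model description and
the reasoning behind every tunable default.

## Worked example

```r
library(smoltomics)

design <- sim_design(n_genes = 300L, n_chroms = 2L,
                     chrom_len = 1800000L, seed = 42L)
ann    <- simulate_annotation(design)
truth  <- plant_truth(design, ann)          # 105 genes across 7 archetypes
expr   <- simulate_expression(design, truth)

de <- run_anova_de(expr)                    # weeks 1/10/19/25, short group
length(de$degs)
#> [1] 115

cl <- cluster_degs(expr, de$degs)           # k = 7, correlation gate 0.5
table(cl$assignments$cluster, useNA = "ifany")
#>    1    2    3    4    5    6    7 <NA>
#>   16   15   15   21   16   17   14    1

pw <- run_pairwise_contrasts(expr, "salinity_w25")
head(pw$results[order(pw$results$p), c("feature_id", "logFC", "p", "FDR")], 3)
#>           feature_id     logFC            p         FDR
#> gene00047  gene00047 -3.042646 1.233347e-05 0.002320486
#> gene00222  gene00222  3.569227 1.546991e-05 0.002320486
#> gene00033  gene00033 -3.213514 4.486439e-05 0.004486439
```

115 of 300 genes are differential across the time course (the 105
planted archetype genes plus a handful of false positives at FDR 0.05);
all seven planted temporal archetypes are recovered as clusters, with
one gene excluded by the correlation gate. The salinity contrast
returns the planted seawater-responsive genes with the documented sign
convention (positive logFC = higher in the seawater arm).

The numbered drivers under `analysis/` run the full study in order —
`01_simulate.R` through `06_methylation.R` — writing their tables under
`results/analysis/` and printing what each stage found.

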