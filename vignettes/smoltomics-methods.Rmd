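---
title: "Methods: multi-omics integration across salmon smoltification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-omics integration across salmon smoltification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The study design this package models

Atlantic salmon undergo smoltification — a preparatory remodelling of
physiology before seawater entry — and the liver's metabolic gene
programs are reorganised across it. The package implements the analysis
layers of a four-timepoint liver multi-omics design: fish sampled at
weeks 1, 10, 19 and 25, where a short-photoperiod ("winter signal")
group is exposed to 8:16 light:dark between weeks 1 and 10, smoltifies
in freshwater to week 19, and moves to seawater until week 25. A
long-photoperiod arm (constant light, sampled at weeks 10 and 19) and a
week-25 freshwater control arm provide the photoperiod and salinity
contrasts. Three molecular layers are analysed and integrated: RNA-seq
counts, ATAC-seq chromatin accessibility with TF footprints, and RRBS
CpG methylation.

Everything runs on synthetic data with planted, machine-readable ground
truth (`sim_design()`, `plant_truth()`, `simulate_*()`), so each claim
the pipeline makes — sensitivity, direction, calibration — is measured
against truth rather than intent.

# Expression layer

Counts are modelled negative binomial: gene baselines are log-normal
around `base_mean` (default 200), library sizes vary ±20%, and the
dispersion default is 0.1, a typical bulk RNA-seq value. The
week-course test is a per-gene one-way F test on log2 CPM
(pseudocount 0.5) across the four weeks within one fish group, with
Benjamini–Hochberg control; pairwise contrasts use a Welch t on the
same transform with the sign convention first-named arm minus second
(short − long; seawater − freshwater control). This is a deliberate,
documented simplification relative to count-model quasi-likelihood
machinery: the package's claims concern the downstream integration, and
the F/Welch kernel is self-contained and calibrated on nulls (empirical
type I within ±2 points of nominal at 2,000 features in the acceptance
suite). Zero-variance features receive p = 1 rather than NA so the BH
denominator is stable.

Co-expression clustering follows the study's recipe: per-gene z-scored
TPM profiles of the differential genes, Euclidean distances,
hierarchical clustering cut at k = 7. The linkage method is not
dictated by anything we reimplement, so the default is Ward
(`ward.D2`), which yields compact clusters; it is an argument, not a
constant. Membership is correlation-gated: a gene whose Pearson
correlation to its own cluster's mean scaled profile is ≤ 0.5 is
excluded but keeps its failing correlation in the output. The gate is
computed on the same scaled profiles used for clustering — whether the
original procedure gated on scaled or raw TPM is not documentable, and
scaled is the coherent choice given the distance matrix. A
within/between sum-of-squares table across candidate k is reported for
the same model-selection inspection the k = 7 choice came from.

The seven planted archetypes are week-multiplier vectors (peak-to-
trough fold 8): induced at sea (0,0,0,1), smolt peak (0,0,1,0), up from
smoltification onward (0,0,1,1), photoperiod peak (0,1,0,0), high
pre-smolt (1,1,0,0), suppressed mid-experiment (1,0,0,1), and loss from
parr onward (1,0,0,0), exponentiated to multipliers. They are stylised
and mutually separable (pairwise profile correlation ≤ 0.58 in z-space)
— deliberately more separable than real co-expression structure, where
neighbouring clusters blend. Recovery numbers on these archetypes
(ARI ≥ 0.9) therefore demonstrate correctness of the chain, not
expected performance on real livers.

Pathway over-representation is the generic upper-tail hypergeometric
test with BH across pathways; it takes any pathway→gene mapping and
ships no pathway database. Note that exact tests on small counts are
conservative: under a random gene set the rejection rate sits at or
below nominal, not at it.

# Chromatin layer

Per-week peak sets are merged into a unified set by interval union;
book-ended intervals (gap 0) merge, matching the common merge
semantics, and each unified peak records which weeks contributed. Read
counting integrates coverage × width over each peak from per-replicate
bedGraph tracks. Differential accessibility between the three key
periods (weeks 1→10, 10→19, 19→25) reuses the Welch kernel on log2 CPM
of peak counts; `logFC` is later minus earlier, so "up" means more
accessible at the later timepoint.

Peaks link to genes by minimal |peak midpoint − TSS|; midpoint (rather
than nearest edge) is the documented choice, ties resolve to the
lexicographically smallest gene id, and the signed distance is negative
upstream of the TSS in the gene's orientation. Genomic context uses
precedence promoter > exon > intron > intergenic with a strand-aware
promoter window of 1,500 bp upstream / 500 bp downstream — a
conventional operational definition, configurable because "promoter"
has no canonical width.

The accessibility–expression association builds, per contrast and per
cluster c, the 2×2 table (up vs down DA peaks) × (nearest gene in
cluster c vs in another cluster), tested with Fisher's exact test. This
reconstruction of the "proportions greater between up and down peaks"
comparison is one of several defensible 2×2 constructions; it is
isolated in `da_deg_association()` so it can be swapped.

The generator plants accessibility folds (default 2×) that persist from
the later week of their contrast onward, and can optionally couple the
"up" direction of one contrast to one cluster's promoter peaks to plant
a direction–cluster association. Coverage is per-base Poisson around a
per-peak plateau height (10–30), zero outside peaks. One consequence
worth knowing: footprint dips that appear or disappear between weeks
change a peak's coverage integral by a few percent, so peaks hosting
dynamic sites can legitimately reach significance in the DA test — the
two layers share one signal, as they do in real ATAC data.

# Footprint layer

A bound TF protects its motif from transposase insertion, leaving a
local dip in coverage inside an otherwise accessible peak. The score is
the explicit flank/centre log-ratio: centre = mean coverage over the
motif span, flank = mean over 20 bp windows placed 5 bp away on both
sides, score = log2((flank + 1)/(centre + 1)); a site is bound when the
score exceeds 0.5. This replaces a full footprinting model
(bias-corrected continuous scores with a two-component bound/unbound
fit) with a desk-scale, fully specified scorer that honours the same
bound/unbound contract; the threshold 0.5 was calibrated on synthetic
null coverage (flat plateaus score ≈ 0, planted dips to 0.3× plateau
score ≈ 1.5–2). Replicates are pooled per week before scoring.
Footprint scoring deliberately uses no sequence: motif sites are
coordinates with a motif label, since occupancy, not motif discovery,
is the object.

Genome-wide change per motif between two weeks is
log2((mean score B + 1)/(mean score A + 1)), with significance from a
seeded paired permutation that swaps each site's two week labels
(default 1,000 permutations); motifs with fewer than 10 sites are
excluded. Bound-site counts are row z-scored across the four weeks for
display, constant rows mapping to zero.

Environment classification applies a conjunction rule on the pairwise
changes with a log2 cutoff of 0.1: "sea" requires more binding at week
25 than at both weeks 1 and 19; "fresh" is the mirror image; "short"
requires more binding at week 10 than at both weeks 1 and 19; "long"
the mirror; salinity and photoperiod labels are assigned independently.
The classification is a pure function of the change table, so applied
to a table shaped like the study's global-binding supplement it is
exactly reproducible. The package bundles
`synthetic_tf_reference()` — a frozen synthetic stand-in for that
supplement (the real table is not distributed with the text), built so
that its planted membership has 33 photoperiod-associated and 35
salinity-associated motifs, 30 of the latter decreasing and 5
increasing in seawater; the acceptance suite requires
`classify_environment()` to recover that membership exactly from the
change columns alone.

# Integration layer

Each site's bound/unbound calls across the four weeks are encoded as a
4-digit binding pattern in chronological order; of the 16 strings the
two constant ones ("0000", "1111") are non-informative, leaving 14.
For every motif M, pattern P and expression cluster C, the 2×2 over M's
cluster-linked sites is (pattern = P vs ≠ P) × (gene in C vs in another
cluster), tested with Fisher's exact test; sites link to genes through
their host unified peak's nearest-TSS link. The background is
restricted to the motif's own DEG-linked sites (within-motif design); a
pooled-background alternative would answer a different question
("does this motif bind near C at all") and is intentionally not the
default. Constant-pattern sites are excluded by default; excluding them
changes the number of tests but never a retained p-value.

The assumed-pattern map (which pattern a cluster's regulators "should"
show, e.g. bound only at week 25 for the seawater-induced cluster)
ships as an editable default keyed to the package's own archetypes; it
drives display flags (primary/secondary and a top-significance quantile
label per test family) and nothing else — no test or acceptance result
depends on its values, since the original assignment is figure-encoded
and not digit-exactly recoverable.

# Methylation layer

CpG records in Bismark coverage dialect (1-based, start = end, counts
authoritative over the percent field) are filtered per sample: coverage
≥ 10 reads, at or below the sample's 99.9th coverage percentile
(strict >, so a constant coverage distribution loses nothing), and on
whitelisted chromosomes. The consensus set keeps loci present in at
least 3 replicates of a week, intersected across weeks. Every dropped
locus carries a machine-readable reason, and drops reconcile exactly
with input minus output.

DMC calling is a one-way F test across weeks on logit-transformed
proportions, log((M + 0.5)/(U + 0.5)), with BH control — a documented
replacement for count-model machinery on methylated counts, keeping
the identical decision thresholds: a DMC needs FDR < 0.05 *and* a
maximum pairwise difference in per-week mean methylation above 25
percentage points. The "fold change > 25%" gate is interpreted as 25
absolute percentage points (the natural reading for a percentage-valued
score); per-week-pair log2 fold changes of mean methylated counts are
still reported for table compatibility. The NA-aware F test excludes
loci with fewer than 2 present replicates in any week and counts them.

Each DMC is annotated with genomic context and its nearest-TSS gene,
then correlated with that gene's expression: Pearson r over the four
per-week means on both sides (per-week means, not all samples, because
the week is the unit of the time course), significant at p < 0.05 and
|r| > 0.95. With n = 4 these two thresholds sit at the feasibility
boundary (|r| = 0.95 alone gives p ≈ 0.0501); the pair is honoured
literally. The null model draws uniformly random (DMC, gene) pairs with
a recorded seed and compares observed and null r distributions with a
two-sample Kolmogorov–Smirnov test; the generator plants methylation
dynamics but no methylation–expression coupling, so the expected
outcome — and the acceptance check — is a non-significant comparison,
mirroring the negative finding the design emulates.

# Numerical and reproducibility choices

* All internal coordinates are 0-based half-open; BED/bedGraph on disk
  are 0-based half-open, GTF is 1-based closed, Bismark coverage is
  1-based with start = end. Converters are mutually inverse and
  round-trip tested.
* Every stochastic step is seeded: generator functions derive
  deterministic sub-seeds from the design seed, and permutation/null
  routines take an explicit seed they record. Fixed seed means
  byte-identical outputs.
* Fisher's two-sided p is the conventional "sum of tables no more
  probable than observed"; odds ratios are sample ORs with a 0.5
  Haldane correction when a cell is zero, and a zero margin yields
  p = 1 with an undefined-OR flag. On small discrete tables exact
  p-values are conservative (stepwise, with mass at 1); they control
  the type-I rate from below but are *not* uniform under the null, so
  distribution-shape checks against the uniform will reject even for a
  correct implementation.
* Degenerate inputs fail loudly and specifically: empty libraries name
  the sample, infeasible gene packing names the required length,
  missing weeks list the weeks present, unknown contrasts list the
  valid names.

# Problem sizes

The test and acceptance runs use desk-scale instances chosen to make
the statistical claims measurable: 2,000 genes × 16 samples for
expression recovery and null calibration (700 planted archetype genes),
~250–400 peaks with 2 ATAC replicates per week for accessibility,
8–12 motifs × 30–45 sites for footprints, and 5,000 CpGs × 16 RRBS
samples with 500 planted 40-point shifts for methylation. The exact
oracle sweep covers all 135,751 2×2 tables with total ≤ 40 and a
10,000-peak nearest-TSS comparison against an all-pairs search.

# Limitations

The generator emulates coordinates, counts and coverage — not reads,
sequence content, GC or insertion bias, or mapping artefacts; planted
effects are cleaner and more separable than real biology; ATAC
replicate counts (2 per week) make per-peak inference power-limited,
exactly as in the emulated design. Passing recovery tests demonstrates
that the pipeline's logic is correct and calibrated under its stated
model, not that the same thresholds are optimal for a real dataset.
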