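#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study and write its reference files.
# The design mirrors the smoltification trial: weeks 1/10/19/25, a
# short-photoperiod time course with long-photoperiod and freshwater
# control arms, ATAC coverage with planted footprints, and RRBS tables.

source(file.path("analysis", "00_config.R"))

write_gtf_lite(annotation, file.path(RESULTS, "annotation.gtf"))
write_tss_tsv(annotation, file.path(RESULTS, "tss.tsv"))
write_ground_truth(truth, file.path(RESULTS, "ground_truth.json"))

expr <- simulate_expression(design, truth)
write_counts_tsv(expr$counts, file.path(RESULTS, "counts.tsv"))
write_tsv(expr$samples, "samples.tsv")

meth <- simulate_methylation(design, truth)
dir.create(file.path(RESULTS, "bismark"), showWarnings = FALSE)
for (sid in names(meth$records)) {
  write_bismark_coverage(meth$records[[sid]],
                         file.path(RESULTS, "bismark", paste0(sid, ".cov")))
}

cat("simulated", nrow(annotation$genes), "genes on", design$n_chroms,
    "chromosomes;", sum(!is.na(truth$genes$cluster)), "genes planted into 7",
    "archetypes;", nrow(truth$da_peaks), "planted DA peak effects;",
    sum(truth$cpgs$delta != 0), "planted DMCs\n")
cat("reference files written under", RESULTS, "\n")
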