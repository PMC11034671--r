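# Shared configuration for the analysis drivers: one seeded study design
# and its planted ground truth, recomputed deterministically by each step.

library(smoltomics)

RESULTS <- file.path("results", "analysis")
dir.create(RESULTS, showWarnings = FALSE, recursive = TRUE)

SEED <- 42L
design <- sim_design(n_genes = 300L, n_chroms = 2L, chrom_len = 1800000L,
                     seed = SEED)
annotation <- simulate_annotation(design)
truth <- plant_truth(design, annotation, n_cpgs = 2000L, n_dmc = 200L,
                     da_cluster_coupling = list(contrast = "w10_w19",
                                                cluster = 3L))

write_tsv <- function(df, name) {
  utils::write.table(df, file.path(RESULTS, name), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(df)
}
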