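#!/usr/bin/env Rscript
# Stage 5: encode per-site binding patterns across the four weeks and
# test every (motif, pattern, cluster) combination for enrichment among
# the motif's DEG-linked sites, then flag the assumed primary/secondary
# patterns expected from each cluster's expression trend.

source(file.path("analysis", "00_config.R"))

atac <- simulate_atac(design, truth)
unified <- merge_peak_sets(atac$peaks_by_week)
fp <- score_sites(atac$coverage_by_week, atac$motif_sites, unified,
                  design$chrom_len)
pat <- encode_patterns(fp, weeks = design$weeks)
cat("encoded", nrow(pat), "site patterns;", sum(pat$constant),
    "constant (excluded from testing)\n")

expr <- simulate_expression(design, truth)
de <- run_anova_de(expr)
cl <- cluster_degs(expr, de$degs)
links <- link_peaks_to_genes(unified, annotation)
site_host <- sites_to_host_peaks(atac$motif_sites, unified)

enr <- enrich_patterns(pat, site_host, links, cl$assignments)
enr <- flag_assumed_and_label(enr, top_quantile = 0.05)
write_tsv(enr, "pattern_enrichment.tsv")
cat(nrow(enr), "motif x pattern x cluster tests (",
    length(unique(enr$motif_id)), "motifs x 14 patterns x",
    length(unique(enr$cluster)), "clusters )\n")

top <- enr[enr$p < 0.01 & enr$odds_ratio > 1, ]
cat(nrow(top), "combinations enriched at p < 0.01; strongest:\n")
print(utils::head(top[order(top$p),
                      c("cluster", "motif_id", "pattern", "count",
                        "odds_ratio", "p", "assumed")], 5))

# cross-check against the planted motif-cluster couplings; recovered
# cluster labels are an arbitrary permutation of the planted archetypes,
# so map them by majority vote first
tru_cl <- truth$genes$cluster[match(cl$assignments$gene_id,
                                    truth$genes$gene_id)]
both <- !is.na(cl$assignments$cluster) & !is.na(tru_cl)
map <- apply(table(cl$assignments$cluster[both], tru_cl[both]), 1,
             function(r) as.integer(names(which.max(r))))
coup <- truth$motif_catalog[!is.na(truth$motif_catalog$coupled_cluster), ]
for (i in seq_len(nrow(coup))) {
  em <- enr[enr$motif_id == coup$motif_id[i], ]
  best <- em[which.min(em$p), ]
  cat(sprintf("%s planted (archetype %d, %s) -> top hit (archetype %d, %s)\n",
              coup$motif_id[i], coup$coupled_cluster[i], coup$pattern[i],
              map[[as.character(best$cluster)]], best$pattern))
}
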