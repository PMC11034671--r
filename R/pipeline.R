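#' @title Pipeline orchestration
#' @description One-call execution of the full synthetic-study workflow
#'   (simulate, expression, chromatin, footprints, integration,
#'   methylation) from a single config, writing per-stage tables and a
#'   run manifest with input hashes so unchanged stages are skipped on
#'   rerun.
#' @name pipeline
NULL

#' Default pipeline configuration
#'
#' Flat sections per module; every threshold the pipeline uses appears
#' here with its default.
#'
#' @param seed Master seed.
#' @return Nested list of parameters.
#' @export
default_config <- function(seed = 1L) {
  list(
    design = list(n_chroms = 2L, chrom_len = 1000000L, n_genes = 300L,
                  weeks = c(1L, 10L, 19L, 25L), replicates_per_week = 4L,
                  atac_replicates = 2L, rrbs_replicates = 4L, seed = seed),
    truth = list(frac_archetype = 0.35, frac_contrast = 0.05,
                 contrast_fold = 8, archetype_fold = 8, frac_da = 0.2,
                 da_fold = 2, n_motifs = 12L, sites_per_motif = 30L,
                 n_coupled_motifs = 3L, dip_frac = 0.3, n_cpgs = 1000L,
                 n_dmc = 100L, dmc_delta = 40),
    expression = list(alpha = 0.05, k = 7L, membership_threshold = 0.5,
                      dispersion = 0.1, base_mean = 200, pseudocount = 0.5,
                      exclude_samples = character()),
    chromatin = list(alpha = 0.05, promoter_window = c(1500L, 500L)),
    footprints = list(flank_bp = 20L, gap_bp = 5L, bound_threshold = 0.5,
                      change_cutoff = 0.1, n_perm = 1000L, min_sites = 10L),
    integration = list(top_quantile = 0.05, exclude_constant = TRUE),
    methylation = list(min_cov = 10L, max_percentile = 99.9,
                       min_present = 3L, alpha = 0.05, min_delta = 25,
                       n_random_pairs = 1000L))
}

.stage_hash <- function(files) {
  unname(tools::md5sum(files[file.exists(files)]))
}

#' Run the full pipeline
#'
#' Executes the six stages in dependency order under `outdir`, writing
#' per-stage TSV outputs and a JSON manifest recording the seed, per-stage
#' output files with md5 hashes and row counts. On rerun, a stage whose
#' recorded output hashes still match is skipped; a corrupted or missing
#' output triggers recomputation.
#'
#' @param config List from [default_config()].
#' @param outdir Run directory (created if needed).
#' @param force Recompute every stage regardless of the manifest.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config = default_config(), outdir, force = FALSE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(outdir, "manifest.json")
  manifest <- if (file.exists(manifest_path) && !force) {
    jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  } else list(seed = config$design$seed, stages = list())
  manifest$seed <- config$design$seed

  design <- do.call(sim_design, config$design)
  state <- new.env(parent = emptyenv())

  stage_done <- function(name, files) {
    st <- manifest$stages[[name]]
    !is.null(st) && length(st$files) == length(files) &&
      all(file.exists(files)) &&
      identical(unname(as.character(st$md5)), as.character(.stage_hash(files)))
  }
  record <- function(name, files, n_rows) {
    manifest$stages[[name]] <<- list(files = basename(files),
                                     md5 = .stage_hash(files), rows = n_rows)
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  }

  # stage 1: simulate (always recomputed in memory; files are the record)
  ann <- simulate_annotation(design)
  truth <- do.call(plant_truth, c(list(design = design, annotation = ann),
                                  config$truth))
  f_sim <- file.path(outdir, c("annotation.gtf", "tss.tsv", "ground_truth.json"))
  if (!stage_done("simulate", f_sim) || force) {
    write_gtf_lite(ann, f_sim[1L]); write_tss_tsv(ann, f_sim[2L])
    write_ground_truth(truth, f_sim[3L])
    record("simulate", f_sim, nrow(ann$genes))
  }

  # stage 2: expression
  expr <- simulate_expression(design, truth,
                              dispersion = config$expression$dispersion,
                              base_mean = config$expression$base_mean)
  de <- run_anova_de(expr, alpha = config$expression$alpha,
                     exclude_samples = config$expression$exclude_samples,
                     pseudocount = config$expression$pseudocount)
  cl <- cluster_degs(expr, de$degs, k = config$expression$k,
                     membership_threshold = config$expression$membership_threshold)
  f_expr <- file.path(outdir, c("counts.tsv", "de_anova.tsv", "clusters.tsv"))
  if (!stage_done("expression", f_expr) || force) {
    write_counts_tsv(expr$counts, f_expr[1L])
    utils::write.table(de$results, f_expr[2L], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(cl$assignments, f_expr[3L], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    record("expression", f_expr, nrow(de$results))
  }
  state$expr <- expr; state$de <- de; state$cl <- cl

  # stage 3: chromatin
  atac <- simulate_atac(design, truth)
  unified <- merge_peak_sets(atac$peaks_by_week)
  counts <- count_reads_in_peaks(unified, atac$coverage_by_sample)
  contrasts <- paste0("w", design$weeks[-4L], "_w", design$weeks[-1L])
  da <- lapply(contrasts, function(ct) {
    test_da(counts, atac$samples, ct, alpha = config$chromatin$alpha)
  })
  names(da) <- contrasts
  links <- link_peaks_to_genes(unified, ann)
  assoc <- do.call(rbind, lapply(da, function(d) {
    da_deg_association(d, links, cl$assignments)
  }))
  f_chr <- file.path(outdir, c("unified_peaks.tsv", "da_results.tsv",
                               "peak_gene_links.tsv", "da_cluster_assoc.tsv"))
  if (!stage_done("chromatin", f_chr) || force) {
    utils::write.table(unified, f_chr[1L], sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(do.call(rbind, da), f_chr[2L], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(links, f_chr[3L], sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(assoc, f_chr[4L], sep = "\t", quote = FALSE, row.names = FALSE)
    record("chromatin", f_chr, nrow(unified))
  }

  # stage 4: footprints
  fp <- score_sites(atac$coverage_by_week, atac$motif_sites, unified,
                    design$chrom_len, flank_bp = config$footprints$flank_bp,
                    gap_bp = config$footprints$gap_bp,
                    bound_threshold = config$footprints$bound_threshold)
  wk <- design$weeks
  pairs <- list(c(wk[1L], wk[2L]), c(wk[2L], wk[3L]), c(wk[1L], wk[4L]),
                c(wk[3L], wk[4L]))
  gbc <- do.call(rbind, lapply(pairs, function(pp) {
    global_binding_change(fp, pp[1L], pp[2L], n_perm = config$footprints$n_perm,
                          seed = design$seed, min_sites = config$footprints$min_sites)
  }))
  cls <- classify_environment(gbc, change_cutoff = config$footprints$change_cutoff,
                              weeks = wk)
  f_fp <- file.path(outdir, c("site_scores.tsv", "global_binding.tsv",
                              "tf_classification.tsv"))
  if (!stage_done("footprints", f_fp) || force) {
    utils::write.table(fp, f_fp[1L], sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(gbc, f_fp[2L], sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(cls, f_fp[3L], sep = "\t", quote = FALSE, row.names = FALSE)
    record("footprints", f_fp, nrow(gbc))
  }

  # stage 5: integration
  pat <- encode_patterns(fp, weeks = wk)
  site_host <- sites_to_host_peaks(atac$motif_sites, unified)
  enr <- enrich_patterns(pat, site_host, links, cl$assignments,
                         exclude_constant = config$integration$exclude_constant)
  enr <- flag_assumed_and_label(enr, top_quantile = config$integration$top_quantile)
  f_int <- file.path(outdir, "pattern_enrichment.tsv")
  if (!stage_done("integration", f_int) || force) {
    utils::write.table(enr, f_int, sep = "\t", quote = FALSE, row.names = FALSE)
    record("integration", f_int, nrow(enr))
  }

  # stage 6: methylation
  meth <- simulate_methylation(design, truth)
  filt <- filter_cpgs(meth$records, min_cov = config$methylation$min_cov,
                      max_percentile = config$methylation$max_percentile,
                      chrom_whitelist = paste0("chr", seq_len(design$n_chroms)))
  cons <- merge_replicates(filt$records, meth$samples,
                           min_present = config$methylation$min_present)
  dmcs <- call_dmcs(cons, alpha = config$methylation$alpha,
                    min_delta = config$methylation$min_delta)
  dmcs <- annotate_dmcs(dmcs, ann, config$chromatin$promoter_window)
  wm <- week_mean_expression(expr)
  corr <- correlate_dmc_expression(dmcs, wm,
                                   n_random_pairs = config$methylation$n_random_pairs,
                                   seed = design$seed)
  f_me <- file.path(outdir, c("dmcs.tsv", "dmc_gene_correlation.tsv"))
  if (!stage_done("methylation", f_me) || force) {
    utils::write.table(dmcs, f_me[1L], sep = "\t", quote = FALSE, row.names = FALSE)
    cres <- corr$results
    if (is.null(cres)) cres <- data.frame(cpg_id = character(), gene_id = character(),
                                          r = numeric(), p = numeric(),
                                          significant = logical())
    utils::write.table(cres, f_me[2L], sep = "\t", quote = FALSE, row.names = FALSE)
    record("methylation", f_me, nrow(dmcs))
  }
  invisible(manifest)
}
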