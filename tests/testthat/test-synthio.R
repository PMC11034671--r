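test_that("an empty design yields a valid empty annotation", {
  d <- sim_design(n_genes = 0L, seed = 1L)
  ann <- simulate_annotation(d)
  expect_equal(nrow(ann$genes), 0L)
  p <- withr::local_tempfile()
  write_gtf_lite(ann, p)
  expect_equal(nrow(read_gtf_lite(p)$genes), 0L)
})

test_that("simulation is deterministic under a fixed seed", {
  d <- sim_design(n_genes = 40L, chrom_len = 500000L, seed = 7L)
  a1 <- simulate_annotation(d); a2 <- simulate_annotation(d)
  expect_identical(a1, a2)
  t1 <- plant_truth(d, a1, n_cpgs = 100L, n_dmc = 10L)
  t2 <- plant_truth(d, a2, n_cpgs = 100L, n_dmc = 10L)
  expect_identical(t1$motif_sites, t2$motif_sites)
  e1 <- simulate_expression(d, t1); e2 <- simulate_expression(d, t2)
  expect_identical(e1$counts, e2$counts)
  m1 <- simulate_methylation(d, t1); m2 <- simulate_methylation(d, t2)
  expect_identical(m1$records, m2$records)
  at1 <- simulate_atac(d, t1); at2 <- simulate_atac(d, t2)
  expect_identical(at1$coverage_by_week, at2$coverage_by_week)
})

test_that("gene bodies never overlap (interval sweep check)", {
  d <- sim_design(n_genes = 200L, n_chroms = 2L, chrom_len = 1500000L, seed = 5L)
  g <- simulate_annotation(d)$genes
  expect_equal(nrow(g), 200L)
  for (ch in unique(g$chrom)) {
    gc <- g[g$chrom == ch, ]
    gc <- gc[order(gc$start), ]
    expect_true(all(gc$start[-1] >= gc$end[-nrow(gc)]))
  }
})

test_that("infeasible packing errors with the required length", {
  d <- sim_design(n_genes = 100L, n_chroms = 1L, chrom_len = 10000L, seed = 1L)
  expect_error(simulate_annotation(d), "need \\d+ bp")
})

test_that("archetype week multipliers show up in group means", {
  d <- sim_design(n_genes = 30L, chrom_len = 400000L,
                  replicates_per_week = 50L, seed = 9L)
  ann <- simulate_annotation(d)
  tr <- plant_truth(d, ann, frac_archetype = 0.7, frac_contrast = 0,
                    n_cpgs = 10L, n_dmc = 0L)
  expr <- simulate_expression(d, tr)
  cl1 <- tr$genes$gene_id[!is.na(tr$genes$cluster) & tr$genes$cluster == 1L]
  sam <- expr$samples[expr$samples$group == "short", ]
  m25 <- rowMeans(expr$counts[cl1, sam$sample_id[sam$week == 25], drop = FALSE])
  rest <- rowMeans(expr$counts[cl1, sam$sample_id[sam$week != 25], drop = FALSE])
  ratio <- m25 / rest
  expect_true(all(ratio > 5 & ratio < 12))
})

test_that("with nothing planted the week-course F test is uniform", {
  d <- sim_design(n_genes = 2000L, n_chroms = 4L, chrom_len = 6000000L, seed = 13L)
  ann <- simulate_annotation(d)
  tr <- plant_truth(d, ann, frac_archetype = 0, frac_contrast = 0,
                    n_cpgs = 10L, n_dmc = 0L)
  expr <- simulate_expression(d, tr)
  de <- run_anova_de(expr)
  ks <- stats::ks.test(de$results$p, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("dispersion must be positive", {
  s <- small_sim()
  expect_error(simulate_expression(s$design, s$truth, dispersion = 0), "dispersion")
})

test_that("planted footprint dips appear only in bound weeks", {
  s <- small_sim()
  atac <- small_atac()
  # take a site whose pattern differs between weeks
  sites <- s$truth$motif_sites
  pick <- sites[1, ]  # every planted pattern mixes bound and unbound weeks
  for (w in c(1, 10, 19, 25)) {
    cov <- atac$coverage_by_week[[paste0("week_", w)]]
    centre <- oracle_window_mean(cov, pick$chrom, pick$start, pick$end)
    flank <- oracle_window_mean(cov, pick$chrom, pick$start - 40L, pick$start - 10L)
    if (substr(pick$pattern, match(w, c(1, 10, 19, 25)), match(w, c(1, 10, 19, 25))) == "1") {
      expect_lt(centre, 0.6 * flank)
    } else {
      expect_gt(centre, 0.7 * flank)
    }
  }
})

test_that("planted accessibility folds are visible in raw counts", {
  s <- small_sim()
  atac <- small_atac()
  da <- s$truth$da_peaks
  up <- da[da$contrast == "w10_w19" & da$direction == "up", ]
  pk <- s$truth$peak_catalog
  ratios <- vapply(up$peak_id[1:5], function(pid) {
    row <- pk[pk$peak_id == pid, ]
    cnt <- function(w) {
      ids <- atac$samples$sample_id[atac$samples$week == w]
      mean(vapply(ids, function(sid) {
        oracle_window_mean(atac$coverage_by_sample[[sid]], row$chrom,
                           row$start, row$end)
      }, numeric(1)))
    }
    cnt(19) / cnt(10)
  }, numeric(1))
  expect_true(all(ratios > 1.6 & ratios < 2.5))
})

test_that("planted methylation deltas match the per-week scores", {
  d <- sim_design(n_genes = 20L, chrom_len = 300000L, rrbs_replicates = 4L, seed = 17L)
  ann <- simulate_annotation(d)
  tr <- plant_truth(d, ann, n_cpgs = 200L, n_dmc = 50L, dmc_delta = 40)
  meth <- simulate_methylation(d, tr, coverage_mean = 100)
  planted <- which(tr$cpgs$delta != 0)
  score <- function(w, i) {
    ids <- meth$samples$sample_id[meth$samples$week == w]
    mean(vapply(ids, function(sid) {
      r <- meth$records[[sid]][i, ]
      100 * r$count_M / (r$count_M + r$count_U)
    }, numeric(1)))
  }
  diffs <- vapply(planted[1:20], function(i) score(25, i) - score(1, i), numeric(1))
  expect_equal(unname(diffs), tr$cpgs$delta[planted[1:20]], tolerance = 0.25)
})

test_that("methylation tables survive the Bismark coverage round-trip", {
  s <- small_sim()
  meth <- simulate_methylation(s$design, s$truth)
  rec <- meth$records[[1]]
  p <- withr::local_tempfile()
  write_bismark_coverage(rec, p)
  back <- read_bismark_coverage(p)
  expect_equal(back[, c("chrom", "pos", "count_M", "count_U")],
               rec[, c("chrom", "pos", "count_M", "count_U")])
})

test_that("ground truth only references simulated entities and serialises", {
  s <- small_sim()
  tr <- s$truth
  expect_true(all(tr$genes$gene_id %in% s$ann$genes$gene_id))
  expect_true(all(tr$contrast_genes$gene_id %in% s$ann$genes$gene_id))
  expect_true(all(tr$da_peaks$peak_id %in% tr$peak_catalog$peak_id))
  expect_true(all(tr$motif_sites$peak_id %in% tr$peak_catalog$peak_id))
  expect_true(all(tr$motif_sites$motif_id %in% tr$motif_catalog$motif_id))
  p <- withr::local_tempfile()
  write_ground_truth(tr, p)
  back <- jsonlite::read_json(p, simplifyVector = TRUE)
  expect_equal(length(back$motif_sites$site_id), nrow(tr$motif_sites))
})

test_that("the synthetic TF reference is frozen and self-consistent", {
  ref1 <- synthetic_tf_reference()
  ref2 <- synthetic_tf_reference()
  expect_identical(ref1, ref2)
  expect_equal(nrow(ref1$global), 746L)
  # change columns are consistent with the planted per-week scores
  chg <- ref1$global$week_1_week_25_change
  back <- log2((ref1$global$week_25_mean_score + 1) /
                 (ref1$global$week_1_mean_score + 1))
  expect_equal(chg, back, tolerance = 1e-9)
})
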