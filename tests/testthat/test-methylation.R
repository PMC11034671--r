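meth_fixture <- function(seed = 71L) {
  key <- paste0("meth", seed)
  if (is.null(.fixture_cache[[key]])) {
    s <- small_sim(seed = 3L)
    .fixture_cache[[key]] <- simulate_methylation(s$design, s$truth)
  }
  .fixture_cache[[key]]
}

test_that("coverage filtering drops the documented loci with reasons", {
  rec <- list(s1 = data.frame(chrom = c("chr1", "chr1", "chr2", "chrM"),
                              pos = c(10L, 20L, 30L, 40L),
                              count_M = c(4L, 8L, 50L, 5L),
                              count_U = c(5L, 8L, 50L, 6L),
                              stringsAsFactors = FALSE))
  out <- filter_cpgs(rec, min_cov = 10L, chrom_whitelist = c("chr1", "chr2"))
  expect_equal(out$records$s1$pos, 20L)
  expect_setequal(out$drops$reason,
                  c("low_coverage", "high_coverage", "off_chromosome"))
  expect_error(filter_cpgs(rec, chrom_whitelist = character()), "whitelist")
})

test_that("a constant coverage distribution loses nothing to the percentile", {
  rec <- list(s1 = data.frame(chrom = "chr1", pos = 1:50 * 10L,
                              count_M = 10L, count_U = 10L,
                              stringsAsFactors = FALSE))
  out <- filter_cpgs(rec, min_cov = 10L, chrom_whitelist = "chr1")
  expect_equal(nrow(out$records$s1), 50L)
})

test_that("filtering matches a brute-force per-sample recount", {
  meth <- meth_fixture()
  out <- filter_cpgs(meth$records, chrom_whitelist = c("chr1", "chr2"))
  for (sid in names(meth$records)[1:3]) {
    d <- meth$records[[sid]]
    cov <- d$count_M + d$count_U
    keep <- cov >= 10 & cov <= quantile(cov, 0.999) &
      d$chrom %in% c("chr1", "chr2")
    expect_equal(out$records[[sid]], d[keep, ], ignore_attr = TRUE)
  }
  expect_equal(sum(vapply(out$records, nrow, integer(1))) + nrow(out$drops),
               sum(vapply(meth$records, nrow, integer(1))))
})

test_that("replicate-presence consensus follows the 3-of-4 rule", {
  samples <- data.frame(sample_id = paste0("s", 1:8),
                        week = rep(c(1L, 10L), each = 4),
                        replicate = rep(1:4, 2), stringsAsFactors = FALSE)
  base <- data.frame(chrom = "chr1", pos = c(100L, 200L, 300L),
                     count_M = 5L, count_U = 5L, stringsAsFactors = FALSE)
  rec <- lapply(1:8, function(i) base)
  names(rec) <- samples$sample_id
  rec$s1 <- base[-2, ]           # pos 200 in 3/4 reps of week 1 -> kept
  rec$s5 <- base[-3, ]; rec$s6 <- base[-3, ]  # pos 300 in 2/4 of week 10 -> out
  cons <- merge_replicates(rec, samples, min_present = 3L)
  expect_equal(cons$loci$pos, c(100L, 200L))
  expect_true(is.na(cons$M["chr1 200", "s1"]))
  expect_error(merge_replicates(rec, samples, min_present = 5L), "exceeds")
})

test_that("consensus size equals a brute-force presence recount", {
  meth <- meth_fixture()
  filt <- filter_cpgs(meth$records, chrom_whitelist = c("chr1", "chr2"))
  cons <- merge_replicates(filt$records, meth$samples)
  keys <- lapply(filt$records, function(d) paste(d$chrom, d$pos))
  weeks <- unique(meth$samples$week)
  per_week <- lapply(weeks, function(w) {
    ids <- meth$samples$sample_id[meth$samples$week == w]
    tab <- table(unlist(keys[ids]))
    names(tab)[tab >= 3]
  })
  expect_equal(nrow(cons$loci), length(Reduce(intersect, per_week)))
})

test_that("constant methylation never yields a DMC and the delta gate holds", {
  samples <- data.frame(sample_id = paste0("s", 1:16),
                        week = rep(c(1L, 10L, 19L, 25L), each = 4),
                        replicate = rep(1:4, 4), stringsAsFactors = FALSE)
  flat <- data.frame(chrom = "chr1", pos = c(10L, 20L), count_M = c(15L, 15L),
                     count_U = c(15L, 15L), stringsAsFactors = FALSE)
  rec <- lapply(1:16, function(i) flat)
  names(rec) <- samples$sample_id
  # pos 20: strong but small shift (about 17 points) in weeks 19/25
  for (i in 9:16) rec[[i]]$count_M[2] <- 20L; for (i in 9:16) rec[[i]]$count_U[2] <- 10L
  cons <- merge_replicates(rec, samples)
  dm <- call_dmcs(cons)
  expect_false(any(dm$is_dmc))
  expect_true(dm$FDR[dm$locus == 20] < 0.05)  # significant but gated out
  expect_lt(dm$max_abs_delta[dm$locus == 20], 25)
})

test_that("planted 40-point shifts are called with high sensitivity", {
  s <- small_sim()
  meth <- meth_fixture()
  filt <- filter_cpgs(meth$records, chrom_whitelist = c("chr1", "chr2"))
  cons <- merge_replicates(filt$records, meth$samples)
  dm <- call_dmcs(cons)
  planted <- paste0(s$truth$cpgs$chrom, "_", s$truth$cpgs$pos)[s$truth$cpgs$delta != 0]
  # coverage filtering legitimately loses a few planted loci before testing;
  # the caller is judged on the loci it can see
  in_cons <- planted[planted %in% dm$uniq_pos]
  expect_gt(length(in_cons) / length(planted), 0.7)
  expect_gt(mean(in_cons %in% dm$uniq_pos[dm$is_dmc]), 0.9)
  # null loci stay below the FDR level
  nulls <- dm[!dm$uniq_pos %in% planted, ]
  expect_lt(mean(nulls$is_dmc), 0.05)
})

test_that("DMC context counts match the sweep oracle", {
  s <- small_sim()
  meth <- meth_fixture()
  filt <- filter_cpgs(meth$records, chrom_whitelist = c("chr1", "chr2"))
  cons <- merge_replicates(filt$records, meth$samples)
  dm <- annotate_dmcs(call_dmcs(cons), s$ann)
  g <- s$ann$genes; e <- s$ann$exons
  oracle <- vapply(seq_len(nrow(dm)), function(i) {
    p <- dm$locus[i] - 1L; ch <- dm$chr[i]
    gc <- g[g$chrom == ch, ]
    d <- ifelse(gc$strand == "+", p - gc$tss, gc$tss - p)
    if (any(d >= -1500 & d < 500)) return("promoter")
    ec <- e[e$chrom == ch, ]
    if (any(ec$start <= p & p < ec$end)) return("exon")
    if (any(gc$start <= p & p < gc$end)) return("intron")
    "intergenic"
  }, character(1))
  expect_equal(dm$genomic_feature, oracle)
  expect_true(all(!is.na(dm$gene_id)))
})

test_that("DMC-gene correlation flags exact coupling and is reproducible", {
  dmcs <- data.frame(uniq_pos = c("chr1_10", "chr1_20"), chr = "chr1",
                     locus = c(10L, 20L),
                     week_1_score = c(10, 50), week_10_score = c(20, 50),
                     week_19_score = c(30, 50.2), week_25_score = c(40, 49.8),
                     is_dmc = TRUE, gene_id = c("gA", "gB"),
                     stringsAsFactors = FALSE)
  wm <- rbind(gA = c(5, 10, 15, 20), gB = c(3, 1, 2, 1.5))
  colnames(wm) <- paste0("week_", c(1, 10, 19, 25))
  r1 <- correlate_dmc_expression(dmcs, wm, n_random_pairs = 200, seed = 4)
  expect_true(r1$results$significant[r1$results$cpg_id == "chr1_10"])
  expect_equal(r1$results$r[1], 1)
  r2 <- correlate_dmc_expression(dmcs, wm, n_random_pairs = 200, seed = 4)
  expect_identical(r1$null_r, r2$null_r)
  # zero-variance methylation profile is excluded and counted
  dmcs$week_1_score[2] <- 50; dmcs$week_19_score[2] <- 50
  dmcs$week_25_score[2] <- 50
  r3 <- correlate_dmc_expression(dmcs, wm, n_random_pairs = 50, seed = 4)
  expect_equal(r3$n_excluded, 1L)
})
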