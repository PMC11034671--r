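test_that("there are exactly 14 informative binding patterns", {
  pats <- all_binding_patterns()
  expect_length(pats, 14L)
  expect_true(all(nchar(pats) == 4L))
  expect_false(any(c("0000", "1111") %in% pats))
})

test_that("patterns encode bound flags in chronological order", {
  sc <- data.frame(site_id = "s1", motif_id = "M1",
                   week = c(1, 10, 19, 25),
                   bound = c(TRUE, FALSE, FALSE, TRUE), stringsAsFactors = FALSE)
  p <- encode_patterns(sc)
  expect_equal(p$pattern, "1001")
  expect_false(p$constant)
  allb <- sc; allb$bound <- TRUE
  expect_true(encode_patterns(allb)$constant)
  expect_equal(encode_patterns(allb)$pattern, "1111")
  expect_error(encode_patterns(sc[-2, ]), "s1")
})

make_pattern_fixture <- function(n_motifs = 4L, sites_per = 60L, seed = 61L,
                                 coupled = NULL) {
  set.seed(seed)
  pats <- all_binding_patterns()
  sites <- do.call(rbind, lapply(seq_len(n_motifs), function(mi) {
    data.frame(site_id = sprintf("m%ds%03d", mi, seq_len(sites_per)),
               motif_id = sprintf("M%d", mi),
               pattern = sample(pats, sites_per, replace = TRUE),
               constant = FALSE,
               gene = sprintf("g%03d", sample.int(70, sites_per, TRUE)),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(coupled)) {
    i <- sites$motif_id == coupled$motif
    take <- which(i)[seq_len(coupled$n)]
    sites$pattern[take] <- coupled$pattern
    sites$gene[take] <- sprintf("g%03d", sample(coupled$genes, coupled$n, TRUE))
  }
  site_peaks <- data.frame(site_id = sites$site_id, peak_id = sites$site_id,
                           stringsAsFactors = FALSE)
  links <- data.frame(peak_id = sites$site_id, gene_id = sites$gene,
                      stringsAsFactors = FALSE)
  assignments <- data.frame(gene_id = sprintf("g%03d", 1:70),
                            cluster = rep(1:7, each = 10), stringsAsFactors = FALSE)
  list(patterns = sites[, c("site_id", "motif_id", "pattern", "constant")],
       site_peaks = site_peaks, links = links, assignments = assignments)
}

test_that("the test count is motifs x 14 patterns x clusters", {
  fx <- make_pattern_fixture()
  enr <- enrich_patterns(fx$patterns, fx$site_peaks, fx$links, fx$assignments)
  expect_equal(nrow(enr), 4L * 14L * 7L)
})

test_that("each 2x2 margin equals the motif's cluster-linked site count", {
  fx <- make_pattern_fixture()
  enr <- enrich_patterns(fx$patterns, fx$site_peaks, fx$links, fx$assignments)
  tot <- enr$count + enr$b + enr$c + enr$d
  expect_true(all(tapply(tot, enr$motif_id, function(x) length(unique(x))) == 1))
  expect_equal(as.vector(tapply(tot, enr$motif_id, unique)[paste0("M", 1:4)]),
               rep(60, 4))
})

test_that("enrichment equals a brute-force recount on a small instance", {
  fx <- make_pattern_fixture(n_motifs = 2L, sites_per = 25L, seed = 62L)
  enr <- enrich_patterns(fx$patterns, fx$site_peaks, fx$links, fx$assignments)
  d <- merge(fx$patterns, fx$site_peaks, by = "site_id")
  d$gene <- fx$links$gene_id[match(d$peak_id, fx$links$peak_id)]
  d$cluster <- fx$assignments$cluster[match(d$gene, fx$assignments$gene_id)]
  for (i in sample.int(nrow(enr), 40L)) {
    row <- enr[i, ]
    dm <- d[d$motif_id == row$motif_id, ]
    a <- sum(dm$pattern == row$pattern & dm$cluster == row$cluster)
    b <- sum(dm$pattern == row$pattern & dm$cluster != row$cluster)
    cc <- sum(dm$pattern != row$pattern & dm$cluster == row$cluster)
    dd <- sum(dm$pattern != row$pattern & dm$cluster != row$cluster)
    expect_equal(c(row$count, row$b, row$c, row$d), c(a, b, cc, dd))
    expect_equal(row$p, oracle_fisher_p(a, b, cc, dd), tolerance = 1e-9)
  }
})

test_that("a planted motif-pattern-cluster coupling ranks first for its motif", {
  fx <- make_pattern_fixture(coupled = list(motif = "M2", pattern = "0010",
                                            n = 30L, genes = 21:30))
  enr <- enrich_patterns(fx$patterns, fx$site_peaks, fx$links, fx$assignments)
  m2 <- enr[enr$motif_id == "M2", ]
  best <- m2[which.min(m2$p), ]
  expect_equal(best$pattern, "0010")
  expect_equal(best$cluster, 3L)  # genes 21-30 sit in cluster 3
  expect_gt(best$odds_ratio, 1)
})

test_that("excluding constant patterns never changes retained p-values", {
  fx <- make_pattern_fixture(n_motifs = 2L, sites_per = 40L, seed = 63L)
  fx$patterns$pattern[1:5] <- "1111"
  fx$patterns$constant[1:5] <- TRUE
  with_const <- enrich_patterns(fx$patterns, fx$site_peaks, fx$links,
                                fx$assignments, exclude_constant = FALSE)
  without <- enrich_patterns(fx$patterns, fx$site_peaks, fx$links,
                             fx$assignments, exclude_constant = TRUE)
  expect_equal(nrow(with_const), nrow(without))  # 14 informative patterns tested either way
  # rows tested on the same sites keep identical p only when the motif has
  # no constant sites; motif M2 is untouched
  expect_equal(with_const[with_const$motif_id == "M2", ],
               without[without$motif_id == "M2", ], ignore_attr = TRUE)
})

test_that("assumed-pattern flags and top-quantile labels behave at limits", {
  fx <- make_pattern_fixture()
  enr <- enrich_patterns(fx$patterns, fx$site_peaks, fx$links, fx$assignments)
  lab <- flag_assumed_and_label(enr, top_quantile = 1)
  expect_true(all(lab$labelled))
  lab0 <- flag_assumed_and_label(enr, top_quantile = 0)
  expect_false(any(lab0$labelled))
  map <- default_assumed_patterns()
  lab2 <- flag_assumed_and_label(enr, map, top_quantile = 0.1)
  prim <- lab2[lab2$cluster == 1L & lab2$pattern == map[["1"]][["primary"]], ]
  expect_true(all(prim$assumed == "primary"))
  badmap <- map; badmap[["1"]] <- c(primary = "0000", secondary = "0011")
  expect_error(flag_assumed_and_label(enr, badmap), "informative")
  expect_error(flag_assumed_and_label(transform(enr, cluster = cluster + 10),
                                      map), "missing cluster")
})

test_that("planted motif couplings surface through the full footprint chain", {
  fs <- fp_sim()
  unified <- merge_peak_sets(fs$atac$peaks_by_week)
  fp <- score_sites(fs$atac$coverage_by_week, fs$atac$motif_sites, unified,
                    fs$design$chrom_len)
  pat <- encode_patterns(fp, weeks = fs$design$weeks)
  links <- link_peaks_to_genes(unified, fs$ann)
  site_host <- sites_to_host_peaks(fs$atac$motif_sites, unified)
  expr <- simulate_expression(fs$design, fs$truth)
  de <- run_anova_de(expr)
  cl <- cluster_degs(expr, de$degs)
  enr <- enrich_patterns(pat, site_host, links, cl$assignments)
  # recovered cluster labels permute the planted archetypes: map by majority
  tru_cl <- fs$truth$genes$cluster[match(cl$assignments$gene_id,
                                         fs$truth$genes$gene_id)]
  both <- !is.na(cl$assignments$cluster) & !is.na(tru_cl)
  map <- apply(table(cl$assignments$cluster[both], tru_cl[both]), 1,
               function(r) as.integer(names(which.max(r))))
  coup <- fs$truth$motif_catalog[!is.na(fs$truth$motif_catalog$coupled_cluster), ]
  for (i in seq_len(nrow(coup))) {
    em <- enr[enr$motif_id == coup$motif_id[i], ]
    best <- em[which.min(em$p), ]
    expect_equal(best$pattern, coup$pattern[i])
    expect_equal(map[[as.character(best$cluster)]], coup$coupled_cluster[i])
    expect_gt(best$odds_ratio, 1)
  }
})
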