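test_that("peak merging handles overlap, book-ends and is idempotent", {
  a <- data.frame(chrom = "chr1", start = 0L, end = 100L)
  b <- data.frame(chrom = "chr1", start = 50L, end = 150L)
  m <- merge_peak_sets(list(w1 = a, w2 = b))
  expect_equal(m[, c("start", "end")], data.frame(start = 0L, end = 150L))
  b2 <- data.frame(chrom = "chr1", start = 100L, end = 200L)
  m2 <- merge_peak_sets(list(w1 = a, w2 = b2))
  expect_equal(m2[, c("start", "end")], data.frame(start = 0L, end = 200L))
  expect_true(all(m2$in_w1) && all(m2$in_w2))
  again <- merge_peak_sets(list(u = m2[, c("chrom", "start", "end")]))
  expect_equal(again[, c("chrom", "start", "end")],
               m2[, c("chrom", "start", "end")])
})

test_that("merged peaks equal the boolean-mask union of random weekly sets", {
  set.seed(41)
  len <- 100000L
  sets <- lapply(1:4, function(i) {
    st <- sort(sample.int(len - 500L, 60L))
    data.frame(chrom = "chr1", start = st, end = st + sample(50:400, 60L, TRUE))
  })
  names(sets) <- paste0("w", c(1, 10, 19, 25))
  m <- merge_peak_sets(sets)
  all_st <- unlist(lapply(sets, `[[`, "start"))
  all_en <- unlist(lapply(sets, `[[`, "end"))
  oracle <- oracle_union(all_st, all_en, len)
  expect_equal(m$start, oracle$start)
  expect_equal(m$end, oracle$end)
})

test_that("read counting integrates coverage over peaks", {
  peaks <- data.frame(peak_id = "p1", chrom = "chr1", start = 100L, end = 200L)
  cov <- data.frame(chrom = "chr1", start = 0L, end = 500L, value = 2)
  cnt <- count_reads_in_peaks(peaks, list(s1 = cov))
  expect_equal(cnt["p1", "s1"], 200)
  zero <- data.frame(chrom = "chr1", start = 300L, end = 400L, value = 3)
  expect_equal(count_reads_in_peaks(peaks, list(s1 = zero))["p1", "s1"], 0)
  off <- data.frame(chrom = "chr9", start = 0L, end = 10L, value = 1)
  expect_warning(count_reads_in_peaks(peaks, list(s1 = off)), "chr9")
})

test_that("differential accessibility recovers planted peaks with direction", {
  s <- small_sim(); atac <- small_atac()
  unified <- merge_peak_sets(atac$peaks_by_week)
  counts <- count_reads_in_peaks(unified, atac$coverage_by_sample)
  da <- test_da(counts, atac$samples, "w10_w19")
  expect_error(test_da(counts, atac$samples, "bogus"), "contrast")
  # map planted peaks onto unified peaks by coordinate containment
  pk <- s$truth$peak_catalog
  planted <- s$truth$da_peaks[s$truth$da_peaks$contrast == "w10_w19", ]
  prow <- pk[match(planted$peak_id, pk$peak_id), ]
  mid <- (prow$start + prow$end) %/% 2
  uid <- vapply(seq_len(nrow(prow)), function(i) {
    hit <- unified$chrom == prow$chrom[i] & unified$start <= mid[i] &
      unified$end > mid[i]
    unified$peak_id[hit][1]
  }, character(1))
  res <- da[match(uid, da$peak_id), ]
  ok <- res$p < 0.01 & !is.na(res$direction) & res$direction == planted$direction
  expect_gt(mean(ok), 0.9)
  rev <- test_da(counts, atac$samples, "w19_w10")
  expect_equal(rev$logFC, -da$logFC)
})

test_that("nearest-TSS linking obeys the tie rule and matches brute force", {
  genes <- data.frame(gene_id = c("gB", "gA"), chrom = "chr1", strand = c("+", "-"),
                      start = c(1000L, 3000L), end = c(2000L, 4000L),
                      stringsAsFactors = FALSE)
  ann <- genome_annotation(genes, genes[0, c("gene_id", "chrom", "start", "end")])
  # TSSs at 1000 (gB, +) and 3999 (gA, -); peak on a TSS
  on_tss <- data.frame(peak_id = "p", chrom = "chr1", start = 990L, end = 1010L)
  ln <- link_peaks_to_genes(on_tss, ann)
  expect_equal(ln$gene_id, "gB")
  expect_equal(ln$distance, 0L)
  # equidistant between the two TSSs: midpoint 2499.5 -> use 2499/2500
  tie_genes <- data.frame(gene_id = c("gB", "gA"), chrom = "chr1",
                          strand = "+", start = c(1000L, 3000L),
                          end = c(2000L, 4000L), stringsAsFactors = FALSE)
  ann2 <- genome_annotation(tie_genes, tie_genes[0, c("gene_id", "chrom", "start", "end")])
  tie <- data.frame(peak_id = "t", chrom = "chr1", start = 1995L, end = 2005L)
  ln2 <- link_peaks_to_genes(tie, ann2)  # midpoint 2000, dists 1000/1000
  expect_equal(ln2$gene_id, "gA")  # lexicographically smallest
  # no genes on chromosome
  orphan <- data.frame(peak_id = "o", chrom = "chrX", start = 0L, end = 10L)
  expect_true(link_peaks_to_genes(orphan, ann)$unassigned)
})

test_that("nearest-TSS linking equals all-pairs search on random peaks", {
  s <- small_sim()
  set.seed(42)
  n <- 2000L
  peaks <- data.frame(peak_id = sprintf("r%05d", 1:n),
                      chrom = sample(c("chr1", "chr2"), n, TRUE),
                      start = sample.int(700000L, n))
  peaks$end <- peaks$start + 200L
  ln <- link_peaks_to_genes(peaks, s$ann)
  mid <- (peaks$start + peaks$end) %/% 2L
  expect_equal(ln$gene_id, oracle_nearest(mid, peaks$chrom, s$ann$genes))
})

test_that("signed distances follow gene strand orientation", {
  genes <- data.frame(gene_id = c("gp", "gm"), chrom = c("chr1", "chr2"),
                      strand = c("+", "-"), start = c(5000L, 5000L),
                      end = c(6000L, 6000L), stringsAsFactors = FALSE)
  ann <- genome_annotation(genes, genes[0, c("gene_id", "chrom", "start", "end")])
  up_plus <- data.frame(peak_id = "a", chrom = "chr1", start = 4400L, end = 4600L)
  expect_lt(link_peaks_to_genes(up_plus, ann)$distance, 0)
  # on the minus strand, upstream is to the right of the TSS (5999)
  up_minus <- data.frame(peak_id = "b", chrom = "chr2", start = 6400L, end = 6600L)
  expect_lt(link_peaks_to_genes(up_minus, ann)$distance, 0)
})

test_that("genomic context classification has promoter precedence", {
  genes <- data.frame(gene_id = "g", chrom = "chr1", strand = "+",
                      start = 10000L, end = 14000L, stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = "g", chrom = "chr1",
                      start = c(10000L, 12000L), end = c(10500L, 12500L))
  ann <- genome_annotation(genes, exons)
  pts <- data.frame(chrom = "chr1",
                    pos = c(9900L, 10250L, 11000L, 12250L, 50000L))
  out <- annotate_location(pts, ann, c(1500L, 500L))
  # 9900 is 100 bp upstream of the TSS; 10250 is in exon 1 but within the
  # 500 bp downstream promoter window
  expect_equal(out, c("promoter", "promoter", "intron", "exon", "intergenic"))
})

test_that("context classification matches a per-position sweep oracle", {
  s <- small_sim()
  set.seed(43)
  pts <- data.frame(chrom = sample(c("chr1", "chr2"), 400, TRUE),
                    pos = sample.int(700000L, 400))
  out <- annotate_location(pts, s$ann, c(1500L, 500L))
  g <- s$ann$genes; e <- s$ann$exons
  oracle <- vapply(seq_len(nrow(pts)), function(i) {
    p <- pts$pos[i]; ch <- pts$chrom[i]
    gc <- g[g$chrom == ch, ]
    d <- ifelse(gc$strand == "+", p - gc$tss, gc$tss - p)
    if (any(d >= -1500 & d < 500)) return("promoter")
    ec <- e[e$chrom == ch, ]
    if (any(ec$start <= p & p < ec$end)) return("exon")
    if (any(gc$start <= p & p < gc$end)) return("intron")
    "intergenic"
  }, character(1))
  expect_equal(out, oracle)
})

test_that("DA-cluster association preserves margins and nulls", {
  da <- data.frame(peak_id = sprintf("p%02d", 1:40), contrast = "w10_w19",
                   logFC = rep(c(1, -1), 20), p = 0.001, FDR = 0.001,
                   significant = TRUE,
                   direction = rep(c("up", "down"), 20),
                   stringsAsFactors = FALSE)
  links <- data.frame(peak_id = da$peak_id,
                      gene_id = sprintf("g%02d", rep(1:20, each = 2)),
                      distance = 0L, unassigned = FALSE, stringsAsFactors = FALSE)
  # identical cluster composition between up and down -> all p = 1
  assignments <- data.frame(gene_id = sprintf("g%02d", 1:20),
                            cluster = rep(1:2, 10), stringsAsFactors = FALSE)
  res <- da_deg_association(da, links, assignments)
  expect_equal(res$p, rep(1, 2))
  expect_true(all(res$a + res$b + res$c + res$d ==
                    sum(!is.na(links$gene_id))))
})

test_that("a planted direction-cluster coupling is detected", {
  set.seed(44)
  n <- 120L
  dirn <- rep(c("up", "down"), each = n / 2)
  cl <- ifelse(dirn == "up",
               sample(c(3L, sample(c(1:2, 4:7), n / 2, TRUE)), n / 2, TRUE),
               sample(1:7, n / 2, TRUE))
  cl[dirn == "up"][1:40] <- 3L  # strong coupling of up-peaks to cluster 3
  da <- data.frame(peak_id = sprintf("p%03d", 1:n), contrast = "w19_w25",
                   logFC = ifelse(dirn == "up", 1, -1), p = 0.001, FDR = 0.001,
                   significant = TRUE, direction = dirn, stringsAsFactors = FALSE)
  links <- data.frame(peak_id = da$peak_id, gene_id = sprintf("g%03d", 1:n),
                      distance = 0L, unassigned = FALSE, stringsAsFactors = FALSE)
  assignments <- data.frame(gene_id = links$gene_id, cluster = cl,
                            stringsAsFactors = FALSE)
  res <- da_deg_association(da, links, assignments)
  r3 <- res[res$cluster == 3L, ]
  expect_lt(r3$p, 0.01)
  expect_gt(r3$odds_ratio, 1)
})
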