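# shared fixtures (built once per run) and independent brute-force oracles

.fixture_cache <- new.env(parent = emptyenv())

small_sim <- function(seed = 3L) {
  key <- paste0("sim", seed)
  if (is.null(.fixture_cache[[key]])) {
    d <- sim_design(n_genes = 120L, chrom_len = 800000L, seed = seed)
    ann <- simulate_annotation(d)
    tr <- plant_truth(d, ann, n_cpgs = 300L, n_dmc = 40L)
    .fixture_cache[[key]] <- list(design = d, ann = ann, truth = tr)
  }
  .fixture_cache[[key]]
}

small_atac <- function(seed = 3L) {
  key <- paste0("atac", seed)
  if (is.null(.fixture_cache[[key]])) {
    s <- small_sim(seed)
    .fixture_cache[[key]] <- simulate_atac(s$design, s$truth)
  }
  .fixture_cache[[key]]
}

# richer archetype planting so cluster-coupled motifs carry enough sites
# for the permutation test's resolution
fp_sim <- function() {
  if (is.null(.fixture_cache[["fp"]])) {
    d <- sim_design(n_genes = 210L, chrom_len = 1200000L, seed = 23L)
    ann <- simulate_annotation(d)
    tr <- plant_truth(d, ann, frac_archetype = 0.7, n_motifs = 8L,
                      sites_per_motif = 30L, n_coupled_motifs = 4L,
                      n_cpgs = 50L, n_dmc = 5L)
    .fixture_cache[["fp"]] <- list(design = d, ann = ann, truth = tr,
                                   atac = simulate_atac(d, tr))
  }
  .fixture_cache[["fp"]]
}

small_expr <- function(seed = 3L) {
  key <- paste0("expr", seed)
  if (is.null(.fixture_cache[[key]])) {
    s <- small_sim(seed)
    .fixture_cache[[key]] <- simulate_expression(s$design, s$truth)
  }
  .fixture_cache[[key]]
}

# --- enumeration oracles (kept independent of the implementations) ---

# two-sided Fisher p by explicit enumeration over all tables with the
# observed margins, using factorial arithmetic directly
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- a + b + c + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || (b + d) == 0) return(1)
  lo <- max(0L, c1 - r2); hi <- min(r1, c1)
  logp <- function(x) {
    lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(n, c1)
  }
  probs <- exp(vapply(lo:hi, logp, numeric(1)))
  obs <- exp(logp(a))
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# upper-tail hypergeometric by explicit enumeration
oracle_hyper_p <- function(k, n, K, N) {
  xs <- k:min(n, K)
  sum(exp(lchoose(K, xs) + lchoose(N - K, n - xs) - lchoose(N, n)))
}

# all-pairs nearest-TSS search with lexicographic tie rule
oracle_nearest <- function(mid, chrom, genes) {
  vapply(seq_along(mid), function(i) {
    gc <- genes[genes$chrom == chrom[i], , drop = FALSE]
    if (nrow(gc) == 0L) return(NA_character_)
    dd <- abs(mid[i] - gc$tss)
    cand <- gc$gene_id[dd == min(dd)]
    sort(cand)[1L]
  }, character(1))
}

# per-base boolean mask union of interval sets on one chromosome
oracle_union <- function(starts, ends, len) {
  mask <- logical(len)
  for (i in seq_along(starts)) mask[(starts[i] + 1L):ends[i]] <- TRUE
  r <- rle(mask)
  e <- cumsum(r$lengths); s <- e - r$lengths
  data.frame(start = s[r$values], end = e[r$values])
}

# mean coverage of a bedGraph over a window, computed the slow way
oracle_window_mean <- function(cov, chrom, start, end) {
  v <- numeric(end - start)
  d <- cov[cov$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(d))) {
    lo <- max(d$start[i], start); hi <- min(d$end[i], end)
    if (hi > lo) v[(lo - start + 1L):(hi - start)] <- d$value[i]
  }
  mean(v)
}
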