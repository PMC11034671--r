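#' @title RRBS differential methylation
#' @description Coverage and percentile filtering of CpG calls,
#'   replicate-presence consensus building, differentially methylated
#'   cytosine (DMC) calling with an effect-size gate, genomic-context
#'   annotation, and the DMC-gene expression correlation test against a
#'   simulated random-pair null.
#' @name methylation
NULL

#' Filter CpG records per sample
#'
#' Per sample, drops loci with coverage below `min_cov` or strictly above
#' that sample's `max_percentile` coverage percentile, and loci on
#' chromosomes outside the whitelist. Every dropped locus carries a
#' machine-readable reason.
#'
#' @param records Named list (per sample) of data.frames with chrom, pos,
#'   count_M, count_U.
#' @param min_cov Minimum reads per locus (default 10).
#' @param max_percentile Upper coverage percentile (default 99.9).
#' @param chrom_whitelist Chromosomes to keep.
#' @return List: `records` (filtered, same structure), `drops`
#'   (data.frame sample_id, chrom, pos, reason).
#' @export
filter_cpgs <- function(records, min_cov = 10L, max_percentile = 99.9,
                        chrom_whitelist) {
  if (missing(chrom_whitelist) || length(chrom_whitelist) == 0L) {
    stop("chrom_whitelist must be non-empty")
  }
  drops <- list()
  out <- lapply(names(records), function(sid) {
    d <- records[[sid]]
    cov <- d$count_M + d$count_U
    cutoff <- stats::quantile(cov, max_percentile / 100, names = FALSE)
    reason <- rep(NA_character_, nrow(d))
    reason[cov > cutoff] <- "high_coverage"
    reason[cov < min_cov] <- "low_coverage"
    reason[!d$chrom %in% chrom_whitelist] <- "off_chromosome"
    dropped <- !is.na(reason)
    drops[[sid]] <<- data.frame(sample_id = rep(sid, sum(dropped)),
                                chrom = d$chrom[dropped],
                                pos = d$pos[dropped], reason = reason[dropped],
                                stringsAsFactors = FALSE)
    d[!dropped, , drop = FALSE]
  })
  names(out) <- names(records)
  list(records = out, drops = do.call(rbind, drops))
}

#' Build the replicate-presence consensus CpG set
#'
#' Per week, keeps loci present (post-filter) in at least `min_present`
#' replicates; the per-week consensus sets are then intersected across
#' weeks so every retained locus is testable at all time points.
#'
#' @param records Filtered per-sample records (as from [filter_cpgs()]).
#' @param samples Sample sheet with `sample_id`, `week`, `replicate`.
#' @param min_present Minimum replicates a locus must appear in
#'   (default 3).
#' @return A `meth_consensus`: `loci` (chrom, pos), matrices `M` and `U`
#'   (loci x samples, NA where the sample lacked the locus), `samples`.
#' @export
merge_replicates <- function(records, samples, min_present = 3L) {
  weeks <- sort(unique(samples$week))
  for (w in weeks) {
    if (min_present > sum(samples$week == w)) {
      stop("min_present (", min_present, ") exceeds replicate count at week ", w)
    }
  }
  key <- function(d) paste(d$chrom, d$pos)
  consensus <- NULL
  for (w in weeks) {
    ids <- samples$sample_id[samples$week == w]
    tab <- table(unlist(lapply(records[ids], key)))
    ok <- names(tab)[tab >= min_present]
    consensus <- if (is.null(consensus)) ok else intersect(consensus, ok)
  }
  all_keys <- unique(do.call(rbind, lapply(records, function(d) {
    data.frame(chrom = d$chrom, pos = d$pos, stringsAsFactors = FALSE)
  })))
  all_keys <- all_keys[paste(all_keys$chrom, all_keys$pos) %in% consensus, ]
  all_keys <- all_keys[order(all_keys$chrom, all_keys$pos), , drop = FALSE]
  rownames(all_keys) <- NULL
  ck <- paste(all_keys$chrom, all_keys$pos)
  M <- U <- matrix(NA_real_, nrow(all_keys), nrow(samples),
                   dimnames = list(ck, samples$sample_id))
  for (sid in samples$sample_id) {
    d <- records[[sid]]
    i <- match(key(d), ck)
    keep <- !is.na(i)
    M[i[keep], sid] <- d$count_M[keep]
    U[i[keep], sid] <- d$count_U[keep]
  }
  structure(list(loci = all_keys, M = M, U = U, samples = samples),
            class = "meth_consensus")
}

#' Call differentially methylated cytosines
#'
#' Per CpG, a one-way F test across weeks on logit-transformed
#' methylation proportions (0.5-read pseudocount on each of the
#' methylated and unmethylated counts), BH adjustment, and an effect-size
#' gate: a DMC needs FDR < `alpha` AND a maximum pairwise difference in
#' per-week mean methylation score above `min_delta` percentage points.
#' Loci with fewer than 2 present replicates in any week are excluded
#' (attribute `n_excluded`).
#'
#' @param consensus A `meth_consensus` from [merge_replicates()].
#' @param alpha FDR threshold (default 0.05).
#' @param min_delta Effect-size gate in percentage points (default 25).
#' @return Data.frame: uniq_pos, chrom, locus, per-week mean scores,
#'   per-week-pair logFC of mean methylated counts, F, p, FDR,
#'   max_abs_delta, is_dmc.
#' @export
call_dmcs <- function(consensus, alpha = 0.05, min_delta = 25) {
  M <- consensus$M; U <- consensus$U
  samples <- consensus$samples
  weeks <- sort(unique(samples$week))
  wk <- samples$week[match(colnames(M), samples$sample_id)]
  present <- !is.na(M)
  n_per_week <- sapply(weeks, function(w) {
    rowSums(present[, wk == w, drop = FALSE])
  })
  ok <- rowSums(n_per_week < 2L) == 0L
  n_excluded <- sum(!ok)
  M <- M[ok, , drop = FALSE]; U <- U[ok, , drop = FALSE]
  loci <- consensus$loci[ok, , drop = FALSE]
  y <- log((M + 0.5) / (U + 0.5))
  score <- 100 * M / (M + U)

  # NA-aware row-wise one-way F across weeks
  obs <- !is.na(y)
  k <- length(weeks)
  gmean <- sapply(weeks, function(w) {
    rowMeans(y[, wk == w, drop = FALSE], na.rm = TRUE)
  })
  ng <- sapply(weeks, function(w) rowSums(obs[, wk == w, drop = FALSE]))
  N <- rowSums(obs)
  overall <- rowSums(y * obs, na.rm = TRUE) / N
  ssb <- rowSums(ng * (gmean - overall)^2)
  fit <- gmean[, match(wk, weeks), drop = FALSE]
  ssw <- rowSums((y - fit)^2, na.rm = TRUE)
  df2 <- N - k
  Fstat <- (ssb / (k - 1)) / (ssw / df2)
  p <- stats::pf(Fstat, k - 1, df2, lower.tail = FALSE)
  sst <- ssb + ssw
  p[sst < 1e-12] <- 1; Fstat[sst < 1e-12] <- 0
  p[sst >= 1e-12 & ssw < 1e-12] <- 0

  wmean_score <- sapply(weeks, function(w) {
    rowMeans(score[, wk == w, drop = FALSE], na.rm = TRUE)
  })
  colnames(wmean_score) <- paste0("week_", weeks, "_score")
  pairs <- utils::combn(weeks, 2L)
  wmean_M <- sapply(weeks, function(w) rowMeans(M[, wk == w, drop = FALSE], na.rm = TRUE))
  lfc <- sapply(seq_len(ncol(pairs)), function(j) {
    a <- match(pairs[1L, j], weeks); b <- match(pairs[2L, j], weeks)
    log2((wmean_M[, b] + 0.5) / (wmean_M[, a] + 0.5))
  })
  colnames(lfc) <- apply(pairs, 2L, function(pp) {
    paste0("week_", pp[2L], "_week_", pp[1L], "_logFC")
  })
  max_delta <- apply(wmean_score, 1L, function(v) max(stats::dist(v)))
  fdr <- bh_adjust(p)
  out <- data.frame(uniq_pos = paste0(loci$chrom, "_", loci$pos),
                    chr = loci$chrom, locus = loci$pos,
                    stringsAsFactors = FALSE)
  out <- cbind(out, wmean_score, lfc)
  out$F <- Fstat; out$PValue <- p; out$FDR <- fdr
  out$max_abs_delta <- max_delta
  out$is_dmc <- out$FDR < alpha & out$max_abs_delta > min_delta
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Annotate DMCs with genomic context and nearest gene
#'
#' @param dmcs Data.frame from [call_dmcs()].
#' @param annotation A `genome_annotation`.
#' @param promoter_window c(upstream_bp, downstream_bp).
#' @return The input with `genomic_feature`, `gene_id`, `tss`, `strand`,
#'   `distance` columns.
#' @export
annotate_dmcs <- function(dmcs, annotation, promoter_window = c(1500L, 500L)) {
  pts <- data.frame(chrom = dmcs$chr, pos = dmcs$locus - 1L,
                    stringsAsFactors = FALSE)
  dmcs$genomic_feature <- annotate_location(pts, annotation, promoter_window)
  pseudo <- data.frame(peak_id = dmcs$uniq_pos, chrom = dmcs$chr,
                       start = dmcs$locus - 1L, end = dmcs$locus,
                       stringsAsFactors = FALSE)
  ln <- link_peaks_to_genes(pseudo, annotation)
  dmcs$gene_id <- ln$gene_id
  gi <- match(dmcs$gene_id, annotation$genes$gene_id)
  dmcs$tss <- annotation$genes$tss[gi]
  dmcs$strand <- annotation$genes$strand[gi]
  dmcs$distance <- ln$distance
  dmcs
}

#' Per-week mean expression profiles
#'
#' @param expr An `expr_set`.
#' @param group Fish group whose samples are averaged.
#' @param layer "tpm" or "cpm".
#' @return Matrix genes x 4 weeks of per-week means.
#' @export
week_mean_expression <- function(expr, group = "short", layer = c("tpm", "cpm")) {
  layer <- match.arg(layer)
  vals <- if (layer == "tpm") tpm(expr) else cpm_normalize(expr$counts)
  sam <- expr$samples[expr$samples$group == group, , drop = FALSE]
  weeks <- sort(unique(sam$week))
  out <- sapply(weeks, function(w) {
    rowMeans(vals[, sam$sample_id[sam$week == w], drop = FALSE])
  })
  colnames(out) <- paste0("week_", weeks)
  out
}

#' Correlate DMC methylation with nearest-gene expression, with a
#' simulated random-pair null
#'
#' For each DMC-nearest-gene pair, Pearson r and p over the four per-week
#' means; a pair is significant when p < 0.05 AND |r| > 0.95. The null
#' draws `n_random_pairs` uniformly random (DMC, gene) pairs with the
#' recorded seed, and the observed r distribution is compared to the null
#' r distribution with a two-sample Kolmogorov-Smirnov test.
#'
#' @param dmcs Annotated DMC table (needs is_dmc rows, per-week score
#'   columns and gene_id).
#' @param expr_week_means Matrix from [week_mean_expression()].
#' @param n_random_pairs Size of the simulated null (default 1000).
#' @param seed RNG seed recorded in the output.
#' @return List: `results` (cpg, gene, r, p, significant), `null_r`,
#'   `ks_p`, `n_excluded` (zero-variance pairs), `seed`.
#' @export
correlate_dmc_expression <- function(dmcs, expr_week_means,
                                     n_random_pairs = 1000L, seed = 1L) {
  d <- dmcs[dmcs$is_dmc & !is.na(dmcs$gene_id) &
              dmcs$gene_id %in% rownames(expr_week_means), , drop = FALSE]
  score_cols <- grep("^week_\\d+_score$", names(d), value = TRUE)
  n_excluded <- 0L
  rows <- lapply(seq_len(nrow(d)), function(i) {
    x <- as.numeric(d[i, score_cols])
    y <- expr_week_means[d$gene_id[i], ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      n_excluded <<- n_excluded + 1L
      return(NULL)
    }
    ct <- pearson_with_p(x, y)
    data.frame(cpg_id = d$uniq_pos[i], gene_id = d$gene_id[i], r = ct$r,
               p = ct$p, significant = ct$p < 0.05 & abs(ct$r) > 0.95,
               stringsAsFactors = FALSE)
  })
  results <- do.call(rbind, rows)
  set.seed(seed)
  null_r <- numeric(0)
  if (nrow(d) > 0L && nrow(expr_week_means) > 0L) {
    ci <- sample.int(nrow(d), n_random_pairs, replace = TRUE)
    gi <- sample.int(nrow(expr_week_means), n_random_pairs, replace = TRUE)
    null_r <- vapply(seq_len(n_random_pairs), function(j) {
      x <- as.numeric(d[ci[j], score_cols])
      y <- expr_week_means[gi[j], ]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
      stats::cor(x, y)
    }, numeric(1))
    null_r <- null_r[!is.na(null_r)]
  }
  ks_p <- if (!is.null(results) && nrow(results) >= 3L && length(null_r) >= 3L) {
    suppressWarnings(stats::ks.test(results$r, null_r)$p.value)
  } else NA_real_
  list(results = results, null_r = null_r, ks_p = ks_p,
       n_excluded = n_excluded, seed = seed)
}
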