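#' @title Differential expression and co-expression clustering
#' @description The transcriptome layer: an ANOVA-like test across the four
#'   sampling weeks within one fish group, pairwise photoperiod/salinity
#'   contrasts, hierarchical co-expression clustering of the differential
#'   genes with a correlation-gated membership rule, and generic pathway
#'   over-representation.
#' @name expression
NULL

#' Week-course differential expression within one fish group
#'
#' Runs the row-wise one-way F test on log2 CPM of the samples belonging
#' to `group`, testing for any difference between the four weeks.
#'
#' @param expr An `expr_set`.
#' @param group Fish group to test within (default "short").
#' @param alpha DEG threshold on BH FDR.
#' @param exclude_samples Sample ids dropped before testing (outlier
#'   handling; screening is reported, never automatic).
#' @param pseudocount Pseudocount for the log2 CPM transform.
#' @return List: `results` (per-gene table), `degs` (gene ids with
#'   FDR < alpha), `values` (the log2 CPM matrix used), `samples`.
#' @export
run_anova_de <- function(expr, group = "short", alpha = 0.05,
                         exclude_samples = character(), pseudocount = 0.5) {
  keep <- expr$samples$group == group &
    !(expr$samples$sample_id %in% exclude_samples)
  sam <- expr$samples[keep, , drop = FALSE]
  weeks_present <- sort(unique(sam$week))
  if (length(weeks_present) < 4L) {
    stop("missing week(s) for group '", group, "': have ",
         paste(weeks_present, collapse = ", "))
  }
  if (any(table(sam$week) < 2L)) stop("need >= 2 replicates per week")
  values <- cpm_normalize(expr$counts[, sam$sample_id, drop = FALSE],
                          log = TRUE, pseudocount = pseudocount)
  res <- anova_like_test(values, paste0("week_", sam$week))
  degs <- res$feature_id[res$FDR < alpha]
  list(results = res, degs = degs, values = values, samples = sam)
}

#' Cluster differential genes by scaled temporal profile
#'
#' Per-gene z-scored TPM profiles of the DEGs are clustered by
#' hierarchical clustering (Ward by default) on Euclidean distances and
#' cut at `k`. Genes whose Pearson correlation to their own cluster's mean
#' scaled profile is <= `membership_threshold` are excluded (cluster NA)
#' but keep their failing correlation. Input gene order never matters:
#' genes are processed sorted by gene_id.
#'
#' @param expr An `expr_set`.
#' @param degs Character vector of DEG ids (>= k).
#' @param k Number of clusters.
#' @param membership_threshold Correlation gate (default 0.5).
#' @param group Fish group whose samples define the profiles.
#' @param linkage hclust method (default "ward.D2").
#' @param exclude_samples Samples dropped before profiling.
#' @return List: `assignments` (gene_id, cluster, correlation_to_mean),
#'   `profiles` (scaled matrix), `cluster_means`, `ss` (within/between
#'   sum-of-squares across candidate k for model inspection).
#' @export
cluster_degs <- function(expr, degs, k = 7L, membership_threshold = 0.5,
                         group = "short", linkage = "ward.D2",
                         exclude_samples = character()) {
  if (k < 2L) stop("k must be >= 2")
  if (length(degs) < k) stop("need at least k DEGs")
  degs <- sort(unique(degs))
  keep <- expr$samples$group == group &
    !(expr$samples$sample_id %in% exclude_samples)
  sam <- expr$samples[keep, , drop = FALSE]
  tpm_mat <- tpm(expr)[degs, sam$sample_id, drop = FALSE]
  mu <- rowMeans(tpm_mat)
  sdv <- apply(tpm_mat, 1L, stats::sd)
  sdv[sdv == 0] <- 1
  z <- (tpm_mat - mu) / sdv
  hc <- stats::hclust(stats::dist(z), method = linkage)
  cl <- stats::cutree(hc, k = k)
  means <- t(sapply(seq_len(k), function(ci) colMeans(z[cl == ci, , drop = FALSE])))
  corr <- vapply(seq_along(degs), function(i) {
    m <- means[cl[i], ]
    if (stats::sd(m) == 0 || stats::sd(z[i, ]) == 0) return(0)
    stats::cor(z[i, ], m)
  }, numeric(1))
  assigned <- ifelse(corr > membership_threshold, cl, NA_integer_)
  ss <- t(sapply(2:min(10L, length(degs) - 1L), function(kk) {
    ck <- stats::cutree(hc, k = kk)
    tot <- sum(sweep(z, 2L, colMeans(z))^2)
    within <- sum(vapply(seq_len(kk), function(ci) {
      zz <- z[ck == ci, , drop = FALSE]
      sum(sweep(zz, 2L, colMeans(zz))^2)
    }, numeric(1)))
    c(k = kk, within_ss = within, between_ss = tot - within)
  }))
  list(assignments = data.frame(gene_id = degs, cluster = assigned,
                                correlation_to_mean = corr,
                                stringsAsFactors = FALSE),
       profiles = z, cluster_means = means, ss = as.data.frame(ss))
}

.contrast_table <- function(weeks) {
  list(photoperiod_w10 = list(week = weeks[2L], armA = "short", armB = "long"),
       photoperiod_w19 = list(week = weeks[3L], armA = "short", armB = "long"),
       salinity_w25 = list(week = weeks[4L], armA = "short", armB = "fresh_control"))
}

#' Pairwise contrast between fish arms at one week
#'
#' Welch t on log2 CPM. The logFC sign convention is first-named arm minus
#' second: short-vs-long positive logFC means higher in the short group,
#' and seawater (short arm at week 25) minus freshwater control.
#'
#' @param expr An `expr_set`.
#' @param contrast One of `photoperiod_w10`, `photoperiod_w19`,
#'   `salinity_w25`.
#' @param alpha DEG threshold on BH FDR.
#' @param pseudocount Pseudocount for the log2 CPM transform.
#' @return List: `results` table (with logFC, p, FDR), `degs`.
#' @export
run_pairwise_contrasts <- function(expr, contrast, alpha = 0.05,
                                   pseudocount = 0.5) {
  weeks <- sort(unique(expr$samples$week))
  tab <- .contrast_table(weeks)
  if (!contrast %in% names(tab)) {
    stop("unknown contrast '", contrast, "'; valid: ",
         paste(names(tab), collapse = ", "))
  }
  cc <- tab[[contrast]]
  idxA <- expr$samples$group == cc$armA & expr$samples$week == cc$week
  idxB <- expr$samples$group == cc$armB & expr$samples$week == cc$week
  if (!any(idxA) || !any(idxB)) {
    stop("contrast '", contrast, "': arm missing at week ", cc$week)
  }
  values <- cpm_normalize(expr$counts, log = TRUE, pseudocount = pseudocount)
  res <- pairwise_test(values, idxA, idxB)
  list(results = res, degs = res$feature_id[res$FDR < alpha], contrast = contrast)
}

#' Pathway over-representation of a gene set
#'
#' Upper-tail hypergeometric test per pathway with BH adjustment across
#' pathways.
#'
#' @param gene_set Character vector of hit genes.
#' @param universe Character vector of all testable genes.
#' @param pathway_db Named list mapping pathway -> gene ids.
#' @param alpha Significance threshold on the adjusted p.
#' @return Data.frame: pathway, hits, set_size, pathway_size, universe, p,
#'   FDR, significant.
#' @export
ora_pathways <- function(gene_set, universe, pathway_db, alpha = 0.05) {
  if (length(universe) == 0L) stop("empty universe")
  gene_set <- intersect(gene_set, universe)
  rows <- lapply(names(pathway_db), function(pw) {
    pg <- intersect(pathway_db[[pw]], universe)
    k <- length(intersect(gene_set, pg))
    p <- hypergeom_ora(k, length(gene_set), length(pg), length(universe))
    data.frame(pathway = pw, hits = k, set_size = length(gene_set),
               pathway_size = length(pg), universe = length(universe),
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$FDR <- bh_adjust(out$p)
  out$significant <- out$FDR < alpha
  out[order(out$p), ]
}
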