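#' @title Binding-pattern x expression-cluster integration
#' @description Encodes per-site bound/unbound calls across the four weeks
#'   as 4-digit binding patterns, tests every (motif, pattern, cluster)
#'   combination for enrichment of the pattern among the motif's sites
#'   near genes of the cluster with Fisher's exact test, and annotates the
#'   results against the assumed primary/secondary pattern expected from
#'   each cluster's expression trend.
#' @name integration
NULL

#' All informative 4-week binding patterns
#'
#' The 16 binary strings over four weeks minus the two constant ones
#' ("0000", "1111"), i.e. 14 patterns.
#'
#' @return Character vector of length 14.
#' @export
all_binding_patterns <- function() {
  pats <- vapply(0:15, function(i) {
    paste(rev(as.integer(intToBits(i)[1:4])), collapse = "")
  }, character(1))
  sort(setdiff(pats, c("0000", "1111")))
}

#' Encode per-site binding patterns
#'
#' Deterministic 4-character 0/1 encoding of the bound flags in
#' chronological week order; constant patterns are flagged
#' non-informative.
#'
#' @param site_scores Long data.frame from [score_sites()] (site_id,
#'   motif_id, week, bound).
#' @param weeks The four weeks in chronological order.
#' @return Data.frame: site_id, motif_id, pattern, constant.
#' @export
encode_patterns <- function(site_scores, weeks = c(1L, 10L, 19L, 25L)) {
  wide <- lapply(weeks, function(w) {
    d <- site_scores[site_scores$week == w, c("site_id", "motif_id", "bound")]
    names(d)[3L] <- paste0("b", w)
    d
  })
  m <- Reduce(function(x, y) merge(x, y, by = c("site_id", "motif_id"),
                                   all = TRUE), wide)
  flags <- as.matrix(m[, paste0("b", weeks), drop = FALSE])
  if (anyNA(flags)) {
    bad <- m$site_id[which(rowSums(is.na(flags)) > 0)[1L]]
    stop("missing week bound flag for site '", bad, "'")
  }
  pattern <- apply(flags, 1L, function(f) paste(as.integer(f), collapse = ""))
  data.frame(site_id = m$site_id, motif_id = m$motif_id, pattern = pattern,
             constant = pattern %in% c("0000", "1111"), stringsAsFactors = FALSE)
}

#' Fisher enrichment of binding patterns per motif and expression cluster
#'
#' Sites are linked to genes via their host peak's nearest-TSS link and
#' restricted to genes with a cluster assignment. For each motif M,
#' pattern P and cluster C, the 2x2 over M's cluster-linked sites is
#' (pattern == P vs != P) x (gene in C vs in another cluster). Constant
#' patterns are excluded by default. Output is sorted by cluster then p.
#'
#' @param patterns Data.frame from [encode_patterns()].
#' @param site_peaks Data.frame site_id -> peak_id.
#' @param links Data.frame from [link_peaks_to_genes()].
#' @param assignments Data.frame gene_id -> cluster (NA allowed).
#' @param exclude_constant Drop "0000"/"1111" sites from testing?
#' @return Data.frame: cluster, motif_id, pattern, count (cell a), b, c,
#'   d, odds_ratio, p. Motifs with no cluster-linked sites are skipped
#'   (attribute `skipped_motifs`).
#' @export
enrich_patterns <- function(patterns, site_peaks, links, assignments,
                            exclude_constant = TRUE) {
  d <- merge(patterns, site_peaks, by = "site_id")
  d$gene_id <- links$gene_id[match(d$peak_id, links$peak_id)]
  d$cluster <- assignments$cluster[match(d$gene_id, assignments$gene_id)]
  d <- d[!is.na(d$cluster), , drop = FALSE]
  if (exclude_constant) d <- d[!d$constant, , drop = FALSE]
  all_motifs <- sort(unique(patterns$motif_id))
  motifs <- sort(unique(d$motif_id))
  skipped <- setdiff(all_motifs, motifs)
  clusters <- sort(unique(assignments$cluster[!is.na(assignments$cluster)]))
  pats <- all_binding_patterns()
  rows <- lapply(motifs, function(mo) {
    dm <- d[d$motif_id == mo, , drop = FALSE]
    do.call(rbind, lapply(clusters, function(cc) {
      in_c <- dm$cluster == cc
      do.call(rbind, lapply(pats, function(pp) {
        is_p <- dm$pattern == pp
        ft <- fisher_exact_2x2(c(sum(is_p & in_c), sum(is_p & !in_c),
                                 sum(!is_p & in_c), sum(!is_p & !in_c)))
        data.frame(cluster = cc, motif_id = mo, pattern = pp, count = ft$a,
                   b = ft$b, c = ft$c, d = ft$d, odds_ratio = ft$odds_ratio,
                   p = ft$p, stringsAsFactors = FALSE)
      }))
    }))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$cluster, out$p, out$motif_id, out$pattern), ]
  rownames(out) <- NULL
  attr(out, "skipped_motifs") <- skipped
  out
}

#' Default assumed primary/secondary binding patterns per cluster
#'
#' Encodes the expectation that a cluster's nearby sites are bound in the
#' weeks of highest expression of the archetype the cluster follows
#' (editable; no downstream result depends on these defaults).
#'
#' @return Named list cluster -> c(primary, secondary).
#' @export
default_assumed_patterns <- function() {
  list(`1` = c(primary = "0001", secondary = "0011"),
       `2` = c(primary = "0010", secondary = "0011"),
       `3` = c(primary = "0011", secondary = "0010"),
       `4` = c(primary = "0100", secondary = "0110"),
       `5` = c(primary = "1100", secondary = "1000"),
       `6` = c(primary = "1001", secondary = "1000"),
       `7` = c(primary = "1000", secondary = "1100"))
}

#' Flag assumed patterns and label the most significant motifs
#'
#' Each enrichment row is flagged primary/secondary/other against the
#' assumed-pattern map of its cluster; within every (cluster, pattern)
#' test family the motifs in the top `top_quantile` proportion by
#' significance get `labelled = TRUE` for display.
#'
#' @param enrichments Data.frame from [enrich_patterns()].
#' @param map Named list cluster -> c(primary, secondary); defaults to
#'   [default_assumed_patterns()].
#' @param top_quantile Proportion labelled per family (0 = none,
#'   1 = all).
#' @return The enrichment table with `assumed` and `labelled` columns.
#' @export
flag_assumed_and_label <- function(enrichments, map = default_assumed_patterns(),
                                   top_quantile = 0.05) {
  valid <- all_binding_patterns()
  for (cl in names(map)) {
    if (!all(map[[cl]] %in% valid)) {
      stop("assumed pattern for cluster ", cl, " not one of the 14 informative patterns")
    }
  }
  clusters <- unique(enrichments$cluster)
  missing <- setdiff(as.character(clusters), names(map))
  if (length(missing)) stop("assumed-pattern map missing cluster(s): ",
                            paste(missing, collapse = ", "))
  ass <- rep("other", nrow(enrichments))
  for (cl in names(map)) {
    i <- enrichments$cluster == as.integer(cl)
    ass[i & enrichments$pattern == map[[cl]][["primary"]]] <- "primary"
    ass[i & enrichments$pattern == map[[cl]][["secondary"]]] <- "secondary"
  }
  fam <- paste(enrichments$cluster, enrichments$pattern)
  labelled <- logical(nrow(enrichments))
  for (f in unique(fam)) {
    i <- which(fam == f)
    n_lab <- floor(top_quantile * length(i) + 1e-9)
    if (top_quantile >= 1) n_lab <- length(i)
    if (n_lab > 0L) {
      labelled[i[order(enrichments$p[i])][seq_len(n_lab)]] <- TRUE
    }
  }
  enrichments$assumed <- ass
  enrichments$labelled <- labelled
  enrichments
}
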