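#' @title Chromatin accessibility analysis
#' @description Unified peak merging across weeks, read counting from
#'   coverage tracks, differential accessibility between the key life-stage
#'   periods, nearest-TSS peak-to-gene linking, genomic-context annotation
#'   and the per-cluster Fisher association between accessibility direction
#'   and co-expression cluster membership.
#' @name chromatin
NULL

.ir <- function(start, end) IRanges::IRanges(start = start + 1L, end = end)

#' Merge per-week peak sets into a unified set
#'
#' Interval union per chromosome: overlapping or book-ended intervals
#' merge. Each unified peak records which weeks contributed a peak, so
#' per-week intersection counts are derivable.
#'
#' @param per_week_beds Named list of BED-like data.frames (chrom, start,
#'   end), one per week.
#' @return Data.frame: peak_id, chrom, start, end and one logical
#'   `in_<week>` column per input set.
#' @export
merge_peak_sets <- function(per_week_beds) {
  all <- do.call(rbind, lapply(names(per_week_beds), function(w) {
    d <- per_week_beds[[w]]
    data.frame(chrom = d$chrom, start = d$start, end = d$end, week = w,
               stringsAsFactors = FALSE)
  }))
  chroms <- sort(unique(all$chrom))
  out <- lapply(chroms, function(ch) {
    d <- all[all$chrom == ch, , drop = FALSE]
    merged <- IRanges::reduce(.ir(d$start, d$end))
    hits <- IRanges::findOverlaps(merged, .ir(d$start, d$end))
    member <- sapply(names(per_week_beds), function(w) {
      q <- unique(S4Vectors::queryHits(hits)[d$week[S4Vectors::subjectHits(hits)] == w])
      seq_along(merged) %in% q
    })
    if (length(merged) == 1L) member <- matrix(member, nrow = 1L,
                                               dimnames = list(NULL, names(per_week_beds)))
    df <- data.frame(chrom = ch, start = IRanges::start(merged) - 1L,
                     end = IRanges::end(merged), stringsAsFactors = FALSE)
    colnames(member) <- paste0("in_", names(per_week_beds))
    cbind(df, member)
  })
  res <- do.call(rbind, out)
  res <- cbind(peak_id = sprintf("upeak%06d", seq_len(nrow(res))), res,
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Count read-equivalents in peaks from coverage tracks
#'
#' Per-peak integral of coverage x width over the interval, one column per
#' sample.
#'
#' @param peaks Data.frame with peak_id, chrom, start, end.
#' @param coverage_by_sample Named list of bedGraph data.frames.
#' @return Numeric matrix peaks x samples (rownames = peak_id).
#' @export
count_reads_in_peaks <- function(peaks, coverage_by_sample) {
  counts <- matrix(0, nrow(peaks), length(coverage_by_sample),
                   dimnames = list(peaks$peak_id, names(coverage_by_sample)))
  for (si in seq_along(coverage_by_sample)) {
    cov <- coverage_by_sample[[si]]
    orphan <- setdiff(unique(cov$chrom), unique(peaks$chrom))
    if (length(orphan)) {
      warning("coverage chromosome(s) absent from peaks: ",
              paste(orphan, collapse = ", "))
    }
    for (ch in intersect(unique(peaks$chrom), unique(cov$chrom))) {
      pi <- which(peaks$chrom == ch)
      cd <- cov[cov$chrom == ch, , drop = FALSE]
      hits <- IRanges::findOverlaps(.ir(peaks$start[pi], peaks$end[pi]),
                                    .ir(cd$start, cd$end))
      q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
      w <- pmin(peaks$end[pi][q], cd$end[s]) - pmax(peaks$start[pi][q], cd$start[s])
      contr <- w * cd$value[s]
      counts[pi, si] <- counts[pi, si] +
        as.vector(tapply(contr, factor(q, levels = seq_along(pi)), sum, default = 0))
    }
  }
  counts
}

#' Differential accessibility between two weeks
#'
#' Welch t on log2 CPM of peak counts. `logFC` is later week minus earlier
#' week, so direction "up" means more accessible at the later time point.
#'
#' @param counts Peak count matrix from [count_reads_in_peaks()].
#' @param samples Sample sheet with `sample_id`, `week` matching columns.
#' @param contrast String "w<A>_w<B>" naming the earlier and later week,
#'   e.g. "w10_w19".
#' @param alpha DA threshold on BH FDR.
#' @param pseudocount Pseudocount for the log2 CPM transform.
#' @return Data.frame: peak_id, contrast, logFC, p, FDR, significant,
#'   direction (up/down for significant peaks, NA otherwise).
#' @export
test_da <- function(counts, samples, contrast, alpha = 0.05, pseudocount = 0.5) {
  m <- regmatches(contrast, regexec("^w(\\d+)_w(\\d+)$", contrast))[[1L]]
  if (length(m) != 3L) stop("unknown contrast '", contrast,
                            "'; expected form 'w<earlier>_w<later>'")
  wA <- as.integer(m[2L]); wB <- as.integer(m[3L])
  if (!all(c(wA, wB) %in% samples$week)) {
    stop("contrast weeks not present; have ",
         paste(sort(unique(samples$week)), collapse = ", "))
  }
  idx <- match(colnames(counts), samples$sample_id)
  wk <- samples$week[idx]
  values <- cpm_normalize(counts, log = TRUE, pseudocount = pseudocount)
  res <- pairwise_test(values, which(wk == wB), which(wk == wA))
  data.frame(peak_id = res$feature_id, contrast = contrast, logFC = res$logFC,
             p = res$p, FDR = res$FDR, significant = res$FDR < alpha,
             direction = ifelse(res$FDR < alpha,
                                ifelse(res$logFC > 0, "up", "down"), NA_character_),
             stringsAsFactors = FALSE)
}

#' Link peaks to their nearest-TSS gene
#'
#' Each peak is linked to the gene minimising |peak midpoint - TSS| on its
#' chromosome; equidistant TSSs resolve to the lexicographically smallest
#' gene_id. The signed distance is negative when the midpoint lies
#' upstream of the TSS on the gene's strand. Peaks on chromosomes without
#' genes are flagged unassigned.
#'
#' @param peaks Data.frame with peak_id, chrom, start, end.
#' @param annotation A `genome_annotation`.
#' @return Data.frame: peak_id, gene_id, distance, unassigned.
#' @export
link_peaks_to_genes <- function(peaks, annotation) {
  g <- annotation$genes
  if (nrow(g) == 0L) stop("annotation is empty")
  mid <- (peaks$start + peaks$end) %/% 2L
  gene_id <- rep(NA_character_, nrow(peaks))
  dist <- rep(NA_integer_, nrow(peaks))
  for (ch in unique(peaks$chrom)) {
    pi <- which(peaks$chrom == ch)
    gc <- g[g$chrom == ch, , drop = FALSE]
    if (nrow(gc) == 0L) next
    # one candidate per distinct TSS position: smaller gene_id always wins
    gc <- gc[order(gc$tss, gc$gene_id), , drop = FALSE]
    gc <- gc[!duplicated(gc$tss), , drop = FALSE]
    i <- findInterval(mid[pi], gc$tss)
    dl <- ifelse(i >= 1L, mid[pi] - gc$tss[pmax(i, 1L)], NA_integer_)
    dr <- ifelse(i < nrow(gc), gc$tss[pmin(i + 1L, nrow(gc))] - mid[pi], NA_integer_)
    pick_left <- !is.na(dl) & (is.na(dr) | dl < dr |
                                 (dl == dr & gc$gene_id[pmax(i, 1L)] <
                                    gc$gene_id[pmin(i + 1L, nrow(gc))]))
    sel <- ifelse(pick_left, pmax(i, 1L), pmin(i + 1L, nrow(gc)))
    gid <- gc$gene_id[sel]
    tss <- gc$tss[sel]
    strand <- gc$strand[sel]
    gene_id[pi] <- gid
    dist[pi] <- ifelse(strand == "+", mid[pi] - tss, tss - mid[pi])
  }
  data.frame(peak_id = peaks$peak_id, gene_id = gene_id, distance = dist,
             unassigned = is.na(gene_id), stringsAsFactors = FALSE)
}

#' Map motif sites to the unified peak containing them
#'
#' @param motif_sites Data.frame with site_id, chrom, start, end.
#' @param peaks Unified peak set with peak_id, chrom, start, end.
#' @return Data.frame site_id, peak_id (sites in no peak are dropped).
#' @export
sites_to_host_peaks <- function(motif_sites, peaks) {
  out <- lapply(unique(motif_sites$chrom), function(ch) {
    si <- which(motif_sites$chrom == ch)
    pc <- peaks[peaks$chrom == ch, , drop = FALSE]
    if (!nrow(pc)) return(NULL)
    hits <- IRanges::findOverlaps(
      .ir(motif_sites$start[si], motif_sites$end[si]),
      .ir(pc$start, pc$end), type = "within", select = "first")
    keep <- !is.na(hits)
    data.frame(site_id = motif_sites$site_id[si][keep],
               peak_id = pc$peak_id[hits[keep]], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Classify points or intervals by genomic context
#'
#' Four-way classification with precedence promoter > exon > intron >
#' intergenic. The promoter window is strand-aware around the TSS;
#' intervals are classified by their midpoint.
#'
#' @param x Data.frame with `chrom` and either `pos` (0-based point) or
#'   `start`/`end`.
#' @param annotation A `genome_annotation`.
#' @param promoter_window c(upstream_bp, downstream_bp) around the TSS.
#' @return Character vector in {promoter, exon, intron, intergenic}.
#' @export
annotate_location <- function(x, annotation, promoter_window = c(1500L, 500L)) {
  pos <- if ("pos" %in% names(x)) x$pos else (x$start + x$end) %/% 2L
  g <- annotation$genes
  e <- annotation$exons
  out <- rep("intergenic", nrow(x))
  up <- promoter_window[1L]; down <- promoter_window[2L]
  for (ch in unique(x$chrom)) {
    xi <- which(x$chrom == ch)
    p1 <- pos[xi] + 1L  # 1-based point
    gc <- g[g$chrom == ch, , drop = FALSE]
    ec <- e[e$chrom == ch, , drop = FALSE]
    if (nrow(gc)) {
      body <- IRanges::findOverlaps(IRanges::IRanges(p1, p1), .ir(gc$start, gc$end))
      out[xi][unique(S4Vectors::queryHits(body))] <- "intron"
    }
    if (nrow(ec)) {
      ex <- IRanges::findOverlaps(IRanges::IRanges(p1, p1), .ir(ec$start, ec$end))
      out[xi][unique(S4Vectors::queryHits(ex))] <- "exon"
    }
    if (nrow(gc)) {
      ps <- ifelse(gc$strand == "+", gc$tss - up + 1L, gc$tss - down + 2L)
      pe <- ifelse(gc$strand == "+", gc$tss + down, gc$tss + up + 1L)
      pr <- IRanges::findOverlaps(IRanges::IRanges(p1, p1), IRanges::IRanges(ps, pe))
      out[xi][unique(S4Vectors::queryHits(pr))] <- "promoter"
    }
  }
  out
}

#' Fisher association between accessibility direction and expression cluster
#'
#' For one contrast, DA peaks are split into up and down sets, linked to
#' their nearest genes, and restricted to genes with a cluster assignment.
#' Per cluster c the 2x2 is (up vs down) x (linked to cluster-c DEGs vs
#' other-cluster DEGs).
#'
#' @param da_results Data.frame from [test_da()] (one contrast).
#' @param links Data.frame from [link_peaks_to_genes()].
#' @param assignments Data.frame from [cluster_degs()] (`gene_id`,
#'   `cluster`).
#' @return Data.frame: contrast, cluster, a, b, c, d, odds_ratio, p,
#'   undefined (flag for clusters with no linked DEGs).
#' @export
da_deg_association <- function(da_results, links, assignments) {
  da <- da_results[!is.na(da_results$direction), , drop = FALSE]
  gid <- links$gene_id[match(da$peak_id, links$peak_id)]
  cl <- assignments$cluster[match(gid, assignments$gene_id)]
  keep <- !is.na(cl)
  da <- da[keep, , drop = FALSE]; cl <- cl[keep]
  clusters <- sort(unique(assignments$cluster[!is.na(assignments$cluster)]))
  rows <- lapply(clusters, function(cc) {
    a <- sum(da$direction == "up" & cl == cc)
    b <- sum(da$direction == "up" & cl != cc)
    c_ <- sum(da$direction == "down" & cl == cc)
    d <- sum(da$direction == "down" & cl != cc)
    ft <- fisher_exact_2x2(c(a, b, c_, d))
    data.frame(contrast = unique(da_results$contrast), cluster = cc,
               a = a, b = b, c = c_, d = d, odds_ratio = ft$odds_ratio,
               p = ft$p, undefined = ft$or_undefined, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
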