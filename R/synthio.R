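#' @title Synthetic multi-omics generator with planted ground truth
#' @description Emulates the smoltification study design: four sampling
#'   weeks (1, 10, 19, 25), a short-photoperiod time-course arm plus a
#'   long-photoperiod arm (weeks 10/19) and a week-25 freshwater control
#'   arm; seven co-expression archetypes planted into negative-binomial
#'   counts; ATAC peaks as coverage plateaus with planted accessibility
#'   fold changes and motif-site footprint dips following planted 4-week
#'   binding patterns; and CpG tables with planted methylation shifts.
#'   Every planted effect is enumerated in a machine-readable ground-truth
#'   object so recovery is always measured against truth, never intent.
#' @name synthio
NULL

.default_weeks <- c(1L, 10L, 19L, 25L)

#' Simulation design
#'
#' @param n_chroms Number of chromosomes (coordinate skeletons only).
#' @param chrom_len Chromosome length in bp.
#' @param n_genes Total genes across chromosomes.
#' @param weeks Exactly four sampling weeks in chronological order.
#' @param replicates_per_week RNA-seq replicates per week (>= 2).
#' @param atac_replicates ATAC replicates per week (>= 2).
#' @param rrbs_replicates RRBS replicates per week (>= 3).
#' @param groups Fish group labels.
#' @param seed Integer seed; fixed seed gives identical outputs.
#' @return A `sim_design` list.
#' @export
sim_design <- function(n_chroms = 2L, chrom_len = 1e6L, n_genes = 200L,
                       weeks = .default_weeks, replicates_per_week = 4L,
                       atac_replicates = 2L, rrbs_replicates = 4L,
                       groups = c("short", "long", "fresh_control"),
                       seed = 1L) {
  if (length(weeks) != 4L || is.unsorted(weeks, strictly = TRUE)) {
    stop("weeks must be exactly 4 labels in chronological order")
  }
  if (replicates_per_week < 2L) stop("replicates_per_week must be >= 2")
  if (atac_replicates < 2L) stop("atac_replicates must be >= 2")
  structure(list(n_chroms = as.integer(n_chroms), chrom_len = as.integer(chrom_len),
                 n_genes = as.integer(n_genes), weeks = as.integer(weeks),
                 replicates_per_week = as.integer(replicates_per_week),
                 atac_replicates = as.integer(atac_replicates),
                 rrbs_replicates = as.integer(rrbs_replicates),
                 groups = groups, seed = as.integer(seed)),
            class = "sim_design")
}

#' Co-expression archetype profiles
#'
#' Seven week-multiplier vectors encoding stylised temporal trends:
#' seawater induction, smolt peak, sustained post-smolt rise, photoperiod
#' peak, pre-smolt plateau with loss at smoltification, suppression during
#' the mid-experiment weeks, and loss from the parr stage onward. The
#' multiplier `fold` sets the planted effect size (default 8).
#'
#' @param fold Peak-to-trough expression ratio of each archetype.
#' @return 7 x 4 matrix of week multipliers (rows = clusters).
#' @export
archetype_profiles <- function(fold = 8) {
  shapes <- rbind(
    c(0, 0, 0, 1),  # 1: induced at sea (week 25)
    c(0, 0, 1, 0),  # 2: smolt peak (week 19)
    c(0, 0, 1, 1),  # 3: up from smoltification onward
    c(0, 1, 0, 0),  # 4: short-photoperiod peak (week 10)
    c(1, 1, 0, 0),  # 5: high pre-smolt, falls at smoltification
    c(1, 0, 0, 1),  # 6: suppressed in the mid-experiment weeks
    c(1, 0, 0, 0))  # 7: loss from parr onward
  m <- fold^shapes
  rownames(m) <- paste0("cluster", 1:7)
  colnames(m) <- paste0("week_", .default_weeks)
  m
}

#' Place non-overlapping gene models on coordinate skeletons
#'
#' Genes get a body of 2-6 kb, 2-5 non-overlapping exons and a random
#' strand; the TSS is the 0-based gene start on + and end - 1 on -.
#' Deterministic under the design seed.
#'
#' @param design A [sim_design()].
#' @return A `genome_annotation`.
#' @export
simulate_annotation <- function(design) {
  set.seed(design$seed + 101L)
  n <- design$n_genes
  if (n == 0L) {
    return(genome_annotation(
      data.frame(gene_id = character(), chrom = character(), strand = character(),
                 start = integer(), end = integer(), stringsAsFactors = FALSE),
      data.frame(gene_id = character(), chrom = character(),
                 start = integer(), end = integer(), stringsAsFactors = FALSE)))
  }
  per_chrom <- diff(floor(seq(0, n, length.out = design$n_chroms + 1L)))
  genes <- list(); exons <- list(); gi <- 0L
  for (ci in seq_len(design$n_chroms)) {
    chrom <- paste0("chr", ci)
    ng <- per_chrom[ci]
    if (ng == 0L) next
    lens <- sample(2000:6000, ng, replace = TRUE)
    gaps <- sample(3000:9000, ng, replace = TRUE)
    need <- sum(lens) + sum(gaps)
    if (need > design$chrom_len) {
      stop("cannot pack ", ng, " genes into ", chrom, ": need ", need,
           " bp but chrom_len is ", design$chrom_len)
    }
    starts <- cumsum(gaps) + c(0L, cumsum(lens))[seq_len(ng)]
    ids <- sprintf("gene%05d", gi + seq_len(ng))
    gi <- gi + ng
    strands <- sample(c("+", "-"), ng, replace = TRUE)
    genes[[ci]] <- data.frame(gene_id = ids, chrom = chrom, strand = strands,
                              start = as.integer(starts),
                              end = as.integer(starts + lens),
                              stringsAsFactors = FALSE)
    ex <- lapply(seq_len(ng), function(i) {
      n_ex <- sample(2:5, 1L)
      # cut the body at sorted interior points; odd segments are exons
      cuts <- sort(sample(seq(100L, lens[i] - 100L, by = 50L), 2L * n_ex - 2L))
      bounds <- c(0L, cuts, lens[i])
      seg_start <- bounds[seq(1L, length(bounds) - 1L, by = 2L)]
      seg_end <- bounds[seq(2L, length(bounds), by = 2L)]
      data.frame(gene_id = ids[i], chrom = chrom,
                 start = as.integer(starts[i] + seg_start),
                 end = as.integer(starts[i] + seg_end),
                 stringsAsFactors = FALSE)
    })
    exons[[ci]] <- do.call(rbind, ex)
  }
  genome_annotation(do.call(rbind, genes), do.call(rbind, exons))
}

#' Plant the ground truth for all omic layers
#'
#' Decides, once, which genes follow which archetype, which genes respond
#' to the photoperiod/salinity contrasts, the peak catalogue with planted
#' accessibility fold changes, the motif catalogue with planted binding
#' patterns (including motifs coupled to an expression cluster), and the
#' CpGs with planted methylation shifts. The returned object enumerates
#' every planted effect; `write_ground_truth()` serialises it as JSON.
#'
#' @param design A [sim_design()].
#' @param annotation A `genome_annotation` from [simulate_annotation()].
#' @param frac_archetype Fraction of genes planted into the 7 archetypes.
#' @param frac_contrast Fraction of genes planted per pairwise contrast.
#' @param contrast_fold Fold change of contrast-responsive genes.
#' @param archetype_fold Peak-to-trough fold of archetype profiles.
#' @param frac_da Fraction of peaks planted differentially accessible per
#'   week-pair contrast (half up, half down).
#' @param da_fold Accessibility fold change of planted DA peaks.
#' @param n_motifs Motif catalogue size.
#' @param sites_per_motif Sites per motif.
#' @param n_coupled_motifs Motifs whose sites sit near genes of one target
#'   cluster and share one planted binding pattern.
#' @param dip_frac Footprint coverage dip as a fraction of the local
#'   plateau (default 0.3).
#' @param n_cpgs CpG sites simulated.
#' @param n_dmc CpGs planted with a methylation shift.
#' @param dmc_delta Planted shift in percentage points, applied at weeks
#'   19 and 25.
#' @param da_cluster_coupling Optional list(contrast =, cluster =): the up
#'   peaks planted for that contrast are drawn preferentially from
#'   promoter peaks of the cluster's genes, planting a direction-cluster
#'   association.
#' @return A `ground_truth` list.
#' @export
plant_truth <- function(design, annotation,
                        frac_archetype = 0.35, frac_contrast = 0.05,
                        contrast_fold = 8, archetype_fold = 8,
                        frac_da = 0.2, da_fold = 2,
                        n_motifs = 12L, sites_per_motif = 30L,
                        n_coupled_motifs = 3L, dip_frac = 0.3,
                        n_cpgs = 1000L, n_dmc = 100L, dmc_delta = 40,
                        da_cluster_coupling = NULL) {
  set.seed(design$seed + 202L)
  g <- annotation$genes
  n <- nrow(g)
  genes <- data.frame(gene_id = g$gene_id, cluster = NA_integer_,
                      stringsAsFactors = FALSE)
  n_arch <- floor(frac_archetype * n / 7) * 7L
  arch_ids <- sample(g$gene_id, n_arch)
  genes$cluster[match(arch_ids, genes$gene_id)] <- rep(1:7, length.out = n_arch)

  pool <- setdiff(g$gene_id, arch_ids)
  n_ctr <- floor(frac_contrast * n)
  contrasts <- c("photoperiod_w10", "salinity_w25")
  ctr <- do.call(rbind, lapply(contrasts, function(cn) {
    ids <- sample(pool, min(n_ctr, length(pool)))
    pool <<- setdiff(pool, ids)
    if (length(ids) == 0L) return(NULL)
    data.frame(gene_id = ids, contrast = cn,
               direction = sample(c(-1L, 1L), length(ids), replace = TRUE),
               fold = contrast_fold, stringsAsFactors = FALSE)
  }))
  if (is.null(ctr)) {
    ctr <- data.frame(gene_id = character(), contrast = character(),
                      direction = integer(), fold = numeric(),
                      stringsAsFactors = FALSE)
  }

  # peak catalogue: one promoter peak per gene plus 30% intergenic peaks
  halfw <- 250L
  mid_prom <- g$tss
  n_inter <- floor(0.3 * n)
  peaks <- data.frame(
    chrom = g$chrom, mid = mid_prom, gene_id = g$gene_id,
    kind = "promoter", stringsAsFactors = FALSE)
  if (n_inter > 0L && n > 0L) {
    ic <- sample(unique(g$chrom), n_inter, replace = TRUE)
    imid <- as.integer(stats::runif(n_inter, 2000, design$chrom_len - 2000))
    peaks <- rbind(peaks, data.frame(chrom = ic, mid = imid,
                                     gene_id = NA_character_, kind = "intergenic",
                                     stringsAsFactors = FALSE))
  }
  peaks$start <- pmax(0L, peaks$mid - halfw)
  peaks$end <- pmin(design$chrom_len, peaks$mid + halfw)
  # drop rare overlaps so planted peaks stay independent units
  o <- order(peaks$chrom, peaks$start)
  peaks <- peaks[o, , drop = FALSE]
  keep <- rep(TRUE, nrow(peaks))
  if (nrow(peaks) > 1L) {
    ovl <- peaks$chrom[-1L] == peaks$chrom[-nrow(peaks)] &
      peaks$start[-1L] < cummax_by(peaks$end[-nrow(peaks)], peaks$chrom[-nrow(peaks)])
    keep[-1L] <- !ovl
  }
  peaks <- peaks[keep, , drop = FALSE]
  peaks$peak_id <- sprintf("peak%05d", seq_len(nrow(peaks)))
  peaks$base_height <- stats::runif(nrow(peaks), 10, 30)
  rownames(peaks) <- NULL
  peaks <- peaks[, c("peak_id", "chrom", "start", "end", "gene_id", "kind",
                     "base_height")]

  # planted DA: per contrast, frac_da of peaks, half up / half down; when
  # a direction-cluster coupling is requested, the up peaks of its contrast
  # are drawn from promoter peaks of the target cluster's genes first
  pair_names <- paste0("w", design$weeks[-4L], "_w", design$weeks[-1L])
  n_da <- floor(frac_da * nrow(peaks) / 2) * 2L
  da_pool <- sample(peaks$peak_id)
  da <- do.call(rbind, lapply(seq_along(pair_names), function(i) {
    n_take <- min(n_da, length(da_pool))
    if (n_take == 0L) return(NULL)
    if (!is.null(da_cluster_coupling) &&
        pair_names[i] == da_cluster_coupling$contrast) {
      cl_genes <- genes$gene_id[!is.na(genes$cluster) &
                                  genes$cluster == da_cluster_coupling$cluster]
      up_take <- utils::head(intersect(da_pool, peaks$peak_id[
        !is.na(peaks$gene_id) & peaks$gene_id %in% cl_genes]), n_take %/% 2L)
      rest <- utils::head(setdiff(da_pool, up_take), n_take - length(up_take))
      take <- c(up_take, rest)
      dirn <- c(rep("up", length(up_take)),
                rep(c("down", "up"), length.out = length(rest)))
    } else {
      take <- da_pool[seq_len(n_take)]
      dirn <- rep(c("up", "down"), length.out = n_take)
    }
    da_pool <<- setdiff(da_pool, take)
    data.frame(peak_id = take, contrast = pair_names[i], fold = da_fold,
               direction = dirn, stringsAsFactors = FALSE)
  }))

  # motif catalogue and sites; coupled motifs target one cluster's promoters
  patterns <- all_binding_patterns()
  motif_ids <- sprintf("MOTIF%03d", seq_len(n_motifs))
  widths <- sample(6:20, n_motifs, replace = TRUE)
  coupled <- rep(NA_integer_, n_motifs)
  if (n_coupled_motifs > 0L) {
    coupled[seq_len(min(n_coupled_motifs, n_motifs))] <-
      rep(1:7, length.out = min(n_coupled_motifs, n_motifs))
  }
  motif_pattern <- sample(patterns, n_motifs, replace = TRUE)
  motifs <- data.frame(motif_id = motif_ids, width = widths,
                       pattern = motif_pattern, coupled_cluster = coupled,
                       stringsAsFactors = FALSE)
  sites <- do.call(rbind, lapply(seq_len(n_motifs), function(mi) {
    w <- widths[mi]
    if (!is.na(coupled[mi])) {
      # planted sites at the target cluster's promoters carry the motif's
      # pattern; background sites elsewhere carry random patterns, so the
      # enrichment 2x2 has a within-motif contrast to work against
      cl_genes <- genes$gene_id[!is.na(genes$cluster) & genes$cluster == coupled[mi]]
      fg <- peaks[!is.na(peaks$gene_id) & peaks$gene_id %in% cl_genes, , drop = FALSE]
      if (nrow(fg) == 0L) return(NULL)
      fg <- fg[sample.int(nrow(fg), min(sites_per_motif, nrow(fg))), , drop = FALSE]
      bg <- peaks[sample.int(nrow(peaks), sites_per_motif, replace = TRUE), ,
                  drop = FALSE]
      host <- rbind(fg, bg)
      pat <- c(rep(motif_pattern[mi], nrow(fg)),
               sample(patterns, nrow(bg), replace = TRUE))
    } else {
      host <- peaks[sample.int(nrow(peaks), sites_per_motif, replace = TRUE), ,
                    drop = FALSE]
      pat <- sample(patterns, nrow(host), replace = TRUE)
    }
    if (any(host$end - host$start < w + 2L)) stop("motif wider than its host peak")
    off <- floor(stats::runif(nrow(host), 60, host$end - host$start - w - 60))
    data.frame(motif_id = motif_ids[mi], peak_id = host$peak_id,
               chrom = host$chrom, start = as.integer(host$start + off),
               end = as.integer(host$start + off + w), pattern = pat,
               stringsAsFactors = FALSE)
  }))
  sites$site_id <- sprintf("site%05d", seq_len(nrow(sites)))
  rownames(sites) <- NULL

  # CpGs: uniform positions; planted shifts at weeks 19/25
  cpg_chrom <- paste0("chr", sample.int(design$n_chroms, n_cpgs, replace = TRUE))
  cpg_pos <- as.integer(stats::runif(n_cpgs, 1, design$chrom_len))
  base_score <- stats::runif(n_cpgs, 20, 60)
  delta <- rep(0, n_cpgs)
  if (n_dmc > 0L) {
    idx <- sample.int(n_cpgs, min(n_dmc, n_cpgs))
    # shift towards the far boundary so default-size deltas never clip
    sgn <- ifelse(base_score[idx] <= 50, 1, -1)
    delta[idx] <- dmc_delta * sgn
  }
  clipped <- base_score + delta
  if (any(clipped > 100 | clipped < 0)) {
    warning("planted methylation delta clipped to [0, 100] for ",
            sum(clipped > 100 | clipped < 0), " CpG(s)")
  }
  cpgs <- data.frame(cpg_id = sprintf("cpg%05d", seq_len(n_cpgs)),
                     chrom = cpg_chrom, pos = cpg_pos,
                     base_score = base_score, delta = delta,
                     affected_weeks = ifelse(delta != 0,
                                             paste(design$weeks[3:4], collapse = ","), ""),
                     stringsAsFactors = FALSE)
  cpgs <- cpgs[order(cpgs$chrom, cpgs$pos), ]
  # collisions would break per-position merging downstream
  cpgs <- cpgs[!duplicated(paste(cpgs$chrom, cpgs$pos)), ]
  rownames(cpgs) <- NULL

  structure(list(design = design, annotation = annotation, genes = genes,
                 contrast_genes = ctr, peak_catalog = peaks, da_peaks = da,
                 motif_catalog = motifs, motif_sites = sites, cpgs = cpgs,
                 params = list(frac_archetype = frac_archetype,
                               frac_contrast = frac_contrast,
                               contrast_fold = contrast_fold,
                               archetype_fold = archetype_fold,
                               frac_da = frac_da, da_fold = da_fold,
                               dip_frac = dip_frac, dmc_delta = dmc_delta)),
            class = "ground_truth")
}

# running max of `x` restarted at each change of `by` (assumes sorted by `by`)
cummax_by <- function(x, by) {
  out <- x
  for (i in seq_along(x)[-1]) {
    out[i] <- if (by[i] == by[i - 1L]) max(out[i - 1L], x[i]) else x[i]
  }
  out
}

#' Serialise a ground-truth object as JSON
#' @param truth A `ground_truth`.
#' @param path Output path.
#' @export
write_ground_truth <- function(truth, path) {
  out <- truth[c("genes", "contrast_genes", "da_peaks", "motif_catalog",
                 "motif_sites", "cpgs", "params")]
  jsonlite::write_json(out, path, dataframe = "columns", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Simulate negative-binomial expression counts
#'
#' Planted archetype genes follow their cluster's week-multiplier profile
#' within every arm; contrast-responsive genes are shifted in the long
#' photoperiod arm (week 10) or the freshwater control arm (week 25) so
#' that the short-vs-other log fold change carries the planted sign.
#' Library sizes vary by +/-20% around their nominal value.
#'
#' @param design A [sim_design()].
#' @param truth A `ground_truth`.
#' @param dispersion Negative-binomial dispersion (> 0).
#' @param base_mean Median baseline expression in counts.
#' @return An `expr_set`: counts matrix, `samples` sheet (sample_id, week,
#'   group, replicate) and `gene_lengths`.
#' @export
simulate_expression <- function(design, truth, dispersion = 0.1,
                                base_mean = 200) {
  if (dispersion <= 0) stop("dispersion must be > 0")
  set.seed(design$seed + 303L)
  weeks <- design$weeks
  reps <- design$replicates_per_week
  sheets <- list(
    expand.grid(week = weeks, replicate = seq_len(reps), group = "short",
                stringsAsFactors = FALSE),
    expand.grid(week = weeks[2:3], replicate = seq_len(reps), group = "long",
                stringsAsFactors = FALSE),
    expand.grid(week = weeks[4L], replicate = seq_len(reps),
                group = "fresh_control", stringsAsFactors = FALSE))
  samples <- do.call(rbind, sheets)
  samples$sample_id <- sprintf("%s_w%d_r%d", samples$group, samples$week,
                               samples$replicate)
  samples <- samples[, c("sample_id", "week", "group", "replicate")]

  g <- truth$annotation$genes
  ng <- nrow(g)
  base <- stats::rlnorm(ng, meanlog = log(base_mean), sdlog = 0.5)
  prof <- archetype_profiles(truth$params$archetype_fold)
  wk_idx <- match(samples$week, weeks)
  mu <- matrix(base, nrow = ng, ncol = nrow(samples))
  cl <- truth$genes$cluster[match(g$gene_id, truth$genes$gene_id)]
  planted <- which(!is.na(cl))
  if (length(planted)) {
    mu[planted, ] <- mu[planted, ] * prof[cl[planted], wk_idx, drop = FALSE]
  }
  for (i in seq_len(nrow(truth$contrast_genes))) {
    row <- truth$contrast_genes[i, ]
    gi <- match(row$gene_id, g$gene_id)
    arm <- if (row$contrast == "photoperiod_w10") {
      samples$group == "long" & samples$week == weeks[2L]
    } else {
      samples$group == "fresh_control" & samples$week == weeks[4L]
    }
    mu[gi, arm] <- mu[gi, arm] * row$fold^(-row$direction)
  }
  libf <- stats::runif(nrow(samples), 0.8, 1.2)
  mu <- sweep(mu, 2L, libf, `*`)
  counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                   nrow = ng,
                   dimnames = list(g$gene_id, samples$sample_id))
  structure(list(counts = counts, samples = samples,
                 gene_lengths = stats::setNames(g$end - g$start, g$gene_id)),
            class = "expr_set")
}

#' @export
print.expr_set <- function(x, ...) {
  cat("expr_set:", nrow(x$counts), "genes x", ncol(x$counts), "samples (",
      paste(unique(x$samples$group), collapse = "/"), ")\n")
  invisible(x)
}

#' Transcripts-per-million layer of an expression set
#' @param expr An `expr_set`.
#' @return TPM matrix.
#' @export
tpm <- function(expr) {
  rate <- expr$counts / expr$gene_lengths
  sweep(rate, 2L, 1e6 / colSums(rate), `*`)
}

#' Simulate ATAC coverage, per-week peak calls and motif sites
#'
#' Coverage is per-base Poisson: zero outside peaks, a plateau of the
#' peak's height inside, scaled by the planted accessibility fold from the
#' later week of a planted contrast onward, and dipped to `dip_frac` of
#' the plateau across a motif site in weeks where the site's planted
#' binding pattern digit is 1. Per-replicate tracks feed read counting;
#' replicate-pooled per-week tracks feed footprint scoring.
#'
#' @param design A [sim_design()].
#' @param truth A `ground_truth`.
#' @return List: `peaks_by_week` (named list of BED-like data.frames),
#'   `coverage_by_week` (pooled bedGraph data.frames), `coverage_by_sample`,
#'   `samples` sheet, and `motif_sites` (BED-like, name = motif_id).
#' @export
simulate_atac <- function(design, truth) {
  set.seed(design$seed + 404L)
  weeks <- design$weeks
  pk <- truth$peak_catalog
  sites <- truth$motif_sites
  dip <- truth$params$dip_frac

  # per-peak week multiplier from planted DA (applies from the later week on)
  fold_mat <- matrix(1, nrow(pk), 4L, dimnames = list(pk$peak_id, NULL))
  if (!is.null(truth$da_peaks) && nrow(truth$da_peaks)) {
    later <- as.integer(sub(".*_w", "", truth$da_peaks$contrast))
    for (i in seq_len(nrow(truth$da_peaks))) {
      r <- truth$da_peaks[i, ]
      wi <- which(weeks >= later[i])
      f <- if (r$direction == "up") r$fold else 1 / r$fold
      fold_mat[r$peak_id, wi] <- fold_mat[r$peak_id, wi] * f
    }
  }
  site_bound <- sapply(1:4, function(wi) substr(sites$pattern, wi, wi) == "1")
  if (nrow(sites) == 1L) site_bound <- matrix(site_bound, nrow = 1L)

  samples <- expand.grid(week = weeks, replicate = seq_len(design$atac_replicates),
                         stringsAsFactors = FALSE)
  samples$sample_id <- sprintf("atac_w%d_r%d", samples$week, samples$replicate)
  libf <- stats::runif(nrow(samples), 0.8, 1.2)

  chroms <- sort(unique(pk$chrom))
  cov_sample <- vector("list", nrow(samples))
  names(cov_sample) <- samples$sample_id
  for (si in seq_len(nrow(samples))) {
    wi <- match(samples$week[si], weeks)
    per_chrom <- lapply(chroms, function(ch) {
      v <- numeric(design$chrom_len)
      rows <- which(pk$chrom == ch)
      for (r in rows) {
        lam <- pk$base_height[r] * fold_mat[r, wi] * libf[si]
        idx <- (pk$start[r] + 1L):pk$end[r]
        v[idx] <- stats::rpois(length(idx), lam)
        srows <- which(sites$peak_id == pk$peak_id[r] & site_bound[, wi])
        for (s in srows) {
          sidx <- (sites$start[s] + 1L):sites$end[s]
          v[sidx] <- stats::rpois(length(sidx), lam * dip)
        }
      }
      rle_to_bedgraph(ch, v)
    })
    cov_sample[[si]] <- do.call(rbind, per_chrom)
  }
  cov_week <- lapply(weeks, function(w) {
    ids <- samples$sample_id[samples$week == w]
    pool_coverage(cov_sample[ids], design$chrom_len)
  })
  names(cov_week) <- paste0("week_", weeks)

  peaks_by_week <- lapply(seq_along(weeks), function(wi) {
    present <- stats::runif(nrow(pk)) < 0.9
    df <- pk[present, c("chrom", "start", "end", "peak_id"), drop = FALSE]
    names(df)[4L] <- "name"
    df$score <- 0; df$strand <- "."
    rownames(df) <- NULL
    df
  })
  names(peaks_by_week) <- paste0("week_", weeks)

  ms <- sites[, c("chrom", "start", "end", "motif_id")]
  names(ms)[4L] <- "name"
  ms$score <- 0; ms$strand <- "."
  ms$site_id <- sites$site_id
  list(peaks_by_week = peaks_by_week, coverage_by_week = cov_week,
       coverage_by_sample = cov_sample, samples = samples, motif_sites = ms)
}

# collapse a per-base vector to bedGraph rows (0-based half-open)
rle_to_bedgraph <- function(chrom, v) {
  r <- rle(v)
  end <- cumsum(r$lengths)
  start <- end - r$lengths
  keep <- r$values != 0
  data.frame(chrom = chrom, start = as.integer(start[keep]),
             end = as.integer(end[keep]), value = r$values[keep],
             stringsAsFactors = FALSE)
}

# sum several bedGraph data.frames into one pooled track
pool_coverage <- function(cov_list, chrom_len) {
  chroms <- sort(unique(unlist(lapply(cov_list, function(d) unique(d$chrom)))))
  out <- lapply(chroms, function(ch) {
    v <- numeric(chrom_len)
    for (d in cov_list) {
      dd <- d[d$chrom == ch, , drop = FALSE]
      for (i in seq_len(nrow(dd))) {
        v[(dd$start[i] + 1L):dd$end[i]] <- v[(dd$start[i] + 1L):dd$end[i]] + dd$value[i]
      }
    }
    rle_to_bedgraph(ch, v)
  })
  do.call(rbind, out)
}

#' Simulate Bismark-style CpG methylation tables
#'
#' Per-CpG binomial draws around the planted base methylation; planted
#' DMCs shift by their delta (clipped to \[0, 100\]) in the affected weeks.
#' Coverage is Poisson around `coverage_mean` with a small low-coverage
#' admixture so the >= 10-read filter has work to do.
#'
#' @param design A [sim_design()].
#' @param truth A `ground_truth`.
#' @param coverage_mean Mean read coverage per CpG.
#' @return List: `records` (per-sample list of data.frames with chrom,
#'   pos, count_M, count_U), `samples` sheet.
#' @export
simulate_methylation <- function(design, truth, coverage_mean = 30) {
  set.seed(design$seed + 505L)
  weeks <- design$weeks
  cp <- truth$cpgs
  samples <- expand.grid(week = weeks, replicate = seq_len(design$rrbs_replicates),
                         stringsAsFactors = FALSE)
  samples$sample_id <- sprintf("rrbs_w%d_r%d", samples$week, samples$replicate)
  affected <- lapply(strsplit(cp$affected_weeks, ","), as.integer)
  recs <- lapply(seq_len(nrow(samples)), function(si) {
    w <- samples$week[si]
    hit <- vapply(affected, function(a) length(a) > 0 && w %in% a, logical(1))
    p <- pmin(pmax((cp$base_score + ifelse(hit, cp$delta, 0)) / 100, 0), 1)
    low <- stats::runif(nrow(cp)) < 0.05
    cov <- ifelse(low, stats::rpois(nrow(cp), 5), stats::rpois(nrow(cp), coverage_mean))
    cov <- pmax(cov, 1L)
    m <- stats::rbinom(nrow(cp), cov, p)
    data.frame(chrom = cp$chrom, pos = cp$pos, count_M = m,
               count_U = cov - m, stringsAsFactors = FALSE)
  })
  names(recs) <- samples$sample_id
  list(records = recs, samples = samples)
}

#' Synthetic reference tables for global TF binding classification
#'
#' A frozen, deterministic stand-in for the study's supplementary global
#' TF-binding change table and its environment classification, labelled
#' synthetic: the real tables are not bundled with the text, so this
#' generator plants per-week mean binding scores for 746 motifs such that
#' exactly 33 motifs carry a photoperiod label and 35 a salinity label
#' (30 fresh / 5 sea), mirroring the reported composition. Pairwise change
#' columns are computed from the planted scores; [classify_environment()]
#' applied to them must recover the planted labels exactly.
#'
#' @param n_motifs Motif catalogue size (default 746).
#' @param seed Fixed seed; the default defines the frozen reference.
#' @return List: `global` (wide table with per-week mean scores, bound
#'   counts and per-pair change/p columns) and `classification`
#'   (motif_id, salinity, photoperiod planted labels).
#' @export
synthetic_tf_reference <- function(n_motifs = 746L, seed = 777L) {
  set.seed(seed)
  n_sea <- 5L; n_fresh <- 30L; n_short <- 19L; n_long <- 14L
  lab_sal <- rep("none", n_motifs)
  lab_pho <- rep("none", n_motifs)
  lab_sal[seq_len(n_sea)] <- "sea"
  lab_sal[n_sea + seq_len(n_fresh)] <- "fresh"
  lab_pho[n_sea + n_fresh + seq_len(n_short)] <- "short"
  lab_pho[n_sea + n_fresh + n_short + seq_len(n_long)] <- "long"
  ord <- sample.int(n_motifs)
  lab_sal <- lab_sal[ord]; lab_pho <- lab_pho[ord]

  # per-week log2 offsets e_w on the (score + 1) scale; pairwise change
  # columns are e_B - e_A, so conjunction rules act on them exactly
  e <- matrix(stats::runif(n_motifs * 4L, -0.045, 0.045), ncol = 4L)
  bump <- function(n) stats::runif(n, 0.12, 0.6)
  i <- lab_sal == "sea"
  e[i, 4L] <- pmax(e[i, 1L], e[i, 3L]) + bump(sum(i))
  i <- lab_sal == "fresh"
  e[i, 4L] <- pmin(e[i, 1L], e[i, 3L]) - bump(sum(i))
  i <- lab_pho == "short"
  e[i, 2L] <- pmax(e[i, 1L], e[i, 3L]) + bump(sum(i))
  i <- lab_pho == "long"
  e[i, 2L] <- pmin(e[i, 1L], e[i, 3L]) - bump(sum(i))

  m0 <- stats::runif(n_motifs, 0.3, 1.2)
  scores <- (m0 + 1) * 2^e - 1
  total <- sample(50:2000, n_motifs, replace = TRUE)
  bound <- round(total * 0.3 * scores / rowMeans(scores))
  motif_id <- sprintf("SYNMOTIF%03d", seq_len(n_motifs))

  pair_idx <- list(c(1L, 2L), c(2L, 3L), c(1L, 4L), c(3L, 4L))
  wk <- .default_weeks
  global <- data.frame(motif_id = motif_id, name = motif_id, total_tfbs = total,
                       stringsAsFactors = FALSE)
  for (j in 1:4) global[[paste0("week_", wk[j], "_mean_score")]] <- scores[, j]
  for (j in 1:4) global[[paste0("week_", wk[j], "_bound")]] <- bound[, j]
  for (p in pair_idx) {
    chg <- e[, p[2L]] - e[, p[1L]]
    sig <- abs(chg) > 0.1
    pv <- ifelse(sig, stats::runif(n_motifs, 1e-6, 1e-3),
                 stats::runif(n_motifs, 0.05, 1))
    global[[paste0("week_", wk[p[1L]], "_week_", wk[p[2L]], "_change")]] <- chg
    global[[paste0("week_", wk[p[1L]], "_week_", wk[p[2L]], "_pvalue")]] <- pv
  }
  list(global = global,
       classification = data.frame(motif_id = motif_id, salinity = lab_sal,
                                   photoperiod = lab_pho, stringsAsFactors = FALSE))
}
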