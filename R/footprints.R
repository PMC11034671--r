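#' @title TF footprint occupancy
#' @description Scores the local drop in ATAC coverage at motif sites
#'   within peaks (the footprint left by a bound protein), calls
#'   bound/unbound per week from pooled-replicate coverage, aggregates
#'   genome-wide per-motif binding changes between weeks with a seeded
#'   permutation p-value, scales bound-site counts for heatmap display and
#'   classifies motifs by concordant environment response (salinity /
#'   photoperiod).
#' @name footprints
NULL

# cumulative per-base coverage per chromosome, for O(1) window means
.coverage_cumsum <- function(covdf, chrom_len) {
  out <- list()
  for (ch in unique(covdf$chrom)) {
    d <- covdf[covdf$chrom == ch, , drop = FALSE]
    v <- numeric(chrom_len)
    for (i in seq_len(nrow(d))) v[(d$start[i] + 1L):d$end[i]] <- d$value[i]
    out[[ch]] <- cumsum(v)
  }
  out
}

.window_mean <- function(cs, start, end) {
  # 0-based half-open window over a cumsum vector
  n <- length(cs)
  start <- pmax(start, 0L); end <- pmin(end, n)
  w <- end - start
  ifelse(w > 0, (cs[pmax(end, 1L)] - ifelse(start > 0L, cs[start], 0)) / w, 0)
}

#' Score footprint dips at motif sites
#'
#' For each site and week: center = mean coverage over the motif span,
#' flank = mean over `[gap, gap + flank)` windows on both sides, and
#' score = log2((flank + eps) / (center + eps)) with eps = 1. A site is
#' bound in a week when its score exceeds `bound_threshold`. Sites not
#' contained in any peak are skipped (count reported as attribute
#' `n_skipped`).
#'
#' @param coverage_by_week Named list of bedGraph data.frames (pooled
#'   replicates per week; names "week_<w>").
#' @param motif_sites Data.frame with site_id, chrom, start, end and a
#'   motif id in `name`.
#' @param peaks Data.frame with chrom, start, end (the unified peak set).
#' @param chrom_len Chromosome length (for the coverage vectors).
#' @param flank_bp Flank window width (default 20).
#' @param gap_bp Gap between motif edge and flank window (default 5).
#' @param bound_threshold Score above which a site is called bound
#'   (default 0.5, calibrated on synthetic nulls).
#' @return Long data.frame: site_id, motif_id, week, score, bound.
#' @export
score_sites <- function(coverage_by_week, motif_sites, peaks, chrom_len,
                        flank_bp = 20L, gap_bp = 5L, bound_threshold = 0.5) {
  inside <- rep(FALSE, nrow(motif_sites))
  for (ch in unique(motif_sites$chrom)) {
    si <- which(motif_sites$chrom == ch)
    pc <- peaks[peaks$chrom == ch, , drop = FALSE]
    if (!nrow(pc)) next
    hits <- IRanges::findOverlaps(
      .ir(motif_sites$start[si], motif_sites$end[si]),
      .ir(pc$start, pc$end), type = "within")
    inside[si[unique(S4Vectors::queryHits(hits))]] <- TRUE
  }
  sites <- motif_sites[inside, , drop = FALSE]
  weeks <- sub("^week_", "", names(coverage_by_week))
  if (nrow(sites) == 0L) {
    out <- data.frame(site_id = character(), motif_id = character(),
                      week = integer(), score = numeric(), bound = logical(),
                      stringsAsFactors = FALSE)
    attr(out, "n_skipped") <- sum(!inside)
    return(out)
  }
  rows <- lapply(seq_along(coverage_by_week), function(wi) {
    cs <- .coverage_cumsum(coverage_by_week[[wi]], chrom_len)
    score <- numeric(nrow(sites))
    for (ch in unique(sites$chrom)) {
      si <- which(sites$chrom == ch)
      v <- cs[[ch]]
      if (is.null(v)) v <- numeric(chrom_len)
      ctr <- .window_mean(v, sites$start[si], sites$end[si])
      lf <- .window_mean(v, sites$start[si] - gap_bp - flank_bp,
                         sites$start[si] - gap_bp)
      rf <- .window_mean(v, sites$end[si] + gap_bp,
                         sites$end[si] + gap_bp + flank_bp)
      flank <- (lf + rf) / 2
      score[si] <- log2((flank + 1) / (ctr + 1))
    }
    data.frame(site_id = sites$site_id, motif_id = sites$name,
               week = as.integer(weeks[wi]), score = score,
               bound = score > bound_threshold, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_skipped") <- sum(!inside)
  out
}

#' Genome-wide per-motif binding change between two weeks
#'
#' Per motif, change = log2((mean score in weekB + 1) / (mean score in
#' weekA + 1)); significance from a seeded paired permutation that swaps
#' each site's two week labels. Motifs with fewer than `min_sites` sites
#' are excluded (count reported as attribute `n_excluded`).
#'
#' @param site_scores Long data.frame from [score_sites()].
#' @param weekA,weekB The two weeks compared (change > 0 means more
#'   binding in weekB).
#' @param n_perm Permutations (default 1000).
#' @param seed RNG seed for the permutations.
#' @param min_sites Minimum sites per motif (default 10).
#' @return Data.frame: motif_id, week_A, week_B, n_sites, mean_score_A,
#'   mean_score_B, n_bound_A, n_bound_B, change, p.
#' @export
global_binding_change <- function(site_scores, weekA, weekB, n_perm = 1000L,
                                  seed = 1L, min_sites = 10L) {
  set.seed(seed)
  a <- site_scores[site_scores$week == weekA, ]
  b <- site_scores[site_scores$week == weekB, ]
  m <- merge(a, b, by = c("site_id", "motif_id"), suffixes = c("_A", "_B"))
  motifs <- sort(unique(m$motif_id))
  excluded <- 0L
  rows <- lapply(motifs, function(mo) {
    mm <- m[m$motif_id == mo, , drop = FALSE]
    n <- nrow(mm)
    if (n < min_sites) { excluded <<- excluded + 1L; return(NULL) }
    chg <- function(sa, sb) log2((mean(sb) + 1) / (mean(sa) + 1))
    obs <- chg(mm$score_A, mm$score_B)
    flips <- matrix(stats::runif(n_perm * n) < 0.5, nrow = n_perm)
    perm <- vapply(seq_len(n_perm), function(i) {
      f <- flips[i, ]
      chg(ifelse(f, mm$score_B, mm$score_A), ifelse(f, mm$score_A, mm$score_B))
    }, numeric(1))
    p <- (1 + sum(abs(perm) >= abs(obs))) / (n_perm + 1)
    data.frame(motif_id = mo, week_A = weekA, week_B = weekB, n_sites = n,
               mean_score_A = mean(mm$score_A), mean_score_B = mean(mm$score_B),
               n_bound_A = sum(mm$bound_A), n_bound_B = sum(mm$bound_B),
               change = obs, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(motif_id = character(), week_A = numeric(),
                      week_B = numeric(), n_sites = integer(),
                      mean_score_A = numeric(), mean_score_B = numeric(),
                      n_bound_A = integer(), n_bound_B = integer(),
                      change = numeric(), p = numeric(), stringsAsFactors = FALSE)
  }
  attr(out, "n_excluded") <- excluded
  out
}

#' Per-motif z-scaled bound-site counts across the four weeks
#'
#' @param n_bound Numeric matrix motifs x 4 weeks of bound-site counts.
#' @return Matrix of row z-scores; constant rows become all zeros.
#' @export
scale_bound_counts <- function(n_bound) {
  if (ncol(n_bound) != 4L) stop("need the 4 weeks as columns")
  mu <- rowMeans(n_bound)
  sdv <- apply(n_bound, 1L, stats::sd)
  z <- (n_bound - mu) / ifelse(sdv == 0, 1, sdv)
  z[sdv == 0, ] <- 0
  z
}

#' Classify motifs by concordant environment response
#'
#' Applies the conjunction rule on pairwise log2 binding changes: a motif
#' is "sea" when binding at week 25 exceeds both week 1 and week 19 by
#' more than the cutoff, "fresh" when it is below both; "short" when
#' binding at week 10 exceeds both week 1 and week 19, "long" when below
#' both. Salinity and photoperiod labels are assigned independently.
#'
#' @param changes Either a long data.frame (motif_id, week_A, week_B,
#'   change) or a wide table with `week_<A>_week_<B>_change` columns and a
#'   motif_id column. Change must be log2(binding in the later week B
#'   relative to the earlier week A).
#' @param change_cutoff Log2 cutoff (default 0.1).
#' @param weeks The four week labels.
#' @return Data.frame: motif_id, salinity, photoperiod, reason (NA unless
#'   a required pair was missing, which leaves the motif unclassified).
#' @export
classify_environment <- function(changes, change_cutoff = 0.1,
                                 weeks = c(1L, 10L, 19L, 25L)) {
  if (change_cutoff <= 0) stop("change_cutoff must be > 0")
  if (!all(c("week_A", "week_B", "change") %in% names(changes))) {
    wide_cols <- grep("^week_\\d+_week_\\d+_change$", names(changes), value = TRUE)
    if (!length(wide_cols)) stop("no change columns recognised")
    id_col <- intersect(c("motif_id", "name"), names(changes))[1L]
    long <- do.call(rbind, lapply(wide_cols, function(cn) {
      ww <- as.integer(regmatches(cn, gregexpr("\\d+", cn))[[1L]])
      data.frame(motif_id = changes[[id_col]], week_A = ww[1L], week_B = ww[2L],
                 change = changes[[cn]], stringsAsFactors = FALSE)
    }))
    changes <- long
  }
  get_change <- function(df, wA, wB) {
    i <- which(df$week_A == wA & df$week_B == wB)
    if (length(i)) return(df$change[i[1L]])
    j <- which(df$week_A == wB & df$week_B == wA)
    if (length(j)) return(-df$change[j[1L]])
    NA_real_
  }
  motifs <- unique(changes$motif_id)
  k <- change_cutoff
  rows <- lapply(motifs, function(mo) {
    d <- changes[changes$motif_id == mo, , drop = FALSE]
    c_1_25 <- get_change(d, weeks[1L], weeks[4L])
    c_19_25 <- get_change(d, weeks[3L], weeks[4L])
    c_1_10 <- get_change(d, weeks[1L], weeks[2L])
    c_10_19 <- get_change(d, weeks[2L], weeks[3L])
    reason <- NA_character_
    if (anyNA(c(c_1_25, c_19_25, c_1_10, c_10_19))) {
      reason <- "missing week pair"
      sal <- pho <- NA_character_
    } else {
      sal <- if (c_1_25 > k && c_19_25 > k) "sea"
             else if (c_1_25 < -k && c_19_25 < -k) "fresh" else "none"
      # week 10 vs 19 on the later-over-earlier scale: more binding at 10
      # means c_10_19 < 0
      pho <- if (c_1_10 > k && c_10_19 < -k) "short"
             else if (c_1_10 < -k && c_10_19 > k) "long" else "none"
    }
    data.frame(motif_id = mo, salinity = sal, photoperiod = pho,
               reason = reason, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
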