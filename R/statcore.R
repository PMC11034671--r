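#' @title Shared statistical kernel
#' @description Normalisation and the differential/enrichment tests every
#'   omic layer of the pipeline reuses: counts-per-million scaling, a
#'   row-vectorised one-way F test ("ANOVA-like"), a row-vectorised Welch t
#'   for pairwise contrasts, Benjamini-Hochberg adjustment, Fisher's exact
#'   test on 2x2 tables with Haldane-corrected sample odds ratios,
#'   upper-tail hypergeometric over-representation and Pearson correlation
#'   with its t-based p-value.
#' @name statcore
NULL

#' Counts-per-million normalisation
#'
#' Scales each sample (column) to one million, optionally returning
#' log2(CPM + pseudocount).
#'
#' @param counts Numeric matrix, features x samples.
#' @param log Return log2-transformed values?
#' @param pseudocount Added before log2 (default 0.5).
#' @return Matrix of the same shape.
#' @export
cpm_normalize <- function(counts, log = FALSE, pseudocount = 0.5) {
  libs <- colSums(counts)
  if (any(libs <= 0)) {
    bad <- colnames(counts)[which(libs <= 0)[1L]]
    if (is.null(bad)) bad <- which(libs <= 0)[1L]
    stop("empty library (column sum 0) for sample '", bad, "'")
  }
  cpm <- sweep(counts, 2L, 1e6 / libs, `*`)
  if (log) log2(cpm + pseudocount) else cpm
}

#' Row-wise one-way F test
#'
#' Per-feature one-way ANOVA F statistic on already-transformed values
#' (typically log2 CPM), with BH-adjusted p-values over all tested features.
#' Zero-variance features get F = 0 and p = 1 by convention, which keeps the
#' BH denominator stable.
#'
#' @param values Numeric matrix, features x samples.
#' @param groups Group label per column.
#' @return Data.frame: `feature_id`, `F`, `p`, `FDR`, plus per-group means.
#' @export
anova_like_test <- function(values, groups) {
  groups <- as.character(groups)
  stopifnot(ncol(values) == length(groups))
  lv <- unique(groups)
  k <- length(lv)
  if (k < 2L) stop("need >= 2 groups")
  n_per <- table(factor(groups, levels = lv))
  N <- ncol(values)
  if (N - k <= 0L) stop("no within-group degrees of freedom (all groups singleton)")
  gm <- sapply(lv, function(g) rowMeans(values[, groups == g, drop = FALSE]))
  if (is.null(dim(gm))) gm <- matrix(gm, nrow = 1, dimnames = list(NULL, lv))
  overall <- rowMeans(values)
  # sum_g n_g (m_g - m)^2 = sum_g n_g m_g^2 - N m^2
  ssb <- as.vector(gm^2 %*% as.numeric(n_per)) - N * overall^2
  sst <- rowSums(values^2) - N * overall^2
  ssw <- pmax(sst - ssb, 0)
  df1 <- k - 1L
  df2 <- N - k
  Fstat <- (ssb / df1) / (ssw / df2)
  p <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  degenerate <- sst < 1e-12
  Fstat[degenerate] <- 0
  p[degenerate] <- 1
  # ssw == 0 with ssb > 0: infinite F, p -> 0
  p[!degenerate & ssw < 1e-12] <- 0
  Fstat[!degenerate & ssw < 1e-12] <- Inf
  ids <- rownames(values)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(values)))
  out <- data.frame(feature_id = ids, F = Fstat, p = p,
                    FDR = bh_adjust(p), stringsAsFactors = FALSE)
  colnames(gm) <- paste0("mean_", lv)
  cbind(out, gm)
}

#' Row-wise Welch two-sample t test
#'
#' Per-feature Welch t on transformed values; `logFC` is mean(A) - mean(B)
#' on the scale supplied (log2 for log2-CPM input).
#'
#' @param values Numeric matrix, features x samples.
#' @param idxA,idxB Column indices (or logical masks) of the two groups.
#' @return Data.frame: `feature_id`, `logFC`, `mean_expr`, `t`, `p`, `FDR`.
#' @export
pairwise_test <- function(values, idxA, idxB) {
  A <- values[, idxA, drop = FALSE]
  B <- values[, idxB, drop = FALSE]
  nA <- ncol(A); nB <- ncol(B)
  if (nA == 0L || nB == 0L) stop("both groups must be non-empty")
  if (nA < 2L || nB < 2L) stop("Welch t requires >= 2 observations per group")
  mA <- rowMeans(A); mB <- rowMeans(B)
  vA <- rowSums((A - mA)^2) / (nA - 1L)
  vB <- rowSums((B - mB)^2) / (nB - 1L)
  se2 <- vA / nA + vB / nB
  tstat <- (mA - mB) / sqrt(se2)
  df <- se2^2 / ((vA / nA)^2 / (nA - 1L) + (vB / nB)^2 / (nB - 1L))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  degenerate <- se2 < 1e-24
  tstat[degenerate] <- 0
  p[degenerate] <- 1
  ids <- rownames(values)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(values)))
  data.frame(feature_id = ids, logFC = mA - mB, mean_expr = (mA + mB) / 2,
             t = tstat, p = p, FDR = bh_adjust(p), stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH with monotonicity, order-preserving; NaN/NA p-values propagate
#' and are excluded from the number of tests.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return Vector of adjusted p-values in input order.
#' @export
bh_adjust <- function(pvals) {
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1)) stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(pvals))
  out[ok] <- stats::p.adjust(pvals[ok], method = "BH")
  out
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p by the conventional sum of hypergeometric probabilities no
#' larger than the observed table's. The odds ratio reported is the sample
#' OR (a*d)/(b*c), with a 0.5 Haldane correction to every cell when any cell
#' is zero. A zero margin yields p = 1 and an undefined-OR flag.
#'
#' @param table 2x2 matrix (or length-4 vector, row-wise a, b, c, d) of
#'   non-negative integer counts.
#' @return List of class `contingency2x2`: `a`, `b`, `c`, `d`,
#'   `odds_ratio`, `haldane`, `or_undefined`, `p`.
#' @export
fisher_exact_2x2 <- function(table) {
  x <- as.vector(t(as.matrix(table)))
  if (length(x) != 4L) stop("need a 2x2 table")
  if (any(x < 0) || any(x != round(x))) stop("counts must be non-negative integers")
  a <- x[1L]; b <- x[2L]; cc <- x[3L]; d <- x[4L]
  zero_margin <- (a + b == 0) || (cc + d == 0) || (a + cc == 0) || (b + d == 0)
  if (zero_margin) {
    return(structure(list(a = a, b = b, c = cc, d = d, odds_ratio = NA_real_,
                          haldane = FALSE, or_undefined = TRUE, p = 1),
                     class = "contingency2x2"))
  }
  haldane <- any(x == 0)
  h <- if (haldane) 0.5 else 0
  or <- ((a + h) * (d + h)) / ((b + h) * (cc + h))
  p <- stats::fisher.test(matrix(c(a, cc, b, d), 2L))$p.value
  structure(list(a = a, b = b, c = cc, d = d, odds_ratio = or,
                 haldane = haldane, or_undefined = FALSE, p = min(p, 1)),
            class = "contingency2x2")
}

#' @export
print.contingency2x2 <- function(x, ...) {
  cat(sprintf("2x2 [%d %d; %d %d]  OR = %s  p = %.4g\n", x$a, x$b, x$c, x$d,
              if (x$or_undefined) "undef" else format(x$odds_ratio, digits = 4), x$p))
  invisible(x)
}

#' Upper-tail hypergeometric over-representation p-value
#'
#' P(X >= k) for k hits in a drawn set of size n, when K of the N universe
#' genes are in the category.
#'
#' @param k Hits in the set.
#' @param n Set size.
#' @param K Hits in the universe.
#' @param N Universe size.
#' @return The upper-tail p-value.
#' @export
hypergeom_ora <- function(k, n, K, N) {
  if (k > min(n, K) || n > N || K > N || k < 0) {
    stop("violated bounds: need 0 <= k <= min(n, K) and n, K <= N")
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Pearson correlation with two-sided p-value
#'
#' p from t = r * sqrt((n - 2) / (1 - r^2)) on n - 2 df. Zero variance in
#' either vector returns an undefined-r flag rather than an error, so callers
#' can exclude such pairs and count them.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return List: `r`, `p`, `n`, `undefined`.
#' @export
pearson_with_p <- function(x, y) {
  n <- length(x)
  if (length(y) != n || n < 3L) stop("need equal-length vectors of length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = n, undefined = TRUE))
  }
  r <- stats::cor(x, y)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE)
  }
  list(r = r, p = p, n = n, undefined = FALSE)
}
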