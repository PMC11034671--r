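#' @title Genomic file formats
#' @description Readers and writers for the plain-text formats the pipeline
#'   touches: BED3/BED6, bedGraph, GTF-lite gene models, Bismark coverage and
#'   counts TSV. All internal coordinates are 0-based half-open; on-disk BED
#'   and bedGraph are 0-based half-open, on-disk GTF is 1-based closed and
#'   Bismark coverage is 1-based with start == end. Gzipped files are read
#'   transparently.
#' @name formats
NULL

.valid_strands <- c("+", "-", ".")

#' Read a BED3-BED6 file
#'
#' Missing optional columns are defaulted (name ".", score 0, strand ".").
#' Coordinates are kept 0-based half-open as on disk.
#'
#' @param path Path to a tab-separated BED file (may be gzipped).
#' @return A data.frame with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), score = numeric(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < 3L)) {
    stop("BED line ", which(ncol < 3L)[1L], ": fewer than 3 columns")
  }
  get <- function(i, default) {
    vapply(fields, function(f) if (length(f) >= i) f[i] else default, character(1))
  }
  start <- suppressWarnings(as.integer(get(2L, NA_character_)))
  end   <- suppressWarnings(as.integer(get(3L, NA_character_)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) stop("BED line ", bad[1L], ": non-integer coordinates")
  bad <- which(start >= end)
  if (length(bad)) {
    stop("BED line ", bad[1L], ": empty or inverted interval (start >= end)")
  }
  bad <- which(start < 0L)
  if (length(bad)) stop("BED line ", bad[1L], ": negative start")
  strand <- get(6L, ".")
  bad <- which(!strand %in% .valid_strands)
  if (length(bad)) {
    stop("BED line ", bad[1L], ": unknown strand symbol '", strand[bad[1L]], "'")
  }
  score <- suppressWarnings(as.numeric(get(5L, "0")))
  score[is.na(score)] <- 0
  data.frame(chrom = get(1L, NA_character_), start = start, end = end,
             name = get(4L, "."), score = score, strand = strand,
             stringsAsFactors = FALSE)
}

#' Write intervals as BED6
#'
#' @param intervals Data.frame with at least `chrom`, `start`, `end`;
#'   `name`/`score`/`strand` defaulted when absent.
#' @param path Output path.
#' @export
write_bed <- function(intervals, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  n <- nrow(intervals)
  name <- if ("name" %in% names(intervals)) intervals$name else rep(".", n)
  score <- if ("score" %in% names(intervals)) intervals$score else rep(0, n)
  strand <- if ("strand" %in% names(intervals)) intervals$strand else rep(".", n)
  out <- paste(intervals$chrom, format(intervals$start, scientific = FALSE, trim = TRUE),
               format(intervals$end, scientific = FALSE, trim = TRUE),
               name, score, strand, sep = "\t")
  writeLines(out, path)
  invisible(path)
}

#' Read a bedGraph coverage track
#'
#' @param path Path to a 4-column bedGraph (chrom, start, end, value),
#'   0-based half-open.
#' @return Data.frame with columns `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "value"),
                          colClasses = c("character", "integer", "integer", "numeric"))
  if (any(df$start >= df$end)) stop("bedGraph: start >= end on line ",
                                    which(df$start >= df$end)[1L])
  df
}

#' Write a bedGraph coverage track
#'
#' Adjacent rows with equal value on the same chromosome are run-length
#' merged; zero-valued rows are dropped.
#'
#' @param df Data.frame with `chrom`, `start`, `end`, `value`.
#' @param path Output path.
#' @export
write_bedgraph <- function(df, path) {
  df <- df[df$value != 0, , drop = FALSE]
  if (nrow(df) > 1L) {
    df <- df[order(df$chrom, df$start), , drop = FALSE]
    same <- c(FALSE, df$chrom[-1L] == df$chrom[-nrow(df)] &
                df$start[-1L] == df$end[-nrow(df)] &
                df$value[-1L] == df$value[-nrow(df)])
    grp <- cumsum(!same)
    df <- data.frame(chrom = df$chrom[!same],
                     start = df$start[!same],
                     end = tapply(df$end, grp, function(x) x[length(x)]),
                     value = df$value[!same], stringsAsFactors = FALSE)
  }
  out <- paste(df$chrom, format(df$start, scientific = FALSE, trim = TRUE),
               format(df$end, scientific = FALSE, trim = TRUE),
               format(df$value, scientific = FALSE, trim = TRUE), sep = "\t")
  writeLines(out, path)
  invisible(path)
}

#' Read a Bismark coverage file
#'
#' Positions are 1-based with start == end (the extractor's dialect). The
#' percent-methylation field is advisory: it is recomputed from the counts
#' and, if it disagrees by more than 0.1, a warning is raised and the
#' recomputed value wins.
#'
#' @param path Path to a 6-column coverage file: chrom, start, end,
#'   percent_methylation, count_methylated, count_unmethylated.
#' @return Data.frame with `chrom`, `pos` (1-based), `count_M`, `count_U`,
#'   `score` (percent methylation from counts).
#' @export
read_bismark_coverage <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "percent",
                                        "count_M", "count_U"),
                          colClasses = c("character", "integer", "integer",
                                         "numeric", "integer", "integer"))
  cov <- df$count_M + df$count_U
  if (any(cov == 0L)) {
    stop("Bismark coverage: zero-coverage record at line ", which(cov == 0L)[1L])
  }
  if (any(df$count_M < 0L | df$count_U < 0L)) stop("Bismark coverage: negative count")
  score <- 100 * df$count_M / cov
  off <- abs(score - df$percent) > 0.1
  if (any(off)) {
    warning(sum(off), " record(s) with percent field differing from counts by >0.1; ",
            "recomputed values used")
  }
  data.frame(chrom = df$chrom, pos = df$start, count_M = df$count_M,
             count_U = df$count_U, score = score, stringsAsFactors = FALSE)
}

#' Write CpG records in Bismark coverage format
#'
#' @param records Data.frame with `chrom`, `pos`, `count_M`, `count_U`.
#' @param path Output path.
#' @export
write_bismark_coverage <- function(records, path) {
  score <- 100 * records$count_M / (records$count_M + records$count_U)
  out <- paste(records$chrom, records$pos, records$pos,
               format(score, scientific = FALSE, trim = TRUE),
               records$count_M, records$count_U, sep = "\t")
  writeLines(out, path)
  invisible(path)
}

#' Construct a genome annotation object
#'
#' @param genes Data.frame with `gene_id`, `chrom`, `strand`, `start`, `end`
#'   (0-based half-open gene body).
#' @param exons Data.frame with `gene_id`, `chrom`, `start`, `end`.
#' @return A `genome_annotation`: genes gain a `tss` column (gene start on
#'   the + strand, end - 1 on the - strand).
#' @export
genome_annotation <- function(genes, exons) {
  stopifnot(all(c("gene_id", "chrom", "strand", "start", "end") %in% names(genes)))
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  if (nrow(exons)) {
    m <- match(exons$gene_id, genes$gene_id)
    if (anyNA(m)) stop("exon references unknown gene_id '",
                       exons$gene_id[which(is.na(m))[1L]], "'")
    out <- exons$start < genes$start[m] | exons$end > genes$end[m]
    if (any(out)) stop("exon outside its gene body for gene_id '",
                       exons$gene_id[which(out)[1L]], "'")
  }
  structure(list(genes = genes, exons = exons), class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:", nrow(x$genes), "genes,", nrow(x$exons),
      "exons on", length(unique(x$genes$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' Write an annotation as GTF-lite
#'
#' Emits gene and exon features with a `gene_id` attribute, converting the
#' internal 0-based half-open coordinates to 1-based closed GTF.
#'
#' @param annotation A `genome_annotation`.
#' @param path Output path.
#' @export
write_gtf_lite <- function(annotation, path) {
  g <- annotation$genes
  e <- annotation$exons
  fmt <- function(chrom, feature, start, end, strand, gene_id) {
    if (length(chrom) == 0L) return(character(0))
    paste(chrom, "smoltomics", feature, start + 1L, end, ".", strand, ".",
          paste0('gene_id "', gene_id, '";'), sep = "\t")
  }
  lines <- fmt(g$chrom, "gene", g$start, g$end, g$strand, g$gene_id)
  if (nrow(e)) {
    strand <- g$strand[match(e$gene_id, g$gene_id)]
    lines <- c(lines, fmt(e$chrom, "exon", e$start, e$end, strand, e$gene_id))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a GTF-lite annotation
#'
#' Accepts gene/exon features with a `gene_id` attribute and converts 1-based
#' closed GTF coordinates to the internal 0-based half-open convention.
#'
#' @param path Path to a GTF-lite file.
#' @return A `genome_annotation`.
#' @export
read_gtf_lite <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(genome_annotation(
      data.frame(gene_id = character(), chrom = character(), strand = character(),
                 start = integer(), end = integer(), stringsAsFactors = FALSE),
      data.frame(gene_id = character(), chrom = character(),
                 start = integer(), end = integer(), stringsAsFactors = FALSE)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 9L)) {
    stop("GTF line ", which(lengths(fields) < 9L)[1L], ": fewer than 9 columns")
  }
  col <- function(i) vapply(fields, `[[`, character(1), i)
  feature <- col(3L)
  keep <- feature %in% c("gene", "exon")
  gene_id <- sub('.*gene_id "([^"]+)".*', "\\1", col(9L))
  start <- as.integer(col(4L)) - 1L
  end <- as.integer(col(5L))
  df <- data.frame(gene_id = gene_id, chrom = col(1L), strand = col(7L),
                   start = start, end = end, feature = feature,
                   stringsAsFactors = FALSE)[keep, , drop = FALSE]
  genes <- df[df$feature == "gene", c("gene_id", "chrom", "strand", "start", "end")]
  exons <- df[df$feature == "exon", c("gene_id", "chrom", "start", "end")]
  rownames(genes) <- rownames(exons) <- NULL
  genome_annotation(genes, exons)
}

#' Write a TSS table (gene_id, chrom, tss, strand) as TSV
#' @param annotation A `genome_annotation`.
#' @param path Output path.
#' @export
write_tss_tsv <- function(annotation, path) {
  g <- annotation$genes
  utils::write.table(g[, c("gene_id", "chrom", "tss", "strand")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a counts matrix as TSV (gene_id column + one column per sample)
#' @param counts Integer matrix, rownames = feature ids.
#' @param path Output path.
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a counts matrix from TSV
#' @param path Path written by [write_counts_tsv()].
#' @return Integer matrix with feature rownames.
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}
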