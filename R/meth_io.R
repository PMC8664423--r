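#' @importFrom stats median mad sd var cor pnorm pt pbinom rpois rbinom rbeta
#'   rnorm runif rexp phyper hclust cutree as.dist t.test anova lm
#'   complete.cases quantile setNames aggregate
#' @importFrom utils read.table write.table
NULL

# ---- MethylationMatrix container ---------------------------------------

#' Construct a methylation count matrix
#'
#' The central container of the package: CpG sites (rows) by samples
#' (columns), each cell holding a pair of read counts (methylated, total).
#' Sites are sorted by (chrom, pos); cells where a site was not observed in
#' a sample are `NA` in both count matrices.
#'
#' @param chrom character vector of chromosome names, one per site.
#' @param pos integer vector of 0-based CpG cytosine positions
#'   (forward strand).
#' @param meth integer matrix (sites x samples) of methylated read counts.
#' @param total integer matrix (sites x samples) of total read counts.
#' @param samples character vector of sample identifiers (column names).
#' @return An object of class `meth_matrix`.
#' @export
meth_matrix <- function(chrom, pos, meth, total, samples) {
  stopifnot(length(chrom) == length(pos),
            nrow(meth) == length(pos), nrow(total) == length(pos),
            ncol(meth) == length(samples), ncol(total) == length(samples))
  if (anyNA(pos) || any(pos < 0)) stop("positions must be non-negative")
  bad <- !is.na(meth) & !is.na(total) & (meth > total | meth < 0)
  if (any(bad)) stop("n_meth must lie in [0, n_total] for every cell")
  if (any(is.na(meth) != is.na(total)))
    stop("meth and total must share the same missingness pattern")
  o <- order(chrom, pos)
  chrom <- chrom[o]; pos <- pos[o]
  meth <- meth[o, , drop = FALSE]; total <- total[o, , drop = FALSE]
  if (anyDuplicated(paste(chrom, pos)))
    stop("duplicate (chrom, pos) site")
  dimnames(meth) <- dimnames(total) <- list(NULL, samples)
  structure(list(chrom = as.character(chrom), pos = as.integer(pos),
                 meth = meth, total = total,
                 samples = as.character(samples)),
            class = "meth_matrix")
}

#' @export
print.meth_matrix <- function(x, ...) {
  cat(sprintf("meth_matrix: %d CpG sites x %d samples (%d chromosome(s))\n",
              length(x$pos), length(x$samples), length(unique(x$chrom))))
  invisible(x)
}

#' Number of sites / samples of a methylation matrix
#' @param m a `meth_matrix`.
#' @return integer count.
#' @export
n_sites <- function(m) length(m$pos)

#' @rdname n_sites
#' @export
n_samples <- function(m) length(m$samples)

# ---- bedGraph ingestion -------------------------------------------------

#' Read a per-sample CpG count table (MethylDackel-style bedGraph)
#'
#' Parses `chrom start end [pct] n_meth n_unmeth` rows.  Positions are the
#' 0-based `start` column.  Lines beginning with `track` or `#` are skipped.
#'
#' @param path file path.
#' @param dialect `"percent+counts"` (6 columns, MethylDackel default) or
#'   `"counts"` (5 columns without the percentage).
#' @return data.frame with columns chrom, pos, n_meth, n_total, ordered as
#'   in the file.
#' @export
read_site_counts <- function(path, dialect = c("percent+counts", "counts")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(track|#)", lines) & nzchar(lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L)
    return(data.frame(chrom = character(), pos = integer(),
                      n_meth = integer(), n_total = integer()))
  fields <- strsplit(lines, "[ \t]+")
  need <- if (dialect == "percent+counts") 6L else 5L
  nf <- lengths(fields)
  if (any(nf < need))
    stop(sprintf("malformed row at line %d: expected %d fields, got %d",
                 lineno[which(nf < need)[1]], need, nf[which(nf < need)[1]]))
  mat <- do.call(rbind, fields)
  ic <- if (dialect == "percent+counts") c(5L, 6L) else c(4L, 5L)
  n_meth <- suppressWarnings(as.integer(mat[, ic[1]]))
  n_unmeth <- suppressWarnings(as.integer(mat[, ic[2]]))
  pos <- suppressWarnings(as.integer(mat[, 2]))
  bad <- which(is.na(n_meth) | is.na(n_unmeth) | is.na(pos))
  if (length(bad))
    stop(sprintf("malformed row at line %d: non-numeric field", lineno[bad[1]]))
  if (any(n_meth < 0 | n_unmeth < 0))
    stop("negative read count encountered")
  data.frame(chrom = mat[, 1], pos = pos,
             n_meth = n_meth, n_total = n_meth + n_unmeth)
}

#' Write a per-sample count table in MethylDackel bedGraph dialect
#'
#' @param counts data.frame as returned by [read_site_counts()].
#' @param path output path.
#' @export
write_site_counts <- function(counts, path) {
  pct <- ifelse(counts$n_total > 0,
                100 * counts$n_meth / counts$n_total, 0)
  df <- data.frame(counts$chrom, counts$pos, counts$pos + 1L,
                   sprintf("%.6g", pct),
                   counts$n_meth, counts$n_total - counts$n_meth)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' Tab-separated file with header columns `sample_id, group, tissue, family,
#' length_mm, weight_g` (phenotype columns optional).
#'
#' @param path file path.
#' @return data.frame of sample metadata.
#' @export
read_sample_meta <- function(path) {
  meta <- read.table(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
  req <- c("sample_id", "group", "tissue")
  miss <- setdiff(req, names(meta))
  if (length(miss)) stop("metadata missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(!nzchar(meta$group)) || any(!nzchar(meta$tissue)))
    stop("group and tissue must be non-empty")
  meta
}

#' Assemble a multi-sample methylation matrix
#'
#' Takes the union of sites across samples; a site absent from a sample's
#' table becomes a missing (`NA`) cell, which is distinct from an observed
#' zero-coverage site.
#'
#' @param tables named list of per-sample count data.frames
#'   (chrom, pos, n_meth, n_total).
#' @param meta sample metadata data.frame containing every sample id.
#' @return a [meth_matrix()].
#' @export
build_matrix <- function(tables, meta = NULL) {
  if (length(tables) == 0L) stop("no sample tables supplied")
  ids <- names(tables)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("tables must be a named list keyed by sample id")
  if (!is.null(meta)) {
    missing_meta <- setdiff(ids, meta$sample_id)
    if (length(missing_meta))
      stop("samples absent from metadata: ",
           paste(missing_meta, collapse = ", "))
  }
  for (id in ids) {
    tb <- tables[[id]]
    if (anyDuplicated(paste(tb$chrom, tb$pos)))
      stop("duplicate (chrom, pos) within sample ", id)
  }
  keys <- unique(do.call(rbind, lapply(tables, function(tb)
    data.frame(chrom = as.character(tb$chrom), pos = tb$pos))))
  keys <- keys[order(keys$chrom, keys$pos), , drop = FALSE]
  key_id <- paste(keys$chrom, keys$pos)
  n <- nrow(keys); m <- length(ids)
  meth <- matrix(NA_integer_, n, m)
  total <- matrix(NA_integer_, n, m)
  for (j in seq_along(ids)) {
    tb <- tables[[ids[j]]]
    idx <- match(paste(tb$chrom, tb$pos), key_id)
    meth[idx, j] <- tb$n_meth
    total[idx, j] <- tb$n_total
  }
  meth_matrix(keys$chrom, keys$pos, meth, total, ids)
}

# ---- interval helpers ---------------------------------------------------

#' Convert 0-based half-open intervals to a GRanges
#'
#' @param df data.frame with chrom, start, end (0-based half-open) and
#'   optionally name/strand.
#' @return a `GRanges` (1-based closed, as GenomicRanges requires).
#' @export
intervals_to_granges <- function(df) {
  if (nrow(df) > 0 && any(df$start >= df$end))
    stop("invalid interval: start must be < end")
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end))
}

#' Read a BED file of intervals
#'
#' @param path BED path (0-based half-open; at least 3 columns).
#' @return data.frame with chrom, start, end, and name if present.
#' @export
read_bed <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE, fill = TRUE)
  if (ncol(df) < 3) stop("BED file needs at least 3 columns")
  std <- c("chrom", "start", "end", "name", "score", "strand")
  k <- min(ncol(df), length(std))
  names(df)[seq_len(k)] <- std[seq_len(k)]
  df
}

#' Remove CpG sites overlapping variant intervals
#'
#' Sites whose cytosine position falls inside any supplied interval (for
#' instance C-T or A-G polymorphisms that confound bisulfite methylation
#' calls) are dropped from the matrix.
#'
#' @param m a [meth_matrix()].
#' @param variants data.frame of 0-based half-open intervals
#'   (chrom, start, end).
#' @return the filtered `meth_matrix`.
#' @export
mask_variant_sites <- function(m, variants) {
  if (is.null(variants) || nrow(variants) == 0L) return(m)
  sites <- GenomicRanges::GRanges(
    m$chrom, IRanges::IRanges(m$pos + 1L, m$pos + 1L))
  vr <- intervals_to_granges(variants)
  hit <- IRanges::overlapsAny(sites, vr)
  subset_sites(m, !hit)
}

subset_sites <- function(m, keep) {
  structure(list(chrom = m$chrom[keep], pos = m$pos[keep],
                 meth = m$meth[keep, , drop = FALSE],
                 total = m$total[keep, , drop = FALSE],
                 samples = m$samples),
            class = "meth_matrix")
}

#' Site-level coverage and contig filters
#'
#' Retains CpG sites that (a) lie on contigs of at least `min_contig_len`
#' (or on whitelisted chromosomes), (b) are covered by at least one read in
#' every sample, and (c) have coverage within `[min_cov, max_cov]` in at
#' least `ceiling(min_frac_samples * n_samples)` samples.  Missing cells
#' count as zero coverage for rule (b).
#'
#' @param m a [meth_matrix()].
#' @param min_cov,max_cov per-sample coverage window (reads).
#' @param min_frac_samples fraction of samples that must satisfy the
#'   coverage window (0 < f <= 1).
#' @param chrom_lengths named numeric vector of contig lengths covering
#'   every chromosome present.
#' @param min_contig_len minimum contig length in bp.
#' @param whitelist chromosomes kept regardless of length.
#' @return the filtered `meth_matrix`.
#' @export
filter_sites <- function(m, min_cov = 5L, max_cov = 20L,
                         min_frac_samples = 0.75,
                         chrom_lengths = NULL, min_contig_len = 10000L,
                         whitelist = character()) {
  if (!(min_frac_samples > 0 && min_frac_samples <= 1))
    stop("min_frac_samples must be in (0, 1]")
  stopifnot(min_cov > 0, min_cov <= max_cov)
  keep <- rep(TRUE, n_sites(m))
  if (!is.null(chrom_lengths)) {
    miss <- setdiff(unique(m$chrom), names(chrom_lengths))
    if (length(miss)) stop("chrom_lengths missing: ",
                           paste(miss, collapse = ", "))
    ok_chrom <- names(chrom_lengths)[chrom_lengths >= min_contig_len]
    keep <- keep & (m$chrom %in% ok_chrom | m$chrom %in% whitelist)
  }
  tot <- m$total
  tot0 <- tot; tot0[is.na(tot0)] <- 0L
  keep <- keep & (rowSums(tot0 >= 1L) == ncol(tot0))
  need <- ceiling(min_frac_samples * n_samples(m))
  inwin <- (tot0 >= min_cov) & (tot0 <= max_cov)
  keep <- keep & (rowSums(inwin) >= need)
  subset_sites(m, keep)
}

#' Write regions as sorted BED
#'
#' @param regions data.frame with chrom, start, end (0-based half-open) and
#'   optional name/score/strand/extra columns.
#' @param path output path.
#' @export
write_regions_bed <- function(regions, path) {
  if (nrow(regions) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  if (any(regions$start >= regions$end)) stop("invalid interval in regions")
  o <- order(regions$chrom, regions$start, regions$end)
  regions <- regions[o, , drop = FALSE]
  if (is.null(regions$name))
    regions$name <- sprintf("region_%d", seq_len(nrow(regions)))
  if (is.null(regions$score)) regions$score <- 0
  if (is.null(regions$strand)) regions$strand <- "."
  core <- c("chrom", "start", "end", "name", "score", "strand")
  extra <- setdiff(names(regions), core)
  write.table(regions[, c(core, extra)], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
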