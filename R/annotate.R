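# Proximity-based gene annotation of regions and Fisher (hypergeometric)
# functional enrichment.

#' Read a minimal gene annotation table
#'
#' BED-like TSV with columns gene_id, chrom, start, end and optional
#' strand (0-based half-open).  Plain BED (chrom, start, end, name) is also
#' accepted and reshuffled into this layout.
#'
#' @param path file path.
#' @param format `"tsv"` (gene_id first) or `"bed"` (name in column 4).
#' @return data.frame with gene_id, chrom, start, end, strand.
#' @export
read_genes <- function(path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE)
  if (format == "bed") {
    out <- data.frame(gene_id = df[[4]], chrom = df[[1]],
                      start = df[[2]], end = df[[3]],
                      strand = if (ncol(df) >= 6) df[[6]] else ".")
  } else {
    out <- data.frame(gene_id = df[[1]], chrom = df[[2]],
                      start = df[[3]], end = df[[4]],
                      strand = if (ncol(df) >= 5) df[[5]] else ".")
  }
  if (any(out$start >= out$end)) stop("invalid gene interval")
  out
}

#' Read a gene-to-term mapping
#'
#' Two-column TSV: gene_id, term_id (one pair per row).
#'
#' @param path file path.
#' @return named list mapping gene_id to a character vector of term ids.
#' @export
read_gene2go <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE,
                   col.names = c("gene_id", "term_id"))
  split(df$term_id, df$gene_id)
}

#' Assign genes to regions by proximity
#'
#' A gene is assigned to a region when the gap between the two intervals is
#' at most `flank_bp` (0 for overlapping or abutting intervals); strand is
#' ignored.
#'
#' @param regions data.frame of regions (chrom, start, end; 0-based
#'   half-open).
#' @param genes data.frame from [read_genes()].
#' @param flank_bp maximum gap in bp (default 5000).
#' @return list, one character vector of gene_ids per region (may be
#'   empty), named by region index.
#' @export
assign_genes_to_regions <- function(regions, genes, flank_bp = 5000L) {
  res <- rep(list(character()), nrow(regions))
  names(res) <- rownames(regions)
  if (nrow(regions) == 0L || nrow(genes) == 0L) return(res)
  gr <- intervals_to_granges(regions)
  gg <- intervals_to_granges(genes)
  h <- suppressWarnings(
    GenomicRanges::findOverlaps(gr, gg, maxgap = flank_bp))
  qh <- S4Vectors::queryHits(h); sh <- S4Vectors::subjectHits(h)
  for (i in unique(qh))
    res[[i]] <- unique(genes$gene_id[sh[qh == i]])
  res
}

#' Interval gap in bp (0 when overlapping or abutting)
#'
#' Helper with half-open semantics used by the assignment rule; exported
#' for verification.
#'
#' @param s1,e1,s2,e2 starts and ends of the two intervals (0-based
#'   half-open), vectorized.
#' @return non-negative gap in bp.
#' @export
interval_gap <- function(s1, e1, s2, e2) {
  pmax(0L, pmax(s1 - e2, s2 - e1))
}

#' One-sided Fisher (hypergeometric) over-representation per term
#'
#' For every term carried by at least one study gene, tests whether the
#' study set is enriched for the term relative to the universe using the
#' hypergeometric upper tail (equivalent to a one-sided Fisher exact test
#' on the 2x2 table).
#'
#' @param study_genes character vector (subset of universe).
#' @param universe_genes character vector of all background genes.
#' @param gene2go named list mapping gene_id to term ids.
#' @return data.frame: term_id, k_sig, n_sig, K_bg, N_bg, p, fdr (BH
#'   column provided for convenience; the primary statistic is the raw p).
#' @export
go_fisher_enrichment <- function(study_genes, universe_genes, gene2go) {
  study_genes <- unique(study_genes)
  universe_genes <- unique(universe_genes)
  if (!all(study_genes %in% universe_genes))
    stop("study set must be a subset of the universe")
  empty <- data.frame(term_id = character(), k_sig = integer(),
                      n_sig = integer(), K_bg = integer(),
                      N_bg = integer(), p = numeric(), fdr = numeric())
  if (length(study_genes) == 0L) return(empty)
  g2g <- gene2go[intersect(names(gene2go), universe_genes)]
  term_by_gene <- data.frame(
    gene = rep(names(g2g), lengths(g2g)),
    term = unlist(g2g, use.names = FALSE))
  if (nrow(term_by_gene) == 0L) return(empty)
  K_bg <- table(unique(term_by_gene)$term)
  study_tb <- unique(term_by_gene[term_by_gene$gene %in% study_genes, ])
  if (nrow(study_tb) == 0L) return(empty)
  k_sig <- table(study_tb$term)
  terms <- names(k_sig)
  n_sig <- length(study_genes)
  N_bg <- length(universe_genes)
  k <- as.integer(k_sig[terms])
  K <- as.integer(K_bg[terms])
  p <- phyper(k - 1, K, N_bg - K, n_sig, lower.tail = FALSE)
  out <- data.frame(term_id = terms, k_sig = k, n_sig = n_sig,
                    K_bg = K, N_bg = N_bg, p = p, fdr = bh_fdr(p))
  out <- out[order(out$p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
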