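# Aggregation of significant CpGs into differentially methylated regions,
# direction-bias statistics and interval-overlap permutation tests.

#' Call differentially methylated regions from per-CpG test results
#'
#' Significant CpGs (p < `p_threshold`) are clustered when consecutive
#' significant sites lie within `merge_gap_bp` of each other; the candidate
#' region spans the first to the last significant member CpG (+1,
#' half-open), with all tested CpGs inside that span as members.  A region
#' is emitted when it is at least `min_len` bp long, has at least `min_cpg`
#' member CpGs, and more than `pct_sig` of its member CpGs are significant.
#' Direction is relative to group 1: `hypo` when the mean member difference
#' is negative (ties broken toward `hyper`).
#'
#' @param dmcs data.frame from [dmc_test()] (chrom, pos, diff, pval).
#' @param p_threshold per-CpG significance threshold.
#' @param min_len minimum region length in bp.
#' @param min_cpg minimum member CpG count.
#' @param pct_sig minimum (strict) fraction of significant member CpGs.
#' @param merge_gap_bp maximum gap between consecutive significant CpGs.
#' @return data.frame of DMRs: chrom, start, end, n_cpg, length_bp,
#'   mean_diff, direction, frac_sig.
#' @export
call_dmrs <- function(dmcs, p_threshold = 0.001, min_len = 50L,
                      min_cpg = 4L, pct_sig = 0.5, merge_gap_bp = 100L) {
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), n_cpg = integer(),
                      length_bp = integer(), mean_diff = numeric(),
                      direction = character(), frac_sig = numeric())
  if (nrow(dmcs) == 0L) return(empty)
  o <- order(dmcs$chrom, dmcs$pos)
  dmcs <- dmcs[o, , drop = FALSE]
  out <- list()
  for (ch in unique(dmcs$chrom)) {
    d <- dmcs[dmcs$chrom == ch, , drop = FALSE]
    sig <- which(d$pval < p_threshold)
    if (length(sig) == 0L) next
    gap_break <- c(TRUE, diff(d$pos[sig]) > merge_gap_bp)
    cl <- cumsum(gap_break)
    for (g in unique(cl)) {
      s <- sig[cl == g]
      span <- c(d$pos[s[1]], d$pos[s[length(s)]] + 1L)
      member <- which(d$pos >= span[1] & d$pos < span[2])
      n_cpg <- length(member)
      len <- span[2] - span[1]
      frac_sig <- length(s) / n_cpg
      if (len < min_len || n_cpg < min_cpg || frac_sig <= pct_sig) next
      mean_diff <- mean(d$diff[member])
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = span[1], end = span[2],
        n_cpg = n_cpg, length_bp = len, mean_diff = mean_diff,
        direction = if (mean_diff < 0) "hypo" else "hyper",
        frac_sig = frac_sig)
    }
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Exact two-sided binomial test for direction bias
#'
#' Tests whether hypo- and hyper-methylated regions occur equally often
#' (p0 = 0.5) by doubling the smaller exact tail, capped at 1.
#'
#' @param n_hypo number of hypo-methylated regions.
#' @param n_total total region count (>= 1).
#' @return two-sided exact p-value.
#' @export
direction_bias_test <- function(n_hypo, n_total) {
  if (n_total < 1) stop("n_total must be >= 1")
  if (n_hypo < 0 || n_hypo > n_total) stop("n_hypo must lie in [0, n_total]")
  lower <- pbinom(n_hypo, n_total, 0.5)
  upper <- pbinom(n_hypo - 1, n_total, 0.5, lower.tail = FALSE)
  min(1, 2 * min(lower, upper))
}

#' Overlapping pairs between two region sets
#'
#' Half-open interval semantics: abutting regions do not overlap.
#'
#' @param a,b data.frames of regions (chrom, start, end; 0-based
#'   half-open).
#' @return data.frame with columns `i` (row in `a`) and `j` (row in `b`)
#'   for every intersecting pair.
#' @export
overlap_regions <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L)
    return(data.frame(i = integer(), j = integer()))
  ga <- intervals_to_granges(a)
  gb <- intervals_to_granges(b)
  # disjoint chromosome sets are a legitimate query, not a warning
  h <- suppressWarnings(GenomicRanges::findOverlaps(ga, gb))
  data.frame(i = S4Vectors::queryHits(h), j = S4Vectors::subjectHits(h))
}

#' Permutation test for overlap between two region sets
#'
#' The observed statistic is the number of regions in `a` intersecting at
#' least one region in `b`.  Each permutation re-places every `a` region on
#' the tested-CpG backbone: a random start CpG is drawn (restricted so the
#' region's CpG count fits on one chromosome) and the region extended to
#' cover the same number of consecutive backbone CpGs, preserving the
#' CpG-density structure of the data.  The empirical p-value uses the
#' add-one form `(1 + #{null >= observed}) / (1 + n_perm)`.
#'
#' @param a,b region data.frames; `a` must carry an `n_cpg` column (as
#'   produced by [call_dmrs()]).
#' @param backbone data.frame of tested CpGs (chrom, pos), sorted.
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed (required for reproducibility).
#' @return list with `observed`, `null_counts` (length n_perm) and `p_emp`.
#' @export
permutation_overlap_test <- function(a, b, backbone, n_perm = 1000L, seed) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (nrow(backbone) == 0L) stop("backbone must be non-empty")
  if (missing(seed)) stop("an explicit seed is required")
  set.seed(seed)
  o <- order(backbone$chrom, backbone$pos)
  backbone <- backbone[o, , drop = FALSE]
  # per-chromosome sorted b intervals with running max of ends, so that
  # "does [s, e) hit any b region" is two binary searches
  b_idx <- split(seq_len(nrow(b)), b$chrom)
  b_sorted <- lapply(b_idx, function(i) {
    bi <- b[i[order(b$start[i])], , drop = FALSE]
    list(start = bi$start, maxend = cummax(bi$end))
  })
  hits_any <- function(chrom, s, e) {
    out <- logical(length(s))
    for (ch in unique(chrom)) {
      bs <- b_sorted[[ch]]
      i <- chrom == ch
      if (is.null(bs)) next
      k <- findInterval(e[i] - 1e-9, bs$start)   # b regions with start < e
      out[i] <- k > 0 & bs$maxend[pmax(k, 1L)] > s[i]
    }
    out
  }
  observed <- if (nrow(a) == 0L) 0L else
    sum(hits_any(a$chrom, a$start, a$end))
  if (nrow(a) == 0L)
    return(list(observed = 0L, null_counts = rep(0L, n_perm), p_emp = 1))
  chrom_rle <- rle(backbone$chrom)
  chrom_of <- rep(seq_along(chrom_rle$values), chrom_rle$lengths)
  nb <- nrow(backbone)
  ncpg <- pmax(1L, as.integer(a$n_cpg))
  if (any(ncpg > min(chrom_rle$lengths)) && any(ncpg > max(chrom_rle$lengths)))
    stop("a region spans more CpGs than the backbone holds")
  # valid start indices per region length: run must stay on one chromosome
  valid_starts <- function(k) {
    s <- seq_len(nb - k + 1L)
    s[chrom_of[s] == chrom_of[s + k - 1L]]
  }
  vs <- lapply(sort(unique(ncpg)), valid_starts)
  names(vs) <- as.character(sort(unique(ncpg)))
  null_counts <- integer(n_perm)
  for (it in seq_len(n_perm)) {
    starts <- integer(length(ncpg))
    for (k in unique(ncpg)) {
      i <- ncpg == k
      pool <- vs[[as.character(k)]]
      starts[i] <- pool[sample.int(length(pool), sum(i), replace = TRUE)]
    }
    ends <- starts + ncpg - 1L
    null_counts[it] <- sum(hits_any(backbone$chrom[starts],
                                    backbone$pos[starts],
                                    backbone$pos[ends] + 1))
  }
  p_emp <- (1 + sum(null_counts >= observed)) / (1 + n_perm)
  list(observed = observed, null_counts = null_counts, p_emp = p_emp)
}
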