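# Window-level co-methylation network: biweight midcorrelation,
# soft-threshold adjacency, topological overlap, module detection by
# hierarchical clustering of TOM dissimilarity, module eigenvectors, and
# module-trait statistics.  The construction follows standard weighted
# correlation network practice with a simplified static tree cut.

#' Summarize methylation in non-overlapping genomic windows
#'
#' Tiles each chromosome with fixed-size windows and computes, per window
#' and sample, the pooled methylation fraction (sum of methylated reads
#' over sum of total reads across member CpGs).  Windows with fewer than
#' `min_cpg` member CpGs or with among-sample variance not exceeding
#' `min_var` are dropped.
#'
#' @param m a filtered [meth_matrix()].
#' @param window_bp window size in bp (non-overlapping tiling).
#' @param min_cpg minimum member CpGs per window.
#' @param min_var minimum (strict) among-sample variance of the window
#'   methylation fraction.
#' @return list with `windows` (data.frame chrom, start, end, n_cpg) and
#'   `values` (windows x samples matrix of fractions).
#' @export
summarize_windows <- function(m, window_bp = 100L, min_cpg = 3L,
                              min_var = 0.05) {
  win_id <- paste(m$chrom, m$pos %/% window_bp)
  meth0 <- m$meth; total0 <- m$total
  meth0[is.na(meth0)] <- 0L; total0[is.na(total0)] <- 0L
  first <- !duplicated(win_id)
  uid <- win_id[first]
  g <- match(win_id, uid)
  n_cpg <- tabulate(g, nbins = length(uid))
  sm <- rowsum(meth0, g, reorder = TRUE)
  st <- rowsum(total0, g, reorder = TRUE)
  vals <- sm / st
  vals[st == 0] <- NA_real_
  windows <- data.frame(
    chrom = m$chrom[first],
    start = (m$pos[first] %/% window_bp) * window_bp,
    n_cpg = n_cpg)
  windows$end <- windows$start + window_bp
  v <- apply(vals, 1, var, na.rm = TRUE)
  keep <- n_cpg >= min_cpg & !is.na(v) & v > min_var &
    rowSums(is.na(vals)) == 0
  windows <- windows[keep, c("chrom", "start", "end", "n_cpg"),
                     drop = FALSE]
  o <- order(windows$chrom, windows$start)
  windows <- windows[o, , drop = FALSE]
  vals <- vals[keep, , drop = FALSE][o, , drop = FALSE]
  rownames(windows) <- NULL
  dimnames(vals) <- list(NULL, m$samples)
  list(windows = windows, values = vals)
}

# biweight transform of one variable; returns normalized weighted
# deviations, or NULL when MAD is zero (caller falls back to Pearson).
bicor_transform <- function(x) {
  med <- median(x)
  md <- mad(x, constant = 1)
  if (md == 0) return(NULL)
  u <- (x - med) / (9 * md)
  w <- (1 - u^2)^2 * (abs(u) < 1)
  xt <- (x - med) * w
  xt / sqrt(sum(xt^2))
}

pearson_transform <- function(x) {
  xt <- x - mean(x)
  s <- sqrt(sum(xt^2))
  if (s == 0) stop("constant variable in correlation")
  xt / s
}

#' Biweight midcorrelation of two vectors
#'
#' Robust correlation based on median/MAD weighting with tuning constant
#' 9 MADs; a variable with zero MAD falls back to its Pearson
#' (mean-centred) transform.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return correlation in `[-1, 1]`.
#' @export
bicor_vec <- function(x, y) {
  if (length(x) < 3) stop("need at least 3 observations")
  xt <- bicor_transform(x); if (is.null(xt)) xt <- pearson_transform(x)
  yt <- bicor_transform(y); if (is.null(yt)) yt <- pearson_transform(y)
  min(1, max(-1, sum(xt * yt)))
}

#' Biweight midcorrelation matrix between windows
#'
#' @param values windows x samples matrix (each row a variable observed
#'   across samples).
#' @return windows x windows symmetric correlation matrix, unit diagonal.
#' @export
bicor_matrix <- function(values) {
  if (ncol(values) < 3) stop("need at least 3 samples")
  tx <- apply(values, 1, function(x) {
    xt <- bicor_transform(x)
    if (is.null(xt)) xt <- pearson_transform(x)
    xt
  })                                   # samples x windows
  cc <- crossprod(tx)
  cc <- pmin(pmax(cc, -1), 1)
  diag(cc) <- 1
  cc
}

#' Soft-threshold adjacency and topological overlap
#'
#' Unsigned adjacency `a_ij = |corr_ij|^power` (diagonal set to 0), and
#' unsigned topological overlap
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_u a_iu a_uj`, `k_i = sum_u a_iu`; `TOM_ii = 1`.
#'
#' @param corr symmetric correlation matrix with unit diagonal.
#' @param power soft threshold exponent (> 0; default 18).
#' @return list with `adjacency`, `tom` and `dissim` (= 1 - tom).
#' @export
adjacency_and_tom <- function(corr, power = 18) {
  if (power <= 0) stop("power must be > 0")
  a <- abs(corr)^power
  diag(a) <- 0
  k <- rowSums(a)
  l <- a %*% a
  kmin <- outer(k, k, pmin)
  tom <- (l + a) / (kmin + 1 - a)
  diag(tom) <- 1
  list(adjacency = a, tom = tom, dissim = 1 - tom)
}

relabel_by_size <- function(labels) {
  tb <- sort(table(labels[labels != 0]), decreasing = TRUE)
  new <- setNames(seq_along(tb), names(tb))
  out <- integer(length(labels))
  nz <- labels != 0
  out[nz] <- new[as.character(labels[nz])]
  out
}

cluster_block <- function(dissim, min_module_size, cut_height) {
  h <- hclust(as.dist(dissim), method = "average")
  cl <- cutree(h, h = cut_height)
  sizes <- table(cl)
  small <- as.integer(names(sizes)[sizes < min_module_size])
  cl[cl %in% small] <- 0L
  cl
}

merge_by_eigencor <- function(values, labels, merge_corr) {
  repeat {
    ids <- sort(unique(labels[labels != 0]))
    if (length(ids) < 2) break
    eig <- module_eigenvectors(values, labels)$eigenvectors
    cc <- cor(eig)
    diag(cc) <- -Inf
    mx <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    if (cc[mx[1], mx[2]] < merge_corr) break
    from <- as.integer(colnames(eig)[mx[2]])
    to <- as.integer(colnames(eig)[mx[1]])
    labels[labels == from] <- to
  }
  labels
}

#' Detect co-methylation modules
#'
#' Average-linkage hierarchical clustering of the TOM dissimilarity with a
#' static tree cut at `cut_height`; clusters smaller than
#' `min_module_size` are left unassigned (label 0); modules whose
#' eigenvectors correlate at or above `merge_corr` are merged iteratively.
#' When more than `max_block` windows are supplied, genome-contiguous
#' blocks of at most `max_block` windows are clustered independently and
#' the resulting modules merged across blocks by eigenvector correlation.
#'
#' @param values windows x samples matrix (network input).
#' @param power soft-threshold exponent.
#' @param min_module_size minimum module size (windows).
#' @param merge_corr eigenvector correlation at which modules merge.
#' @param max_block maximum windows per clustering block.
#' @param cut_height static cut height on TOM dissimilarity.
#' @param dissim optional precomputed TOM dissimilarity (single block
#'   only); computed from `values` when NULL.
#' @return integer vector of module labels (0 = unassigned), relabelled
#'   1..K by decreasing module size.
#' @export
detect_modules <- function(values, power = 18, min_module_size = 10L,
                           merge_corr = 0.75, max_block = 30000L,
                           cut_height = 0.99, dissim = NULL) {
  n <- nrow(values)
  if (!is.null(dissim)) {
    if (nrow(dissim) != ncol(dissim)) stop("dissimilarity must be square")
    if (nrow(dissim) != n) stop("dissimilarity does not match values")
  }
  if (n < 2) return(integer(n))
  blocks <- split(seq_len(n), ceiling(seq_len(n) / max_block))
  labels <- integer(n)
  offset <- 0L
  for (idx in blocks) {
    d <- if (!is.null(dissim) && length(blocks) == 1L) dissim else
      adjacency_and_tom(bicor_matrix(values[idx, , drop = FALSE]),
                        power)$dissim
    cl <- cluster_block(d, min_module_size, cut_height)
    cl[cl != 0] <- cl[cl != 0] + offset
    offset <- offset + max(cl, 0L)
    labels[idx] <- cl
  }
  labels <- merge_by_eigencor(values, labels, merge_corr)
  relabel_by_size(labels)
}

#' Module eigenvectors and module membership
#'
#' Per module, windows are z-scored across samples and the first principal
#' axis of the standardized profiles gives the per-sample eigenvector
#' score (unit norm).  The sign is fixed so that the eigenvector
#' correlates non-negatively with the module's mean methylation.  Module
#' membership (MM) of a window is the absolute correlation of its raw
#' methylation profile with its module's eigenvector.
#'
#' @param values windows x samples matrix.
#' @param labels integer module labels (0 = unassigned).
#' @return list with `eigenvectors` (samples x modules matrix, columns
#'   named by module id) and `mm` (per-window module membership, NA for
#'   unassigned windows).
#' @export
module_eigenvectors <- function(values, labels) {
  ids <- sort(unique(labels[labels != 0]))
  nsamp <- ncol(values)
  eig <- matrix(NA_real_, nsamp, length(ids),
                dimnames = list(colnames(values), as.character(ids)))
  mm <- rep(NA_real_, nrow(values))
  for (j in seq_along(ids)) {
    idx <- which(labels == ids[j])
    if (length(idx) < 2) stop("module with fewer than 2 windows")
    X <- values[idx, , drop = FALSE]
    sds <- apply(X, 1, sd)
    if (any(sds == 0)) {
      warning("excluding zero-variance window(s) from module PCA")
      X <- X[sds > 0, , drop = FALSE]
    }
    Z <- t(scale(t(X)))                       # rows standardized
    sv <- svd(Z, nu = 0, nv = 1)
    v1 <- sv$v[, 1]
    if (cor(v1, colMeans(values[idx, , drop = FALSE])) < 0) v1 <- -v1
    eig[, j] <- v1
    mm[idx] <- abs(apply(values[idx, , drop = FALSE], 1, cor, y = v1))
  }
  list(eigenvectors = eig, mm = mm)
}

#' Module-trait association statistics
#'
#' Biweight midcorrelation of each module eigenvector with each trait
#' across samples; two-sided p from the Student-t transform with n-2
#' degrees of freedom.  Also returns gene significance (GS): the absolute
#' biweight midcorrelation of every window's methylation with each trait.
#'
#' @param eigenvectors samples x modules matrix from
#'   [module_eigenvectors()].
#' @param traits data.frame of phenotypes (samples in rows, numeric
#'   columns).
#' @param values optional windows x samples matrix to compute GS.
#' @return list with `module_trait` (data.frame module, trait, r, p,
#'   retained) and `gs` (windows x traits matrix or NULL).
#' @export
trait_association <- function(eigenvectors, traits, values = NULL) {
  n <- nrow(eigenvectors)
  stopifnot(nrow(traits) == n)
  rows <- list()
  for (tr in names(traits)) {
    y <- traits[[tr]]
    if (!is.numeric(y) || anyNA(y)) stop("trait must be numeric, complete")
    if (sd(y) == 0) stop("constant trait: ", tr)
    for (j in seq_len(ncol(eigenvectors))) {
      r <- bicor_vec(eigenvectors[, j], y)
      rows[[length(rows) + 1L]] <- data.frame(
        module = as.integer(colnames(eigenvectors)[j]), trait = tr,
        r = r, p = cor_t_pvalue(r, n))
    }
  }
  mt <- do.call(rbind, rows)
  mt$retained <- mt$p < 0.05
  gs <- NULL
  if (!is.null(values)) {
    gs <- sapply(names(traits), function(tr)
      apply(values, 1, function(x) abs(bicor_vec(x, traits[[tr]]))))
    gs <- matrix(gs, nrow = nrow(values),
                 dimnames = list(NULL, names(traits)))
  }
  list(module_trait = mt, gs = gs)
}

#' Student-t p-value for a correlation coefficient
#'
#' Two-sided p for H0: rho = 0 with `n - 2` degrees of freedom; |r| = 1
#' returns the smallest representable positive double.
#'
#' @param r correlation.
#' @param n sample size (> 2).
#' @return p-value in (0, 1].
#' @export
cor_t_pvalue <- function(r, n) {
  stopifnot(n > 2, abs(r) <= 1)
  if (abs(r) >= 1) return(.Machine$double.xmin)
  t <- r * sqrt((n - 2) / (1 - r^2))
  max(2 * pt(-abs(t), n - 2), .Machine$double.xmin)
}

#' Permutation enrichment of DMR overlap within a module
#'
#' Observed statistic: number of module windows intersecting any DMR.
#' Null: the same count for random draws of `|module|` windows without
#' replacement from all network windows.  Add-one empirical p.
#'
#' @param module_idx indices of the module's windows.
#' @param dmr_overlap logical vector over all network windows (TRUE when
#'   the window intersects a DMR).
#' @param n_perm permutations.
#' @param seed integer seed (required).
#' @return list with `observed`, `null_counts`, `p_emp`.
#' @export
module_dmr_enrichment <- function(module_idx, dmr_overlap,
                                  n_perm = 1000L, seed) {
  if (missing(seed)) stop("an explicit seed is required")
  nw <- length(dmr_overlap)
  k <- length(module_idx)
  if (k == 0) stop("module must be non-empty")
  if (k > nw) stop("module larger than background")
  set.seed(seed)
  observed <- sum(dmr_overlap[module_idx])
  null_counts <- vapply(seq_len(n_perm), function(i)
    sum(dmr_overlap[sample.int(nw, k)]), integer(1))
  list(observed = observed, null_counts = null_counts,
       p_emp = (1 + sum(null_counts >= observed)) / (1 + n_perm))
}

#' Flag network windows that intersect a DMR
#'
#' @param windows data.frame of network windows (chrom, start, end).
#' @param dmrs data.frame of DMRs (chrom, start, end).
#' @return logical vector, one element per window.
#' @export
window_dmr_overlap <- function(windows, dmrs) {
  flags <- rep(FALSE, nrow(windows))
  if (nrow(dmrs) == 0L || nrow(windows) == 0L) return(flags)
  ov <- overlap_regions(windows, dmrs)
  flags[unique(ov$i)] <- TRUE
  flags
}

#' Welch t comparison of MM and GS between DMR and non-DMR windows
#'
#' Within one module, compares mean module membership and mean gene
#' significance between windows that do and do not overlap DMRs using
#' Welch's two-sample t-test (Welch-Satterthwaite degrees of freedom).
#'
#' @param mm module membership values for the module's windows.
#' @param gs gene significance values for the module's windows.
#' @param dmr_flags logical, TRUE for DMR-overlapping windows.
#' @return data.frame with one row per measure (mm, gs): t, df, p;
#'   all NA with `testable = FALSE` when a stratum has < 2 windows.
#' @export
mm_gs_comparison <- function(mm, gs, dmr_flags) {
  one <- function(x, name) {
    a <- x[dmr_flags]; b <- x[!dmr_flags]
    if (length(a) < 2 || length(b) < 2 || (sd(a) == 0 && sd(b) == 0))
      return(data.frame(measure = name, t = NA_real_, df = NA_real_,
                        p = NA_real_, testable = FALSE))
    tt <- t.test(a, b, var.equal = FALSE)
    data.frame(measure = name, t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value,
               testable = TRUE)
  }
  rbind(one(mm, "mm"), one(gs, "gs"))
}
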