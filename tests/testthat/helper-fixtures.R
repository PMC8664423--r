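# Small in-code fixtures shared across test files.

# meth_matrix from a compact spec: one row per site, counts as a
# list of (meth, total) per sample; NA pairs mark missing cells
mk_matrix <- function(chrom, pos, meth, total, samples = NULL) {
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(ncol(meth)))
  meth_matrix(rep(chrom, length.out = length(pos)), pos, meth, total,
              samples)
}

# beta-binomial draws (moment parameterization used by the generator)
rbb <- function(n, size, mu, phi) {
  p <- rbeta(n, mu * (1 - phi) / phi, (1 - mu) * (1 - phi) / phi)
  rbinom(n, size, p)
}

# two-group matrix of beta-binomial counts at given positions; `mu` is a
# sites x 2 matrix of group means
mk_bb_matrix <- function(pos, mu, n_per = 8, cov_mean = 8.3, phi = 0.1,
                         chrom = "chr1") {
  n <- length(pos)
  tot <- matrix(pmin(1 + rpois(n * 2 * n_per, cov_mean - 1), 20),
                n, 2 * n_per)
  muM <- cbind(matrix(mu[, 1], n, n_per), matrix(mu[, 2], n, n_per))
  met <- matrix(rbb(length(tot), as.vector(tot), as.vector(muM), phi),
                n, 2 * n_per)
  samples <- c(sprintf("g1_%d", 1:n_per), sprintf("g2_%d", 1:n_per))
  meth_matrix(rep(chrom, n), pos, met, tot, samples)
}

g1_of <- function(m) grep("^g1_", m$samples, value = TRUE)
g2_of <- function(m) grep("^g2_", m$samples, value = TRUE)

# brute-force BH step-up (textbook definition, independent of bh_fdr)
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    vals <- sapply(i:m, function(j) m * p[o[j]] / j)
    q[o[i]] <- min(1, min(vals))
  }
  q
}

# brute-force biweight midcorrelation (published formula, double loop)
bicor_oracle <- function(x, y) {
  tf <- function(v) {
    med <- median(v); md <- median(abs(v - med))
    u <- (v - med) / (9 * md)
    w <- (1 - u^2)^2 * (abs(u) < 1)
    (v - med) * w
  }
  a <- tf(x); b <- tf(y)
  sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
}

# brute-force unsigned TOM (triple loop)
tom_oracle <- function(corr, power) {
  a <- abs(corr)^power; diag(a) <- 0
  n <- nrow(a)
  tom <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { tom[i, j] <- 1; next }
    l <- sum(sapply(seq_len(n), function(u) a[i, u] * a[u, j]))
    k_i <- sum(a[i, ]); k_j <- sum(a[j, ])
    tom[i, j] <- (l + a[i, j]) / (min(k_i, k_j) + 1 - a[i, j])
  }
  tom
}

# hand Welch t-test (formula oracle)
welch_oracle <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# planted-block values matrix for module recovery: `k` blocks of `size`
# windows with within-block correlation ~rho, plus `noise` independent
# windows; returns values matrix and true labels
planted_blocks <- function(k = 3, size = 30, noise = 50, nsamp = 16,
                           rho = 0.9) {
  lat <- matrix(rnorm(nsamp * k), nsamp, k)
  rows <- list(); labels <- integer()
  for (b in seq_len(k)) for (w in seq_len(size)) {
    rows[[length(rows) + 1L]] <-
      sqrt(rho) * lat[, b] + sqrt(1 - rho) * rnorm(nsamp)
    labels <- c(labels, b)
  }
  for (w in seq_len(noise)) {
    rows[[length(rows) + 1L]] <- rnorm(nsamp)
    labels <- c(labels, 0L)
  }
  vals <- do.call(rbind, rows)
  # map to (0,1) methylation-like scale preserving correlation structure
  vals <- 0.5 + 0.15 * vals
  list(values = vals, labels = labels)
}
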