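test_that("window summaries pool counts and apply the filters", {
  # 3 CpGs (4,10),(6,10),(10,10) in one window, second sample varies
  m <- mk_matrix(rep("chr1", 3), c(110L, 150L, 190L),
                 matrix(c(4L, 6L, 10L, 0L, 1L, 0L), 3, 2),
                 matrix(10L, 3, 2))
  wm <- summarize_windows(m, min_cpg = 3L, min_var = 0.01)
  expect_equal(nrow(wm$windows), 1L)
  expect_equal(wm$windows$start, 100L)
  expect_equal(unname(wm$values[1, 1]), 20 / 30, tolerance = 1e-12)
  # fewer than 3 CpGs -> dropped
  m2 <- mk_matrix(rep("chr1", 2), c(110L, 150L),
                  matrix(c(4L, 6L, 0L, 1L), 2, 2), matrix(10L, 2, 2))
  expect_equal(nrow(summarize_windows(m2, min_var = 0)$windows), 0L)
  # constant across samples -> variance filter drops it
  m3 <- mk_matrix(rep("chr1", 3), c(110L, 150L, 190L),
                  matrix(5L, 3, 4), matrix(10L, 3, 4))
  expect_equal(nrow(summarize_windows(m3)$windows), 0L)
})

test_that("bicor has correlation identities and matches its oracle", {
  set.seed(9)
  x <- rnorm(10)
  expect_equal(bicor_vec(x, x), 1, tolerance = 1e-12)
  expect_equal(bicor_vec(x, -x), -1, tolerance = 1e-12)
  for (i in 1:20) {
    a <- rnorm(10); b <- rnorm(10)
    expect_equal(bicor_vec(a, b), bicor_oracle(a, b), tolerance = 1e-10)
  }
  vals <- matrix(rnorm(8 * 12), 8, 12)
  cm <- bicor_matrix(vals)
  expect_equal(diag(cm), rep(1, 8))
  expect_equal(cm, t(cm))
  for (i in 1:7) for (j in (i + 1):8)
    expect_equal(cm[i, j], bicor_oracle(vals[i, ], vals[j, ]),
                 tolerance = 1e-10)
  expect_error(bicor_matrix(vals[, 1:2]), "3 samples")
})

test_that("TOM follows its formula, collapses for two nodes, and is bounded", {
  # two-node network: TOM12 reduces to the adjacency
  c2 <- matrix(c(1, 0.6, 0.6, 1), 2, 2)
  t2 <- adjacency_and_tom(c2, power = 3)
  expect_equal(t2$tom[1, 2], 0.6^3, tolerance = 1e-12)
  # identical columns: full overlap
  cI <- matrix(1, 4, 4)
  tI <- adjacency_and_tom(cI, power = 18)
  expect_true(all(abs(tI$tom - 1) < 1e-12))
  # random 5-node matrix vs triple-loop oracle
  set.seed(15)
  x <- matrix(rnorm(25), 5)
  cr <- cov2cor(crossprod(x) + diag(5))
  tr <- adjacency_and_tom(cr, power = 6)
  expect_equal(tr$tom, tom_oracle(cr, 6), tolerance = 1e-12)
  # bounded, symmetric, unit diagonal on random inputs
  expect_true(all(tr$tom >= 0 & tr$tom <= 1))
  expect_equal(tr$tom, t(tr$tom))
  expect_equal(diag(tr$tom), rep(1, 5))
  expect_error(adjacency_and_tom(cr, power = 0), "power")
})

test_that("module detection recovers planted blocks and ignores noise", {
  skip_if_not_installed("mclust")
  set.seed(77)
  pb <- planted_blocks(k = 3, size = 30, noise = 50, nsamp = 16, rho = 0.9)
  labels <- detect_modules(pb$values)
  ari <- mclust::adjustedRandIndex(labels, pb$labels)
  expect_gte(ari, 0.8)
  # all-noise input: nothing reaches the module size floor
  noise <- matrix(rnorm(40 * 16), 40, 16)
  expect_true(all(detect_modules(noise) == 0))
  # a single 5-window block with floor 10 stays unassigned
  pb5 <- planted_blocks(k = 1, size = 5, noise = 20, nsamp = 16)
  expect_true(all(detect_modules(pb5$values, min_module_size = 10L) == 0))
})

test_that("module eigenvectors are first principal axes with fixed sign", {
  set.seed(19)
  # rank-1 module: identical windows -> all mm = 1
  base <- runif(12)
  vals <- matrix(rep(base, each = 6), 6, 12)
  vals <- vals + 1e-9 * matrix(rnorm(72), 6, 12)  # break exact ties
  me <- module_eigenvectors(vals, rep(1L, 6))
  expect_true(all(me$mm > 1 - 1e-6))
  expect_gt(cor(me$eigenvectors[, 1], base), 1 - 1e-6)
  # oracle: dense eigendecomposition of the standardized covariance
  vals2 <- matrix(runif(10 * 16), 10, 16)
  me2 <- module_eigenvectors(vals2, rep(1L, 10))
  Z <- t(scale(t(vals2)))
  ev <- eigen(crossprod(Z))$vectors[, 1]
  if (sum(ev * me2$eigenvectors[, 1]) < 0) ev <- -ev
  expect_equal(as.vector(me2$eigenvectors[, 1]), ev, tolerance = 1e-8)
  expect_equal(sqrt(sum(me2$eigenvectors[, 1]^2)), 1, tolerance = 1e-12)
  # variance explained by the first axis beats any single window
  scores <- as.vector(Z %*% me2$eigenvectors[, 1])
  expect_gte(sum(scores^2), max(rowSums(Z^2)) - 1e-8)
})

test_that("module-trait statistics use the Student-t convention", {
  expect_equal(round(cor_t_pvalue(0.69, 16), 3), 0.003)
  expect_equal(cor_t_pvalue(0, 10), 1)
  expect_equal(cor_t_pvalue(1, 10), .Machine$double.xmin)
  set.seed(4)
  vals <- matrix(runif(20 * 16), 20, 16)
  labels <- rep(1:2, each = 10)
  me <- module_eigenvectors(vals, labels)
  traits <- data.frame(tr = rnorm(16))
  ta <- trait_association(me$eigenvectors, traits, vals)
  expect_equal(nrow(ta$module_trait), 2L)
  expect_true(all(abs(ta$module_trait$r) <= 1))
  expect_equal(dim(ta$gs), c(20L, 1L))
  expect_error(trait_association(me$eigenvectors,
                                 data.frame(tr = rep(1, 16))),
               "constant")
})

test_that("module DMR enrichment has the add-one lower bound", {
  flags <- c(rep(TRUE, 20), rep(FALSE, 380))
  r <- module_dmr_enrichment(1:20, flags, n_perm = 1000, seed = 6)
  expect_equal(r$observed, 20L)
  expect_equal(r$p_emp, 1 / 1001)
  # module = all windows: every draw ties the observed count
  r2 <- module_dmr_enrichment(1:400, flags, n_perm = 100, seed = 6)
  expect_equal(r2$p_emp, 1)
  # no DMR overlap anywhere
  r3 <- module_dmr_enrichment(1:20, rep(FALSE, 400), n_perm = 100,
                              seed = 6)
  expect_equal(r3$observed, 0L)
  expect_equal(r3$p_emp, 1)
  expect_error(module_dmr_enrichment(integer(), flags, seed = 1),
               "non-empty")
})

test_that("MM/GS comparison is a Welch t-test", {
  set.seed(26)
  a <- rnorm(20, 0.8, 0.05); b <- rnorm(20, 0.6, 0.05)
  flags <- rep(c(TRUE, FALSE), each = 20)
  res <- mm_gs_comparison(c(a, b), c(a, b) / 2, flags)
  o <- welch_oracle(a, b)
  expect_equal(res$t[res$measure == "mm"], o$t, tolerance = 1e-10)
  expect_equal(res$df[res$measure == "mm"], o$df, tolerance = 1e-10)
  expect_equal(res$p[res$measure == "mm"], o$p, tolerance = 1e-10)
  # fractional (Welch) degrees of freedom, not pooled
  a2 <- rnorm(12, 0.8, 0.12); b2 <- rnorm(28, 0.6, 0.03)
  res2 <- mm_gs_comparison(c(a2, b2), c(a2, b2), rep(c(TRUE, FALSE),
                                                     c(12, 28)))
  expect_false(abs(res2$df[1] - 38) < 1e-6)
  # identical strata -> t = 0, p = 1
  v <- rnorm(10)
  res3 <- mm_gs_comparison(c(v, v), c(v, v),
                           rep(c(TRUE, FALSE), each = 10))
  expect_equal(res3$t[1], 0)
  expect_equal(res3$p[1], 1)
  # undersized stratum flagged untestable
  res4 <- mm_gs_comparison(rnorm(5), rnorm(5), c(TRUE, rep(FALSE, 4)))
  expect_false(res4$testable[1])
})
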