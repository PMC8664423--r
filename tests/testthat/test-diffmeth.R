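test_that("smoothing pools window counts and respects isolation", {
  # isolated CpG returns its raw fraction
  m <- mk_matrix("chr1", c(0L, 10000L),
                 matrix(c(8L, 3L), 2, 1), matrix(c(10L, 10L), 2, 1))
  sm <- smooth_methylation(m, 500L)
  expect_equal(unname(sm$frac[1, 1]), 0.8)
  # two sites 100 bp apart pool to 15/20 (single sample: pooled ratio)
  m2 <- mk_matrix("chr1", c(0L, 100L),
                  matrix(c(5L, 10L), 2, 1), matrix(c(10L, 10L), 2, 1))
  sm2 <- smooth_methylation(m2, 500L)
  expect_equal(as.vector(sm2$frac), c(0.75, 0.75))
  # constant fraction is invariant under smoothing
  n <- 20
  m3 <- mk_matrix(rep("chr1", n), seq(0L, by = 50L, length.out = n),
                  matrix(9L, n, 3), matrix(10L, n, 3))
  expect_true(all(abs(smooth_methylation(m3)$frac - 0.9) < 1e-12))
})

test_that("smoothing equals a double-loop weighted-mean oracle", {
  set.seed(13)
  n <- 60; k <- 4
  pos <- sort(sample.int(3000, n))
  tot <- matrix(rpois(n * k, 8) + 1L, n, k)
  met <- matrix(rbinom(n * k, as.vector(tot), 0.6), n, k)
  m <- mk_matrix(rep("chr1", n), pos, met, tot)
  sm <- smooth_methylation(m, 500L)
  w <- rowSums(tot)
  for (s in sample(n, 10)) for (j in seq_len(k)) {
    inwin <- which(abs(pos - pos[s]) <= 250)
    expected <- sum(w[inwin] * met[inwin, j] / tot[inwin, j]) /
      sum(w[inwin])
    expect_equal(unname(sm$frac[s, j]), expected, tolerance = 1e-12)
  }
})

test_that("moment dispersion estimator is unbiased in Monte Carlo", {
  set.seed(101)
  n <- 1e4; m <- 8; N <- 10; mu <- 0.7; phi <- 0.1
  p <- matrix(rbeta(n * m, mu * 9, (1 - mu) * 9), n, m)
  x <- matrix(rbinom(n * m, N, p), n, m)
  est <- phi_moment_raw(x / N, matrix(N, n, m))
  expect_lt(abs(mean(est, na.rm = TRUE) - phi), 0.03)
})

test_that("group variance matches the closed form for isolated sites", {
  # identical samples, fractions 0.5, phi at the floor:
  # var_mu = 0.25 * sum(N_i + N_i (N_i - 1) phi) / (sum N_i)^2
  N <- c(10L, 12L, 8L)
  m <- mk_matrix("chr1", 0L, matrix(as.integer(N / 2), 1, 3),
                 matrix(N, 1, 3))
  sm <- smooth_methylation(m)
  est <- estimate_group_dispersion(m, sm, 1:3)
  phi <- est$phi[1]
  expected <- 0.25 * sum(N + N * (N - 1) * phi) / sum(N)^2
  expect_equal(est$var_mu[1], expected, tolerance = 1e-10)
  # boundary mean is clamped before the variance formula: var stays > 0
  m0 <- mk_matrix("chr1", 0L, matrix(0L, 1, 3), matrix(N, 1, 3))
  est0 <- estimate_group_dispersion(m0, smooth_methylation(m0), 1:3)
  expect_gt(est0$var_mu[1], 0)
})

test_that("Wald statistic is null-centred, antisymmetric and monotone", {
  set.seed(3)
  n <- 50
  pos <- sort(sample.int(1e5, n))
  mu <- cbind(rep(0.7, n), rep(0.7, n))
  m <- mk_bb_matrix(pos, mu)
  sm <- smooth_methylation(m)
  i1 <- match(g1_of(m), m$samples); i2 <- match(g2_of(m), m$samples)
  e1 <- estimate_group_dispersion(m, sm, i1)
  e2 <- estimate_group_dispersion(m, sm, i2)
  r12 <- dmc_wald_test(e1, e2, m$chrom, m$pos)
  r21 <- dmc_wald_test(e2, e1, m$chrom, m$pos)
  expect_equal(r12$stat, -r21$stat)
  expect_equal(r12$pval, r21$pval)
  # identical estimates give stat 0, p 1
  r11 <- dmc_wald_test(e1, e1, m$chrom, m$pos)
  expect_true(all(r11$stat == 0))
  expect_true(all(r11$pval == 1))
  # increasing |mu1 - mu2| at fixed variance never decreases |stat|
  e_shift <- e1
  stats <- sapply(c(0.05, 0.1, 0.2, 0.3), function(d) {
    e_shift$mu <- e1$mu + d
    mean(abs(dmc_wald_test(e_shift, e2, m$chrom, m$pos)$stat))
  })
  expect_true(all(diff(stats) > 0))
})

test_that("BH q-values follow the step-up definition", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(0.03), 0.03)
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("BH agrees exactly with brute-force step-up and p.adjust", {
  set.seed(21)
  for (rep in 1:100) {
    p <- runif(sample(3:30, 1))
    q <- bh_fdr(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    expect_equal(q, p.adjust(p, "BH"), tolerance = 1e-12)
  }
})

test_that("null simulation keeps the Wald test calibrated at p<0.001", {
  # two groups of 8 with no group effect, coverage ~8x, phi = 0.1
  cfg <- sim_config(seed = 3, chrom_len_bp = 1.4e6, n_dmrs = 0L,
                    n_modules = 0L, n_noise_windows = 0L)
  bb <- simulate_backbone_and_genes(cfg)
  cnt <- simulate_counts(bb, cfg)
  m <- build_matrix(cnt$tables, cnt$meta)
  m <- filter_sites(m, chrom_lengths = bb$chrom_lengths)
  dmc <- dmc_test(m, cnt$meta$sample_id[cnt$meta$group == "SAS"],
                  cnt$meta$sample_id[cnt$meta$group == "wild"])
  frac <- mean(dmc$pval < 0.001)
  expect_gte(frac, 0.0002)
  expect_lte(frac, 0.005)
})

test_that("per-site power at a planted 0.39 difference exceeds 0.5", {
  cfg <- sim_config(seed = 17, chrom_len_bp = 4e5,
                    n_dmrs = 25L, dmr_effect_range = c(0.39, 0.39),
                    dmr_n_cpg = c(6L, 10L),
                    n_modules = 0L, n_noise_windows = 0L)
  bb <- simulate_backbone_and_genes(cfg)
  cnt <- simulate_counts(bb, cfg)
  m <- build_matrix(cnt$tables, cnt$meta)
  m <- filter_sites(m, chrom_lengths = bb$chrom_lengths)
  dmc <- dmc_test(m, cnt$meta$sample_id[cnt$meta$group == "SAS"],
                  cnt$meta$sample_id[cnt$meta$group == "wild"])
  tr <- cnt$truth$dmrs
  inside <- rep(FALSE, nrow(dmc))
  for (i in seq_len(nrow(tr)))
    inside <- inside | (dmc$chrom == tr$chrom[i] &
                          dmc$pos >= tr$start[i] & dmc$pos < tr$end[i])
  expect_gt(mean(dmc$pval[inside] < 0.001), 0.5)
})
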