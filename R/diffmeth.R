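# Smoothed beta-binomial two-group differential methylation (DSS-style).
#
# Per sample, methylation fractions are smoothed by pooling read counts over
# a fixed genomic window around each CpG.  Group means are coverage-weighted
# means of the smoothed fractions; their variance combines binomial sampling
# noise with a beta-binomial overdispersion phi estimated per site per group
# and shrunk toward a genome-wide value.  The two-group contrast is a Wald
# statistic referred to the standard normal.

#' Window-smooth per-sample methylation fractions
#'
#' For each sample and CpG site, averages per-site methylation fractions
#' over all retained sites within `window_bp / 2` bp on either side (same
#' chromosome), weighting each site by its total coverage summed over all
#' samples.  Sharing the site weights across samples keeps every sample's
#' smoothed value an estimate of the same local mean, so that between-group
#' contrasts are not perturbed by stochastic coverage differences; with a
#' single sample (or equal coverage) the estimate equals the pooled-count
#' ratio.  Missing cells contribute nothing; a site with no observed
#' counts anywhere in its window is `NA`.
#'
#' @param m a [meth_matrix()] (already filtered).
#' @param window_bp total window size in bp (default 500, i.e. +/-250).
#' @return list with sites x samples matrices: `frac` (smoothed
#'   fractions), `total` (window-pooled per-sample read totals), and the
#'   variance bookkeeping terms `wden` (windowed sum of site weights
#'   observed in the sample), `A` (windowed sum of w^2 / N) and `B`
#'   (windowed sum of w^2 (1 - 1/N)); see
#'   [estimate_group_dispersion()].
#' @export
smooth_methylation <- function(m, window_bp = 500L) {
  stopifnot(window_bp > 0)
  half <- window_bp / 2
  n <- n_sites(m); k <- n_samples(m)
  meth0 <- m$meth; total0 <- m$total
  meth0[is.na(meth0)] <- 0L; total0[is.na(total0)] <- 0L
  w <- rowSums(total0)                       # shared site weight
  p_raw <- ifelse(total0 > 0, meth0 / total0, 0)
  num0 <- w * p_raw
  den0 <- w * (total0 > 0)
  A0 <- ifelse(total0 > 0, w^2 / total0, 0)
  B0 <- ifelse(total0 > 0, w^2 - w^2 / total0, 0)
  win_sum <- function(x, lo, hi) {
    cs <- rbind(0, apply(x, 2, cumsum))
    cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]
  }
  num <- den <- A <- B <- tt <- matrix(0, n, k)
  for (ch in unique(m$chrom)) {
    i <- which(m$chrom == ch)
    pos <- m$pos[i]
    lo <- findInterval(pos - half, pos, left.open = TRUE) + 1L
    hi <- findInterval(pos + half, pos)
    num[i, ] <- win_sum(num0[i, , drop = FALSE], lo, hi)
    den[i, ] <- win_sum(den0[i, , drop = FALSE], lo, hi)
    A[i, ] <- win_sum(A0[i, , drop = FALSE], lo, hi)
    B[i, ] <- win_sum(B0[i, , drop = FALSE], lo, hi)
    tt[i, ] <- win_sum(total0[i, , drop = FALSE], lo, hi)
  }
  frac <- num / den
  frac[den == 0] <- NA_real_
  dimnames(frac) <- list(NULL, m$samples)
  list(frac = frac, total = tt, wden = den, A = A, B = B)
}

MU_EPS <- 1e-5
PHI_FLOOR <- 1e-4
PHI_CEIL <- 0.9

clamp_mu <- function(mu) pmin(pmax(mu, MU_EPS), 1 - MU_EPS)

#' Per-site beta-binomial dispersion (moment estimator)
#'
#' Kleinman-type weighted moment estimator of the beta-binomial
#' overdispersion phi from per-sample methylation fractions `p` with
#' coverage weights `n` (one site per row).  Returns the raw, unclamped
#' estimate; negative values indicate underdispersion relative to binomial.
#'
#' @param p sites x samples matrix of raw methylation fractions.
#' @param n sites x samples matrix of total read counts (weights).
#' @return numeric vector of raw phi estimates (NA where fewer than two
#'   samples carry data or the mean is at the boundary).
#' @export
phi_moment_raw <- function(p, n) {
  n[is.na(p)] <- NA_real_
  w <- n
  W <- rowSums(w, na.rm = TRUE)
  m <- rowSums(!is.na(p))
  pbar <- rowSums(w * p, na.rm = TRUE) / W
  S <- rowSums(w * (p - pbar)^2, na.rm = TRUE)
  sumw2 <- rowSums(w^2, na.rm = TRUE)
  denom <- W - sumw2 / W - (m - 1)
  v <- pbar * (1 - pbar)
  phi <- (S / v - (m - 1)) / denom
  phi[m < 2 | v <= 0 | denom <= 0] <- NA_real_
  phi
}

#' Group-level smoothed mean, dispersion and variance per CpG
#'
#' For one group of samples, computes per site: `mu`, the coverage-weighted
#' mean of smoothed per-sample fractions (weights `U_i` = sample i's
#' window-pooled total); `phi`, the moment estimate of beta-binomial
#' dispersion from raw per-sample fractions shrunk toward the genome-wide
#' trimmed mean with weight m / (m + m0) and clamped to `[1e-4, 0.9]`; and
#' `var_mu`, the delta-method variance of the group-mean estimator:
#' each sample's smoothed fraction has variance
#' `mu(1-mu) (A_i + phi B_i) / W_i^2` (windowed sums from
#' [smooth_methylation()]), and
#' `var_mu = sum_i U_i^2 Var(s_i) / (sum_i U_i)^2`.  For an isolated CpG
#' this reduces to the familiar
#' `sum_i N_i mu(1-mu)(1 + (N_i - 1) phi) / (sum_i N_i)^2`.
#'
#' @param m a [meth_matrix()].
#' @param sm result of [smooth_methylation()] on `m`.
#' @param sample_idx integer/logical index of this group's columns.
#' @param m0 shrinkage prior weight (samples-worth of pseudo-data).
#' @param trim trim fraction for the genome-wide mean dispersion.
#' @return data.frame with mu, phi, var_mu, n_obs (samples with window
#'   data) and `testable` flag; attribute `phi_global`.
#' @export
estimate_group_dispersion <- function(m, sm, sample_idx, m0 = 20,
                                      trim = 0.1) {
  p_raw <- m$meth[, sample_idx, drop = FALSE] /
    m$total[, sample_idx, drop = FALSE]
  n_raw <- m$total[, sample_idx, drop = FALSE]
  phi_raw <- phi_moment_raw(p_raw, n_raw)
  # the moment estimator degenerates near the methylation boundaries
  # (counts saturate at 0 or N), so the genome-wide target averages over
  # sites with intermediate mean methylation only
  n0 <- n_raw; n0[is.na(n0)] <- 0L
  x0 <- m$meth[, sample_idx, drop = FALSE]; x0[is.na(x0)] <- 0L
  pbar <- rowSums(x0) / rowSums(n0)
  mid <- !is.na(pbar) & pbar >= 0.1 & pbar <= 0.9
  pool <- if (sum(mid & !is.na(phi_raw)) >= 100) phi_raw[mid] else phi_raw
  phi_global <- mean(pool, trim = trim, na.rm = TRUE)
  if (!is.finite(phi_global)) phi_global <- PHI_FLOOR
  nsamp <- rowSums(!is.na(p_raw))
  w_site <- nsamp / (nsamp + m0)
  phi_site <- ifelse(is.na(phi_raw), phi_global,
                     w_site * phi_raw + (1 - w_site) * phi_global)
  # one-sided safeguard: a site whose observed dispersion far exceeds the
  # genome-wide value is genuinely variable between samples, and shrinking
  # it down would manufacture significance there; such sites keep most of
  # their own estimate (weight m / (m + m0_up), m0_up = 4)
  w_up <- nsamp / (nsamp + 4)
  phi_up <- ifelse(is.na(phi_raw), phi_global,
                   w_up * phi_raw + (1 - w_up) * phi_global)
  phi_site <- pmax(phi_site, phi_up)
  phi <- pmin(pmax(phi_site, PHI_FLOOR), PHI_CEIL)

  s <- sm$frac[, sample_idx, drop = FALSE]
  U <- sm$total[, sample_idx, drop = FALSE]
  W <- sm$wden[, sample_idx, drop = FALSE]
  A <- sm$A[, sample_idx, drop = FALSE]
  B <- sm$B[, sample_idx, drop = FALSE]
  obs <- !is.na(s) & U > 0
  s0 <- s; s0[!obs] <- 0
  U0 <- U; U0[!obs] <- 0
  Usum <- rowSums(U0)
  mu <- rowSums(U0 * s0) / Usum
  mu_c <- clamp_mu(mu)
  var_s <- ifelse(W > 0, (A + phi * B) / W^2, 0)  # / (mu(1-mu)) factored
  Vi <- mu_c * (1 - mu_c) * var_s                 # model Var(s_i)
  a <- U0 / Usum
  S1 <- rowSums(a * Vi); S2 <- rowSums(a^2 * Vi)
  var_mu <- S2
  n_obs <- rowSums(obs)
  # gated empirical (sandwich) variance: regions whose between-sample
  # spread of smoothed fractions exceeds the site-independent model by far
  # more than chi-square noise allows are genuinely variable (regionally
  # correlated biological variance); their group-mean variance comes from
  # the data instead of the model
  v_emp <- rowSums(a * (s0 - mu)^2, na.rm = TRUE)
  ratio <- ifelse(S1 - S2 > 0, v_emp / (S1 - S2), 1)
  gate <- is.finite(ratio) & ratio > 3 & n_obs >= 4
  var_mu[gate] <- ratio[gate] * S2[gate]
  testable <- n_obs >= 2 & Usum > 0
  out <- data.frame(mu = mu, phi = phi, var_mu = var_mu,
                    n_obs = n_obs, testable = testable)
  attr(out, "phi_global") <- phi_global
  out
}

#' Wald test for two-group differential methylation per CpG
#'
#' `stat = (mu1 - mu2) / sqrt(var_mu1 + var_mu2)`, two-sided p from the
#' standard normal.  Sites untestable in either group get `NA` statistics
#' and are excluded from FDR adjustment downstream.
#'
#' @param est1,est2 group estimates from [estimate_group_dispersion()].
#' @param chrom,pos site coordinates (parallel to the estimate rows).
#' @return data.frame of DMC records: chrom, pos, mu1, mu2, diff, stat,
#'   pval (no fdr column yet; see [bh_fdr()]).
#' @export
dmc_wald_test <- function(est1, est2, chrom, pos) {
  stopifnot(nrow(est1) == nrow(est2))
  vsum <- est1$var_mu + est2$var_mu
  if (any(vsum[est1$testable & est2$testable] <= 0, na.rm = TRUE))
    stop("zero variance after clamping; should be impossible")
  stat <- (est1$mu - est2$mu) / sqrt(vsum)
  p <- 2 * pnorm(-abs(stat))
  ok <- est1$testable & est2$testable
  stat[!ok] <- NA_real_; p[!ok] <- NA_real_
  data.frame(chrom = chrom, pos = pos,
             mu1 = est1$mu, mu2 = est2$mu,
             diff = est1$mu - est2$mu,
             stat = stat, pval = p)
}

#' Benjamini-Hochberg step-up q-values
#'
#' `q_(i) = min_{j >= i} (m * p_(j) / j)` capped at 1, mapped back to the
#' input order.  `NA` p-values propagate as `NA` and do not count toward m.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return q-values in the input order.
#' @export
bh_fdr <- function(p) {
  ok <- !is.na(p)
  pv <- p[ok]
  if (any(pv < 0 | pv > 1)) stop("p-values must lie in [0, 1]")
  m <- length(pv)
  q <- rep(NA_real_, length(p))
  if (m > 0) {
    o <- order(pv)
    qq <- pmin(1, cummin(rev(m * pv[o] / seq_len(m))))
    qq <- rev(qq)
    qs <- numeric(m)
    qs[o] <- qq
    q[ok] <- qs
  }
  q
}

#' Full two-group DMC analysis
#'
#' Smooths, estimates group models, tests every testable CpG and adjusts
#' jointly with BH.  Group 1 is the focal group (its mean enters `diff`
#' with positive sign), group 2 the reference.
#'
#' @param m a filtered [meth_matrix()].
#' @param group1,group2 sample ids (or column indices) of the two groups.
#' @param window_bp smoothing window (bp).
#' @param m0 dispersion shrinkage weight.
#' @return data.frame of DMC records with fdr column; untestable sites are
#'   dropped.  Attributes: `n_untestable`, `phi_global` (per group).
#' @export
dmc_test <- function(m, group1, group2, window_bp = 500L, m0 = 20) {
  idx1 <- if (is.character(group1)) match(group1, m$samples) else group1
  idx2 <- if (is.character(group2)) match(group2, m$samples) else group2
  if (anyNA(idx1) || anyNA(idx2)) stop("unknown sample id in group")
  sm <- smooth_methylation(m, window_bp)
  e1 <- estimate_group_dispersion(m, sm, idx1, m0 = m0)
  e2 <- estimate_group_dispersion(m, sm, idx2, m0 = m0)
  res <- dmc_wald_test(e1, e2, m$chrom, m$pos)
  n_unt <- sum(is.na(res$pval))
  res <- res[!is.na(res$pval), , drop = FALSE]
  res$fdr <- bh_fdr(res$pval)
  rownames(res) <- NULL
  attr(res, "n_untestable") <- n_unt
  attr(res, "phi_global") <- c(attr(e1, "phi_global"),
                               attr(e2, "phi_global"))
  res
}
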