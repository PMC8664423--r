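# Seedable synthetic bisulfite-count generator with planted ground truth.
#
# Emulates the statistical structure of sperm/liver WGBS count data:
# bimodal CpG methylation (most sites highly methylated, a small fraction
# unmethylated), regional autocorrelation of baseline methylation,
# moderate coverage, beta-binomial overdispersion, planted DMRs with a
# hypo-methylation bias in the focal group, trait-linked co-methylation
# modules, and family-structured growth phenotypes.

#' Synthetic data configuration
#'
#' Defaults reproduce the study conditions the package is benchmarked
#' under: 8 samples per group in 4 families, mean coverage 8.3x capped at
#' 20x, beta-binomial dispersion 0.1, a two-plus-one-component Beta
#' mixture giving ~5% unmethylated and ~91% highly methylated CpGs,
#' planted DMR effects uniform on 0.08-0.70 (mean 0.39) with a 2:1
#' hypo:hyper bias, and a module-trait correlation of 0.69 on the
#' condition factor at n = 16.
#'
#' @param ... overrides for any default field.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_chrom = 2L,
    chrom_len_bp = 1e6,
    cpg_spacing_mean_bp = 100,
    island_gap_mean_bp = 30,
    island_enter = 0.01, island_exit = 0.05,
    n_samples_per_group = 8L,
    n_families_per_group = 4L,
    tissue = "liver",
    coverage_mean = 8.3,
    coverage_max = 20L,
    frac_low = 0.05, frac_high = 0.91,
    low_shape = c(0.3, 15), high_shape = c(30, 2), mid_shape = c(2, 2),
    phi = 0.1,
    block_bp = 500,
    n_dmrs = 50L,
    dmr_effect_range = c(0.08, 0.70),
    dmr_n_cpg = c(6L, 12L),
    hypo_fraction = 2 / 3,
    n_modules = 3L,
    module_size = 30L,
    module_amp = 0.3,
    n_noise_windows = 50L,
    module_trait_r = 0.69,
    trait_module = 1L,
    length_mean = 65.2, length_sd = 6.6,
    condition_mean = 1.20, condition_sd = 0.06,
    group_length_shift = 2.0,
    family_var_share = 0.3,
    gene_len_bp = 4000, gene_gap_mean_bp = 12000,
    n_go_terms = 30L,
    seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(cfg$hypo_fraction >= 0, cfg$hypo_fraction <= 1,
            cfg$frac_low >= 0, cfg$frac_high >= 0,
            cfg$frac_low + cfg$frac_high <= 1,
            abs(cfg$module_trait_r) < 1)
  class(cfg) <- "sim_config"
  cfg
}

draw_baseline_mu <- function(n, cfg) {
  comp <- sample(c("low", "high", "mid"), n, replace = TRUE,
                 prob = c(cfg$frac_low, cfg$frac_high,
                          1 - cfg$frac_low - cfg$frac_high))
  mu <- numeric(n)
  for (cp in c("low", "high", "mid")) {
    i <- comp == cp
    sh <- cfg[[paste0(cp, "_shape")]]
    mu[i] <- rbeta(sum(i), sh[1], sh[2])
  }
  pmin(pmax(mu, 0.001), 0.999)
}

#' Simulate the CpG backbone, gene models and a toy GO mapping
#'
#' CpG positions follow exponential inter-site gaps modulated by a
#' two-state (CpG-island vs background) Markov chain, reproducing the
#' clustered spacing of real vertebrate CpGs: island stretches have mean
#' gap `island_gap_mean_bp`, the background mean gap is derived so that
#' the overall mean spacing equals `cpg_spacing_mean_bp`.  Genes are tiled
#' with exponential gaps and each receives 1-5 terms from a toy
#' vocabulary.
#'
#' @param cfg a [sim_config()].
#' @return list with `cpg` (data.frame chrom, pos), `chrom_lengths`
#'   (named vector), `genes` (data.frame gene_id, chrom, start, end,
#'   strand) and `gene2go` (named list).
#' @export
simulate_backbone_and_genes <- function(cfg) {
  set.seed(cfg$seed)
  chroms <- sprintf("chr%d", seq_len(cfg$n_chrom))
  island_frac <- cfg$island_enter / (cfg$island_enter + cfg$island_exit)
  bg_mean <- (cfg$cpg_spacing_mean_bp -
                island_frac * cfg$island_gap_mean_bp) / (1 - island_frac)
  if (bg_mean <= 0) stop("island_gap_mean_bp too large for target spacing")
  cpg <- do.call(rbind, lapply(chroms, function(ch) {
    ngap <- ceiling(2 * cfg$chrom_len_bp / cfg$cpg_spacing_mean_bp)
    flip <- runif(ngap)
    state <- logical(ngap)                  # TRUE = island
    s <- runif(1) < island_frac
    for (i in seq_len(ngap)) {
      s <- if (s) flip[i] >= cfg$island_exit else flip[i] < cfg$island_enter
      state[i] <- s
    }
    gaps <- rexp(ngap, rate = 1 / ifelse(state, cfg$island_gap_mean_bp,
                                         bg_mean))
    pos <- cumsum(pmax(2, round(gaps)))
    pos <- pos[pos < cfg$chrom_len_bp]
    data.frame(chrom = ch, pos = as.integer(pos))
  }))
  genes <- do.call(rbind, lapply(chroms, function(ch) {
    starts <- integer(); at <- 0
    repeat {
      at <- at + round(rexp(1, 1 / cfg$gene_gap_mean_bp))
      if (at + cfg$gene_len_bp >= cfg$chrom_len_bp) break
      starts <- c(starts, at)
      at <- at + cfg$gene_len_bp
    }
    if (length(starts) == 0L) return(NULL)
    data.frame(chrom = ch, start = as.integer(starts),
               end = as.integer(starts + cfg$gene_len_bp))
  }))
  genes$gene_id <- sprintf("gene_%04d", seq_len(nrow(genes)))
  genes$strand <- sample(c("+", "-"), nrow(genes), replace = TRUE)
  genes <- genes[, c("gene_id", "chrom", "start", "end", "strand")]
  vocab <- sprintf("GO:%07d", seq_len(cfg$n_go_terms))
  gene2go <- lapply(seq_len(nrow(genes)), function(i)
    sample(vocab, sample(1:5, 1)))
  names(gene2go) <- genes$gene_id
  list(cpg = cpg,
       chrom_lengths = setNames(rep(cfg$chrom_len_bp, cfg$n_chrom),
                                chroms),
       genes = genes, gene2go = gene2go)
}

rbetabinom <- function(n, size, mu, phi) {
  a <- mu * (1 - phi) / phi
  b <- (1 - mu) * (1 - phi) / phi
  p <- rbeta(n, a, b)
  rbinom(n, size, p)
}

# pick `k` disjoint runs of consecutive CpGs, avoiding flagged sites;
# `max_gap` restricts runs to stretches whose internal inter-CpG gaps do
# not exceed it (planted regions must be representable under the DMR
# definition, whose clustering rule caps gaps between significant CpGs)
pick_runs <- function(cpg, k, len_range, forbidden, max_gap = Inf) {
  n <- nrow(cpg)
  used <- forbidden
  runs <- vector("list", k)
  tries <- 0
  for (r in seq_len(k)) {
    repeat {
      tries <- tries + 1
      if (tries > 500 * k)
        stop("cannot place requested regions: genome too small")
      len <- sample(seq(len_range[1], len_range[2]), 1)
      s <- sample.int(n - len + 1L, 1L)
      idx <- s:(s + len - 1L)
      if (length(unique(cpg$chrom[idx])) > 1L) next
      if (any(used[idx])) next
      if (is.finite(max_gap) && any(diff(cpg$pos[idx]) > max_gap)) next
      used[idx] <- TRUE
      runs[[r]] <- idx
      break
    }
  }
  runs
}

#' Simulate two-group bisulfite count tables with planted truth
#'
#' Baseline methylation is block-constant over `block_bp` stretches with
#' levels drawn from the configured bimodal Beta mixture.  Planted DMRs
#' shift the focal group's mean by the planted effect (hypo with
#' probability `hypo_fraction`); planted co-methylation modules impose a
#' shared per-sample latent signal on scattered 100-bp windows; additional
#' "noise" windows receive independent per-sample levels so that the
#' network has variable background windows.  Coverage is
#' `1 + Poisson(coverage_mean - 1)` capped at `coverage_max`; methylated
#' counts are beta-binomial with dispersion `phi`.
#'
#' @param backbone output of [simulate_backbone_and_genes()].
#' @param cfg a [sim_config()].
#' @return list with `tables` (named list of per-sample count
#'   data.frames), `meta` (sample metadata), and `truth` (planted DMRs,
#'   module windows, per-sample module latents, family map).
#' @export
simulate_counts <- function(backbone, cfg) {
  set.seed(cfg$seed + 1L)
  cpg <- backbone$cpg
  n <- nrow(cpg)
  n_per <- cfg$n_samples_per_group
  ids <- c(sprintf("sas_%02d", seq_len(n_per)),
           sprintf("wild_%02d", seq_len(n_per)))
  group <- rep(c("SAS", "wild"), each = n_per)
  family <- paste0(rep(c("sasF", "wildF"), each = n_per),
                   rep_len(seq_len(cfg$n_families_per_group), n_per))
  nsamp <- length(ids)

  # baseline: block-constant bimodal mixture
  block <- paste(cpg$chrom, cpg$pos %/% cfg$block_bp)
  ub <- unique(block)
  mu_block <- draw_baseline_mu(length(ub), cfg)
  mu0 <- mu_block[match(block, ub)]

  # planted module + noise windows (100 bp tiles with >= 3 CpGs)
  win_id <- paste(cpg$chrom, cpg$pos %/% 100L)
  win_count <- table(win_id)
  eligible <- names(win_count)[win_count >= 3]
  used_site <- rep(FALSE, n)
  n_mod_win <- cfg$n_modules * cfg$module_size + cfg$n_noise_windows
  if (n_mod_win > length(eligible))
    stop("not enough eligible windows for requested modules")
  chosen <- sample(eligible, n_mod_win)
  mod_of_win <- c(rep(seq_len(cfg$n_modules), each = cfg$module_size),
                  rep(0L, cfg$n_noise_windows))
  site_win <- match(win_id, chosen)          # NA when not a chosen window
  used_site <- !is.na(site_win)

  latents <- matrix(rnorm(nsamp * cfg$n_modules), nsamp, cfg$n_modules,
                    dimnames = list(ids, NULL))
  latents <- scale(latents)                  # standardized per module

  # per-(site, sample) mean methylation
  mu <- matrix(rep(mu0, nsamp), n, nsamp, dimnames = list(NULL, ids))
  for (w in seq_along(chosen)) {
    idx <- which(site_win == w)
    mod <- mod_of_win[w]
    if (mod > 0) {
      lam <- runif(1, 0.8, 1) * cfg$module_amp
      base_w <- runif(1, 0.35, 0.65)
      mu[idx, ] <- rep(pmin(pmax(base_w + lam * latents[, mod],
                                 0.02), 0.98),
                       each = length(idx))
    } else {
      mu[idx, ] <- rep(pmin(pmax(rbeta(nsamp, 0.6, 0.6), 0.02), 0.98),
                       each = length(idx))
    }
  }

  # planted DMRs on runs of consecutive CpGs, away from planted windows
  dmr_truth <- NULL
  if (cfg$n_dmrs > 0) {
    runs <- pick_runs(cpg, cfg$n_dmrs, cfg$dmr_n_cpg, used_site,
                      max_gap = 100)
    effect <- runif(cfg$n_dmrs, cfg$dmr_effect_range[1],
                    cfg$dmr_effect_range[2])
    hypo <- runif(cfg$n_dmrs) < cfg$hypo_fraction
    g1 <- group == "SAS"
    dmr_truth <- do.call(rbind, lapply(seq_len(cfg$n_dmrs), function(r) {
      idx <- runs[[r]]
      if (hypo[r]) {
        base <- runif(1, min(effect[r] + 0.04, 0.95), 0.97)
        mu_sas <- base - effect[r]
      } else {
        base <- runif(1, 0.02, max(0.97 - effect[r], 0.03))
        mu_sas <- base + effect[r]
      }
      mu[idx, !g1] <<- base
      mu[idx, g1] <<- pmin(pmax(mu_sas, 0.01), 0.99)
      data.frame(chrom = cpg$chrom[idx[1]], start = cpg$pos[idx[1]],
                 end = cpg$pos[idx[length(idx)]] + 1L,
                 n_cpg = length(idx),
                 effect = ifelse(hypo[r], -effect[r], effect[r]),
                 direction = ifelse(hypo[r], "hypo", "hyper"))
    }))
    dmr_truth <- dmr_truth[order(dmr_truth$chrom, dmr_truth$start), ]
    rownames(dmr_truth) <- NULL
  }

  # coverage and beta-binomial counts
  total <- matrix(pmin(1L + rpois(n * nsamp, cfg$coverage_mean - 1),
                       cfg$coverage_max), n, nsamp)
  meth <- matrix(rbetabinom(n * nsamp, as.vector(total), as.vector(mu),
                            cfg$phi), n, nsamp)
  tables <- lapply(seq_len(nsamp), function(j)
    data.frame(chrom = cpg$chrom, pos = cpg$pos,
               n_meth = meth[, j], n_total = total[, j]))
  names(tables) <- ids
  meta <- data.frame(sample_id = ids, group = group, tissue = cfg$tissue,
                     family = family)

  mod_windows <- data.frame(
    chrom = sub(" .*", "", chosen),
    start = as.integer(sub(".* ", "", chosen)) * 100L,
    module = mod_of_win)
  mod_windows$end <- mod_windows$start + 100L
  mod_windows <- mod_windows[, c("chrom", "start", "end", "module")]
  mod_windows <- mod_windows[order(mod_windows$chrom, mod_windows$start), ]
  rownames(mod_windows) <- NULL

  list(tables = tables, meta = meta,
       truth = list(dmrs = dmr_truth, module_windows = mod_windows,
                    latents = latents,
                    family = setNames(family, ids)))
}

#' Simulate family-structured growth phenotypes linked to a module
#'
#' Length gets a family intercept plus Gaussian noise around the
#' configured mean/SD (with a small group shift); the condition factor is
#' generated as `condition_mean + condition_sd * z` where `z` mixes the
#' planted module latent (population correlation `module_trait_r`) with
#' family-structured noise; weight is derived so that Fulton's condition
#' factor of the emitted (weight, length) pairs equals the generated
#' condition exactly.
#'
#' @param cfg a [sim_config()].
#' @param truth the `truth` element of [simulate_counts()].
#' @param meta sample metadata from [simulate_counts()].
#' @return data.frame of phenotype records (sample_id, family, group,
#'   length_mm, weight_g, condition_k).
#' @export
simulate_phenotypes <- function(cfg, truth, meta) {
  set.seed(cfg$seed + 2L)
  nsamp <- nrow(meta)
  fams <- unique(meta$family)
  share <- cfg$family_var_share
  fam_len <- setNames(rnorm(length(fams), 0, sqrt(share) * cfg$length_sd),
                      fams)
  length_mm <- cfg$length_mean +
    ifelse(meta$group == "SAS", cfg$group_length_shift / 2,
           -cfg$group_length_shift / 2) +
    fam_len[meta$family] +
    rnorm(nsamp, 0, sqrt(1 - share) * cfg$length_sd)
  r <- cfg$module_trait_r
  s <- if (ncol(truth$latents) >= cfg$trait_module)
    as.vector(truth$latents[, cfg$trait_module]) else rep(0, nsamp)
  fam_k <- setNames(rnorm(length(fams)), fams)
  e <- sqrt(share) * fam_k[meta$family] +
    sqrt(1 - share) * rnorm(nsamp)
  z <- r * s + sqrt(1 - r^2) * e
  condition_k <- cfg$condition_mean + cfg$condition_sd * z
  weight_g <- condition_k * (length_mm / 10)^3 / 100
  data.frame(sample_id = meta$sample_id, family = meta$family,
             group = meta$group, length_mm = length_mm,
             weight_g = weight_g, condition_k = condition_k)
}

#' Simulate a complete dataset
#'
#' Runs [simulate_backbone_and_genes()], [simulate_counts()] and
#' [simulate_phenotypes()] under one seed and returns everything the
#' pipeline consumes plus the planted truth.
#'
#' @param cfg a [sim_config()].
#' @return list: tables, meta (with phenotype columns), chrom_lengths,
#'   genes, gene2go, phenotypes, truth.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  bb <- simulate_backbone_and_genes(cfg)
  cnt <- simulate_counts(bb, cfg)
  ph <- simulate_phenotypes(cfg, cnt$truth, cnt$meta)
  meta <- merge(cnt$meta, ph[, c("sample_id", "length_mm", "weight_g",
                                 "condition_k")], by = "sample_id",
                sort = FALSE)
  list(tables = cnt$tables, meta = meta,
       chrom_lengths = bb$chrom_lengths,
       genes = bb$genes, gene2go = bb$gene2go,
       phenotypes = ph, truth = cnt$truth)
}

#' Write a simulated dataset to disk in the pipeline's input formats
#'
#' Emits one MethylDackel-style bedGraph per sample, a metadata TSV, a
#' genes TSV, a gene-to-term TSV and a ground-truth JSON.
#'
#' @param ds output of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(ds$tables))
    write_site_counts(ds$tables[[id]],
                      file.path(dir, paste0(id, ".bedGraph")))
  write.table(ds$meta, file.path(dir, "samples.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(ds$genes, file.path(dir, "genes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  g2g <- data.frame(gene = rep(names(ds$gene2go), lengths(ds$gene2go)),
                    term = unlist(ds$gene2go, use.names = FALSE))
  write.table(g2g, file.path(dir, "gene2go.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  truth <- ds$truth
  truth$latents <- apply(truth$latents, 2, identity, simplify = FALSE)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
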