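# Config-driven orchestration of the full analysis: filtering, DMC/DMR
# calling, direction bias, annotation and enrichment, co-methylation
# network, phenotype statistics, and a machine-readable run summary.

#' Default pipeline parameters
#'
#' All tunables of every stage, namespaced per stage, with defaults set to
#' the analysis conventions the package implements (coverage window 5-20x
#' in >= 75% of samples, 500-bp smoothing, DMC p < 0.001, DMR rules
#' 50 bp / 4 CpGs / >50% significant, 5-kb gene flank, 100-bp network
#' windows with variance > 0.05, soft power 18).
#'
#' @param ... overrides as `stage.key = value` (e.g. `dmr.min_cpg = 5`).
#' @return nested list of parameters.
#' @export
pipeline_params <- function(...) {
  p <- list(
    filter = list(min_cov = 5L, max_cov = 20L, min_frac_samples = 0.75,
                  min_contig_len = 10000L),
    dmc = list(window_bp = 500L, m0 = 20),
    dmr = list(p_threshold = 0.001, min_len = 50L, min_cpg = 4L,
               pct_sig = 0.5, merge_gap_bp = 100L),
    annotate = list(flank_bp = 5000L),
    network = list(window_bp = 100L, min_cpg = 3L, min_var = 0.05,
                   power = 18, min_module_size = 10L, merge_corr = 0.75,
                   max_block = 30000L, cut_height = 0.99,
                   n_perm = 1000L),
    pheno = list(traits = c("length_mm", "weight_g", "condition_k")))
  over <- list(...)
  for (key in names(over)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (length(parts) != 2 || is.null(p[[parts[1]]]) ||
        !parts[2] %in% names(p[[parts[1]]]))
      stop("unknown parameter: ", key)
    p[[parts[1]]][[parts[2]]] <- over[[key]]
  }
  p
}

#' Load pipeline parameters from a YAML config file
#'
#' Keys are namespaced per stage as in [pipeline_params()]; values present
#' in the file override the defaults.
#'
#' @param path YAML file.
#' @return nested parameter list.
#' @export
read_params_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  p <- pipeline_params()
  for (stage in intersect(names(cfg), names(p)))
    for (key in intersect(names(cfg[[stage]]), names(p[[stage]])))
      p[[stage]][[key]] <- cfg[[stage]][[key]]
  p
}

#' Read a dataset directory in the formats written by [write_dataset()]
#'
#' @param dir directory containing `*.bedGraph`, `samples.tsv`,
#'   `genes.tsv`, `gene2go.tsv`.
#' @param chrom_lengths named vector of contig lengths (optional;
#'   contig-length filtering is skipped when NULL).
#' @return list usable as the `ds` argument of [run_pipeline()].
#' @export
read_dataset <- function(dir, chrom_lengths = NULL) {
  meta <- read_sample_meta(file.path(dir, "samples.tsv"))
  tables <- lapply(meta$sample_id, function(id)
    read_site_counts(file.path(dir, paste0(id, ".bedGraph"))))
  names(tables) <- meta$sample_id
  genes_path <- file.path(dir, "genes.tsv")
  genes <- if (file.exists(genes_path)) read_genes(genes_path) else NULL
  g2g_path <- file.path(dir, "gene2go.tsv")
  gene2go <- if (file.exists(g2g_path)) read_gene2go(g2g_path) else NULL
  ph <- intersect(c("length_mm", "weight_g", "condition_k"), names(meta))
  list(tables = tables, meta = meta, chrom_lengths = chrom_lengths,
       genes = genes, gene2go = gene2go,
       phenotypes = if (length(ph)) meta[, c("sample_id", "family",
                                             "group", ph)] else NULL)
}

#' Run the full analysis
#'
#' Assembles the count matrix, applies variant masking and site filters,
#' tests every CpG for differential methylation between the two groups,
#' calls DMRs, computes the direction-bias binomial test, annotates DMRs
#' with nearby genes and tests functional enrichment, builds the
#' co-methylation network with module-trait statistics and DMR-overlap
#' resampling, summarizes phenotypes with family-controlled ANOVA, and
#' returns (optionally writes) all stage outputs plus a summary.
#'
#' @param ds dataset list: `tables`, `meta`, and optionally
#'   `chrom_lengths`, `variants`, `genes`, `gene2go`, `phenotypes` (as
#'   produced by [simulate_dataset()] or [read_dataset()]).
#' @param params nested parameter list from [pipeline_params()].
#' @param group_levels character(2): focal and reference group labels.
#' @param seed integer seed for the permutation stages.
#' @param out_dir optional output directory; when given, stage outputs are
#'   written (TSV/BED/JSON).
#' @return list with elements `dmc`, `dmrs`, `direction`, `annotation`,
#'   `enrichment`, `network`, `pheno`, `summary`.
#' @export
run_pipeline <- function(ds, params = pipeline_params(),
                         group_levels = c("SAS", "wild"),
                         seed = 1L, out_dir = NULL) {
  stage <- "assemble"
  res <- tryCatch({
    m <- build_matrix(ds$tables, ds$meta)
    if (!is.null(ds$variants)) {
      stage <- "mask_variants"
      m <- mask_variant_sites(m, ds$variants)
    }
    stage <- "filter"
    fp <- params$filter
    m <- filter_sites(m, min_cov = fp$min_cov, max_cov = fp$max_cov,
                      min_frac_samples = fp$min_frac_samples,
                      chrom_lengths = ds$chrom_lengths,
                      min_contig_len = fp$min_contig_len)
    stage <- "dmc"
    g1 <- ds$meta$sample_id[ds$meta$group == group_levels[1]]
    g2 <- ds$meta$sample_id[ds$meta$group == group_levels[2]]
    if (length(g1) == 0 || length(g2) == 0)
      stop("both groups must have samples")
    dmc <- dmc_test(m, g1, g2, window_bp = params$dmc$window_bp,
                    m0 = params$dmc$m0)
    stage <- "dmr"
    dp <- params$dmr
    dmrs <- call_dmrs(dmc, p_threshold = dp$p_threshold,
                      min_len = dp$min_len, min_cpg = dp$min_cpg,
                      pct_sig = dp$pct_sig,
                      merge_gap_bp = dp$merge_gap_bp)
    n_hypo <- sum(dmrs$direction == "hypo")
    direction <- list(
      n_hypo = n_hypo, n_hyper = nrow(dmrs) - n_hypo,
      n_total = nrow(dmrs),
      p = if (nrow(dmrs) > 0)
        direction_bias_test(n_hypo, nrow(dmrs)) else NA_real_)

    stage <- "annotate"
    annotation <- NULL; enrichment <- NULL
    if (!is.null(ds$genes) && nrow(dmrs) > 0) {
      annotation <- assign_genes_to_regions(dmrs, ds$genes,
                                            params$annotate$flank_bp)
      if (!is.null(ds$gene2go)) {
        study <- unique(unlist(annotation))
        enrichment <- go_fisher_enrichment(study, ds$genes$gene_id,
                                           ds$gene2go)
      }
    }

    stage <- "network"
    np <- params$network
    wm <- summarize_windows(m, window_bp = np$window_bp,
                            min_cpg = np$min_cpg, min_var = np$min_var)
    network <- NULL
    if (nrow(wm$windows) >= 2 * np$min_module_size) {
      labels <- detect_modules(wm$values, power = np$power,
                               min_module_size = np$min_module_size,
                               merge_corr = np$merge_corr,
                               max_block = np$max_block,
                               cut_height = np$cut_height)
      me <- if (any(labels != 0))
        module_eigenvectors(wm$values, labels) else NULL
      mt <- NULL; gs <- NULL; enr <- NULL; mmgs <- NULL
      if (!is.null(me) && !is.null(ds$phenotypes)) {
        traits <- ds$phenotypes[match(m$samples,
                                      ds$phenotypes$sample_id),
                                params$pheno$traits, drop = FALSE]
        ta <- trait_association(me$eigenvectors, traits, wm$values)
        mt <- ta$module_trait; gs <- ta$gs
        flags <- window_dmr_overlap(wm$windows, dmrs)
        sig_modules <- unique(mt$module[mt$retained])
        enr <- lapply(sig_modules, function(md)
          module_dmr_enrichment(which(labels == md), flags,
                                n_perm = np$n_perm, seed = seed + md))
        names(enr) <- as.character(sig_modules)
        mmgs <- lapply(sig_modules, function(md) {
          idx <- which(labels == md)
          tr1 <- mt$trait[mt$module == md & mt$retained][1]
          mm_gs_comparison(me$mm[idx], gs[idx, tr1], flags[idx])
        })
        names(mmgs) <- as.character(sig_modules)
      }
      network <- list(windows = wm$windows, values = wm$values,
                      labels = labels,
                      eigenvectors = me$eigenvectors, mm = me$mm,
                      module_trait = mt, gs = gs,
                      dmr_enrichment = enr, mm_gs = mmgs)
    }

    stage <- "pheno"
    pheno <- NULL
    if (!is.null(ds$phenotypes)) {
      recs <- ds$phenotypes
      anovas <- lapply(params$pheno$traits, function(tr)
        tryCatch(family_anova(recs, tr), error = function(e) NULL))
      names(anovas) <- params$pheno$traits
      pheno <- list(summary = phenotype_summary(recs,
                                                params$pheno$traits),
                    anova = anovas)
    }

    summary <- list(
      tested_sites = nrow(dmc),
      n_dmc = sum(dmc$pval < params$dmr$p_threshold),
      n_dmr = nrow(dmrs),
      n_hypo = direction$n_hypo, n_hyper = direction$n_hyper,
      binomial_p = direction$p,
      n_modules = if (is.null(network)) 0L else
        length(unique(network$labels[network$labels != 0])),
      n_sig_modules = if (is.null(network) ||
                          is.null(network$module_trait)) 0L else
        length(unique(network$module_trait$module[
          network$module_trait$retained])),
      seed = seed)

    list(matrix = m, dmc = dmc, dmrs = dmrs, direction = direction,
         annotation = annotation, enrichment = enrichment,
         network = network, pheno = pheno, summary = summary)
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

#' Write pipeline stage outputs to a directory
#'
#' @param res result of [run_pipeline()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.table(res$dmc, file.path(out_dir, "dmc.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  dmrs <- res$dmrs
  if (nrow(dmrs) > 0) {
    bed <- data.frame(chrom = dmrs$chrom, start = dmrs$start,
                      end = dmrs$end,
                      name = sprintf("DMR_%04d", seq_len(nrow(dmrs))),
                      score = round(1000 * abs(dmrs$mean_diff)),
                      strand = ".",
                      mean_diff = dmrs$mean_diff,
                      direction = dmrs$direction, n_cpg = dmrs$n_cpg)
    write_regions_bed(bed, file.path(out_dir, "dmrs.bed"))
  } else file.create(file.path(out_dir, "dmrs.bed"))
  if (!is.null(res$enrichment))
    write.table(res$enrichment, file.path(out_dir, "enrichment.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$network)) {
    nw <- cbind(res$network$windows, module = res$network$labels,
                mm = res$network$mm)
    write.table(nw, file.path(out_dir, "network_windows.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(res$network$module_trait))
      write.table(res$network$module_trait,
                  file.path(out_dir, "module_trait.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(res$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
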