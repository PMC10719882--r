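#' Write a delimited table with provenance header comments
#'
#' Every pipeline output is tab-delimited with `#`-prefixed header lines
#' recording the tool version plus any caller-supplied metadata (config
#' hash, seed, stage). Numeric columns are formatted with `%.10g` so
#' identical runs produce bit-identical files.
#'
#' @param tab data frame.
#' @param path output file.
#' @param meta named character vector of extra header fields.
#' @return `path`, invisibly.
#' @export
write_table_with_header <- function(tab, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# sparsegwa ", .sparsegwa_version()), con)
  if (!is.null(meta))
    writeLines(paste0("# ", names(meta), ": ", unname(meta)), con)
  out <- tab
  for (j in seq_along(out))
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- sprintf("%.10g", out[[j]])
  writeLines(paste(colnames(out), collapse = "\t"), con)
  if (nrow(out))
    writeLines(do.call(paste, c(unname(as.list(out)), sep = "\t")), con)
  invisible(path)
}

#' Default run configuration
#'
#' A single declarative list controlling every pipeline stage; serialize
#' with [write_run_config] / [read_run_config] (YAML). Fields are grouped
#' per stage: input paths (or `simulate: yes`), SNP filters, pruning
#' geometry, PC count, LMM threshold settings, subset fractions, BSLMM
#' schedule and the base seed.
#'
#' @param ... named overrides of the defaults, e.g.
#'   `run_config(seed = 7, bslmm = list(chains = 3))`; list-valued fields
#'   are merged element-wise.
#' @return list of class `"run_config"`.
#' @export
run_config <- function(...) {
  cfg <- list(
    seed = 1,
    simulate = TRUE,
    sim = list(n_samples = 300, n_snps = 1000, n_blocks = 20,
               within_block_r = 0.8, maf_range = c(0.05, 0.5),
               inbreeding = 0.95, n_causal_sparse = 10, pve_target = 0.5,
               pge_target = 0.8),
    filters = list(maf_min = 0.05, het_max = 0.10, miss_max = 1),
    prune = list(window_snps = 50, step_snps = 5, threshold = 0.8),
    n_pcs = 4,
    thresholds = list(mode = "block-count", variance_fraction = 0.995,
                      alpha = 0.05, block_dprime = 0.8),
    subsets = list(fraction = 0.01),
    bslmm = list(burn_in = 10000, steps = 100000, record_pace = 10,
                 chains = 3, smax = 300),
    pip_threshold = 0.1,
    flank_bp = 0)
  ov <- list(...)
  for (nm in names(ov)) {
    if (is.list(ov[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]][names(ov[[nm]])] <- ov[[nm]]
    else cfg[[nm]] <- ov[[nm]]
  }
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param path YAML file.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' @rdname run_config
#' @param config `run_config` object.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(config), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full association workflow
#'
#' filter -> kinship / pruning / structure PCs -> LMM scan -> Gao-corrected
#' thresholds -> ranked SNP subsets -> BSLMM (genome-wide and per subset)
#' -> candidate pathway association (when a pathway is configured) ->
#' summary tables. Every stage writes its outputs under `out_dir` with
#' provenance headers; a config snapshot sits next to them, and rerunning
#' with an identical config produces bit-identical files.
#'
#' @param config [run_config] object.
#' @param out_dir output directory (created if needed).
#' @return invisible list with all fitted objects and the output paths.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- .config_hash(config)
  meta <- c(config_hash = hash, seed = as.character(config$seed))
  log_lines <- character()
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    message(line)
    log_lines <<- c(log_lines, line)
  }
  write_run_config(config, file.path(out_dir, "config.yaml"))

  # ---- stage: input ----
  if (isTRUE(config$simulate)) {
    sim_cfg <- do.call(sim_config, c(config$sim, list(seed = config$seed)))
    G <- simulate_genotypes(sim_cfg)
    sim <- simulate_phenotype(G, sim_cfg)
    y <- sim$phenotype
    truth <- sim$truth
    write_table_with_header(
      data.frame(id = truth$causal_ids, beta = truth$beta),
      file.path(out_dir, "sim_truth.tsv"),
      c(meta, realized_pve = sprintf("%.10g", truth$realized_pve),
        realized_pge = sprintf("%.10g", truth$realized_pge)))
  } else {
    if (is.null(config$vcf) || is.null(config$phenotype))
      stop("config must supply vcf and phenotype paths when simulate is off")
    G <- read_vcf(config$vcf)
    y <- read_phenotype(config$phenotype)
    truth <- NULL
  }
  al <- align_samples(G, y)
  G <- al$genotypes; y <- al$phenotype
  say("input: %d samples x %d SNPs", length(G$samples), nrow(G$snps))

  # ---- stage: filter + impute ----
  G <- filter_snps(G, config$filters$maf_min, config$filters$het_max,
                   config$filters$miss_max)
  rem <- attr(G, "removed")
  say("filter: %d SNPs retained (removed maf=%d het=%d missing=%d)",
      nrow(G$snps), rem["maf"], rem["het"], rem["missing"])
  G <- impute_missing_mean(G)

  # ---- stage: relatedness ----
  K <- centered_kinship(G)
  ktab <- as.data.frame(K)
  write_table_with_header(cbind(sample = rownames(K), ktab),
                          file.path(out_dir, "kinship.tsv"), meta)
  pruned_idx <- prune_by_dprime(G, config$prune$window_snps,
                                config$prune$step_snps,
                                config$prune$threshold)
  say("prune: %d of %d SNPs retained as independent set", length(pruned_idx),
      nrow(G$snps))
  writeLines(c(paste0("# sparsegwa ", .sparsegwa_version()),
               paste0("# config_hash: ", hash),
               G$snps$id[pruned_idx]),
             file.path(out_dir, "pruned_snps.txt"))
  W <- pca_covariates(G[, pruned_idx], k = config$n_pcs)
  write_table_with_header(cbind(sample = rownames(W), as.data.frame(W)),
                          file.path(out_dir, "covariates.tsv"), meta)

  # ---- stage: LMM ----
  scan <- lmm_gwas(G, y, K = K, W = W)
  write_scan(scan, file.path(out_dir, "lmm_assoc.tsv"), meta)
  blocks <- infer_blocks(G, config$thresholds$block_dprime)
  thr <- gao_meff(G, blocks, mode = config$thresholds$mode,
                  variance_fraction = config$thresholds$variance_fraction,
                  alpha = config$thresholds$alpha)
  say("thresholds: m_eff = %d (%s), significant -log10 P = %.3f", thr$m_eff,
      thr$mode, thr$significant_logp)

  # ---- stage: subsets ----
  sub_p <- subset_by_rank(scan, config$subsets$fraction, "lowest_p")
  sub_b <- subset_by_rank(scan, config$subsets$fraction, "largest_abs_beta")
  sub_u <- subset_union(sub_p, sub_b)
  subsets <- list(sub_p, sub_b, sub_u)
  for (s in subsets) {
    writeLines(c(paste0("# sparsegwa ", .sparsegwa_version()),
                 paste0("# config_hash: ", hash), s$snp_ids),
               file.path(out_dir, paste0("subset_", s$name, ".txt")))
    say("subset %s: %d SNPs", s$name, length(s$snp_ids))
  }

  # ---- stage: BSLMM (genome-wide + per subset) ----
  bs_args <- config$bslmm
  fit_one <- function(Gx, label, seed_offset) {
    fit <- bslmm(Gx, y, K = K, W = W, burn_in = bs_args$burn_in,
                 steps = bs_args$steps, record_pace = bs_args$record_pace,
                 chains = bs_args$chains, seed = config$seed + seed_offset,
                 smax = bs_args$smax)
    write_bslmm_hyp(fit, file.path(out_dir, paste0("bslmm_", label, ".hyp.tsv")),
                    c(meta, analysis = label))
    write_bslmm_param(fit, file.path(out_dir, paste0("bslmm_", label,
                                                     ".param.tsv")),
                      c(meta, analysis = label))
    say("bslmm %s: %d SNPs, %d chains", label, ncol(Gx$dosages),
        bs_args$chains)
    fit
  }
  fits <- list(GWA = fit_one(G, "GWA", 100))
  for (s in subsets)
    fits[[s$name]] <- fit_one(G[, s$snp_ids], s$name,
                              100 + 10 * length(fits))

  # ---- stage: CPA ----
  cpa <- NULL
  if (!is.null(config$gff) && !is.null(config$pathway_table)) {
    pathway <- read_pathway_table(config$pathway_table)
    genes <- load_pathway_genes(config$gff, pathway)
    cpa <- run_cpa(G, y, K, W, genes, thresholds = thr,
                   flank_bp = config$flank_bp,
                   bslmm_args = c(bs_args,
                                  list(seed = config$seed + 900)),
                   pip_threshold = config$pip_threshold)
    fits[["CPA"]] <- cpa$bslmm
    write_table_with_header(cpa$genes, file.path(out_dir, "cpa_genes.tsv"),
                            meta)
    write_table_with_header(cpa$major, file.path(out_dir, "cpa_major.tsv"),
                            meta)
    say("cpa: %d pathway SNPs in %d genes", length(cpa$subset$snp_ids),
        nrow(cpa$genes))
  }

  # ---- stage: report ----
  tabs <- render_tables(fits, scan, out_dir = out_dir, meta = meta)
  manh <- data.frame(chrom = scan$results$chrom, pos = scan$results$pos,
                     id = scan$results$id,
                     neg_log10_p = -log10(scan$results$p_wald))
  write_table_with_header(manh, file.path(out_dir, "manhattan_lmm.tsv"), meta)
  gw <- fits$GWA
  write_table_with_header(
    data.frame(chrom = gw$snps$chrom, pos = gw$snps$pos, id = gw$snps$id,
               pip = gw$pip, sparse_effect = sparse_effect(gw$beta_mean,
                                                           gw$pip)),
    file.path(out_dir, "manhattan_bslmm.tsv"), meta)
  writeLines(c(paste0("# sparsegwa ", .sparsegwa_version()),
               paste0("# config_hash: ", hash),
               paste0("# seed: ", config$seed), log_lines),
             file.path(out_dir, "pipeline.log"))

  invisible(list(genotypes = G, phenotype = y, kinship = K, covariates = W,
                 scan = scan, thresholds = thr, subsets = subsets,
                 bslmm = fits, cpa = cpa, tables = tabs, truth = truth,
                 out_dir = out_dir))
}

#' Publication-style summary tables
#'
#' Table 1 style: SNP heritability from the LMM null model next to the
#' BSLMM PVE of every analysis, as percentages with 2.5-97.5\% bounds.
#' Table 2 style: PGE, Rho, Pi and N.Gamma per analysis (PGE and Pi on the
#' percentage scale).
#'
#' @param fits named list of `bslmm` objects (one per analysis).
#' @param scan `lmm_scan` object supplying the LMM h2 row.
#' @param out_dir optional directory to write `table1_pve.tsv` and
#'   `table2_hyperparameters.tsv`.
#' @param meta header metadata for the written files.
#' @return list with data frames `table1` and `table2`.
#' @export
render_tables <- function(fits, scan = NULL, out_dir = NULL, meta = NULL) {
  stopifnot(length(fits) >= 1)
  smry <- lapply(fits, summary)
  pick <- function(s, par) {
    r <- s$hyperparameters[s$hyperparameters$parameter == par, ]
    c(r$estimate, r$lo, r$hi)
  }
  pct <- function(v) 100 * v
  t1 <- do.call(rbind, lapply(names(fits), function(nm) {
    v <- pick(smry[[nm]], "pve")
    data.frame(analysis = nm, method = "BSLMM",
               estimate_pct = pct(v[1]), lo_pct = pct(v[2]),
               hi_pct = pct(v[3]), stringsAsFactors = FALSE)
  }))
  if (!is.null(scan)) {
    t1 <- rbind(data.frame(analysis = "GWA", method = "LMM_h2",
                           estimate_pct = pct(scan$h2),
                           lo_pct = pct(scan$h2_ci[1]),
                           hi_pct = pct(scan$h2_ci[2]),
                           stringsAsFactors = FALSE), t1)
  }
  t2 <- do.call(rbind, lapply(names(fits), function(nm) {
    pge <- pick(smry[[nm]], "pge"); rho <- pick(smry[[nm]], "rho")
    pi <- pick(smry[[nm]], "pi"); ng <- pick(smry[[nm]], "n_gamma")
    data.frame(analysis = nm,
               pge_pct = pct(pge[1]), pge_lo = pct(pge[2]),
               pge_hi = pct(pge[3]),
               rho = rho[1], rho_lo = rho[2], rho_hi = rho[3],
               pi_pct = pct(pi[1]), pi_lo = pct(pi[2]), pi_hi = pct(pi[3]),
               n_gamma = ng[1], n_gamma_lo = ng[2], n_gamma_hi = ng[3],
               stringsAsFactors = FALSE)
  }))
  if (!is.null(out_dir)) {
    write_table_with_header(t1, file.path(out_dir, "table1_pve.tsv"), meta)
    write_table_with_header(t2, file.path(out_dir,
                                          "table2_hyperparameters.tsv"), meta)
  }
  list(table1 = t1, table2 = t2)
}
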