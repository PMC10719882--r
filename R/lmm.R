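#' Linear mixed model association scan
#'
#' Per-SNP association of a quantitative trait under
#' \deqn{y = W\alpha + x\beta + u + \epsilon,\quad u \sim N(0, \lambda\tau^{-1}K),
#'   \ \epsilon \sim N(0, \tau^{-1}I)}
#' with the variance ratio \eqn{\lambda} estimated per SNP by restricted
#' maximum likelihood on the eigenbasis of the kinship matrix (decomposed
#' once and reused for every SNP). The Wald statistic is referred to
#' F(1, n - c - 1), c = number of fixed-effect columns including the SNP.
#'
#' @param G genotypes object, no missing dosages.
#' @param y named phenotype vector aligned to `G` (see [align_samples]).
#' @param K kinship matrix (default: [centered_kinship] of `G`). Must be
#'   symmetric and positive semidefinite up to numerical tolerance.
#' @param W fixed-effect covariate matrix with leading intercept column
#'   (default intercept only); see [pca_covariates].
#' @param lambda fix the variance ratio instead of estimating it per SNP
#'   (mainly for validation against generalized least squares); `NULL`
#'   (default) estimates by REML.
#' @param lambda_bounds REML search range for `lambda` (default `1e-5` to
#'   `1e5`), scanned on a 100-point log grid before golden-section
#'   refinement.
#' @return object of class `"lmm_scan"`: list with `results` (data frame:
#'   chrom, pos, id, maf, beta, se, p_wald, lambda), the null-model
#'   heritability estimate `h2` with its interval, and bookkeeping fields.
#' @seealso [gao_meff] for significance thresholds, [subset_by_rank] for
#'   the ranked SNP subsets fed to the sparse model.
#' @export
lmm_gwas <- function(G, y, K = NULL, W = NULL, lambda = NULL,
                     lambda_bounds = c(1e-5, 1e5)) {
  X <- G$dosages
  n <- nrow(X)
  if (anyNA(X)) stop("missing dosages: impute first")
  if (length(y) != n) stop("phenotype length does not match sample count")
  if (!is.null(names(y)) && !identical(names(y), G$samples))
    stop("phenotype samples are not aligned with genotypes; run align_samples()")
  if (anyNA(y)) stop("missing phenotype values")
  if (is.null(K)) K <- centered_kinship(G)
  .check_kinship(K, n)
  if (is.null(W)) W <- matrix(1, n, 1, dimnames = list(G$samples, "intercept"))
  W <- as.matrix(W)
  if (qr(W)$rank < ncol(W)) stop("singular covariate matrix W")
  ek <- eigen(K, symmetric = TRUE)
  d <- pmax(ek$values, 0)
  Ut <- t(ek$vectors)
  Uty <- drop(Ut %*% y)
  UtW <- Ut %*% W
  UtX <- Ut %*% X
  fixed <- if (is.null(lambda)) -1 else lambda
  sc <- lmm_scan_cpp(d, UtW, Uty, UtX, lambda_bounds[1], lambda_bounds[2],
                     100L, fixed)
  null <- lmm_null_cpp(d, UtW, Uty, lambda_bounds[1], lambda_bounds[2], 100L)
  h2 <- null$lambda / (1 + null$lambda)
  se_loglam <- if (null$curvature_loglambda < 0)
    sqrt(-1 / null$curvature_loglambda) else NA_real_
  h2_ci <- if (is.na(se_loglam)) c(NA_real_, NA_real_) else {
    ll <- log(null$lambda) + c(-1, 1) * 1.96 * se_loglam
    exp(ll) / (1 + exp(ll))
  }
  res <- data.frame(chrom = G$snps$chrom, pos = G$snps$pos, id = G$snps$id,
                    maf = G$snps$maf, beta = sc$beta, se = sc$se,
                    p_wald = pmax(sc$p_wald, 1e-300), lambda = sc$lambda,
                    stringsAsFactors = FALSE)
  structure(list(results = res, n = n, n_covariates = ncol(W),
                 lambda_null = null$lambda, h2 = h2, h2_ci = h2_ci,
                 trait = attr(y, "trait_name") %||% "trait",
                 call = match.call()),
            class = "lmm_scan")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.check_kinship <- function(K, n) {
  if (!is.matrix(K) || nrow(K) != n || ncol(K) != n)
    stop("kinship matrix dimension mismatch")
  sym_err <- max(abs(K - t(K)))
  if (sym_err > 1e-10 * max(1, max(abs(K))))
    stop("kinship matrix is not symmetric")
  ev_min <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-8 * max(1, max(abs(K))))
    stop("kinship matrix is not positive semidefinite")
  invisible(TRUE)
}

#' REML estimate of the variance ratio lambda
#'
#' Restricted-likelihood maximization over \eqn{\lambda \in} `bounds` by a
#' coarse 100-point log-grid pass followed by golden-section refinement,
#' given a precomputed eigendecomposition of the kinship matrix.
#'
#' @param y phenotype vector.
#' @param x optional SNP dosage column added to the fixed effects.
#' @param W covariate matrix (default intercept only).
#' @param eigenK result of `eigen(K, symmetric = TRUE)`.
#' @param bounds search range (default `c(1e-5, 1e5)`).
#' @return list with `lambda`, `logl` (restricted log-likelihood up to a
#'   constant) and `curvature_loglambda`.
#' @export
reml_lambda <- function(y, x = NULL, W = NULL, eigenK, bounds = c(1e-5, 1e5)) {
  n <- length(y)
  if (is.null(W)) W <- matrix(1, n, 1)
  d <- pmax(eigenK$values, 0)
  Ut <- t(eigenK$vectors)
  Xf <- if (is.null(x)) W else cbind(W, x)
  out <- lmm_null_cpp(d, Ut %*% Xf, drop(Ut %*% y), bounds[1], bounds[2], 100L)
  if (!is.finite(out$logl)) stop("restricted likelihood is not finite")
  out
}

#' Gao-corrected significance thresholds
#'
#' Computes the effective number of independent tests m_eff over a haplotype
#' block partition and the corresponding family-wise threshold
#' \eqn{-\log_{10}(\alpha / m_{eff})}, alongside the conventional suggestive
#' line at \eqn{-\log_{10}(0.001)}.
#'
#' Two modes: `"block-count"` takes m_eff as the size of the supplied block
#' partition (the workflow's usage, where a precomputed multi-SNP haplotype
#' block map counts the independent tests); `"simpleM"` is the
#' eigenvalue-based estimator — per block, the smallest number of leading
#' eigenvalues of the SNP correlation matrix whose sum reaches
#' `variance_fraction` of the total, summed over blocks.
#'
#' @param G genotypes object (needed for `"simpleM"`; optional otherwise).
#' @param blocks integer/factor vector assigning each SNP to a block; must
#'   partition the SNP list. See [infer_blocks].
#' @param mode `"block-count"` or `"simpleM"`.
#' @param variance_fraction eigenvalue mass per block for simpleM
#'   (default 0.995).
#' @param alpha family-wise error rate (default 0.05).
#' @return object of class `"scan_thresholds"`: list with `m_eff`, `alpha`,
#'   `significant_logp`, `suggestive_logp`, `mode`.
#' @export
gao_meff <- function(G = NULL, blocks, mode = c("block-count", "simpleM"),
                     variance_fraction = 0.995, alpha = 0.05) {
  mode <- match.arg(mode)
  if (length(blocks) == 0) stop("empty block partition")
  blocks <- as.integer(factor(blocks, levels = unique(blocks)))
  if (anyNA(blocks)) stop("blocks must assign every SNP")
  if (mode == "block-count") {
    m_eff <- length(unique(blocks))
  } else {
    if (is.null(G)) stop("simpleM mode needs the genotype matrix")
    if (length(blocks) != nrow(G$snps))
      stop("blocks must partition the SNP list")
    m_eff <- 0L
    for (b in unique(blocks)) {
      j <- which(blocks == b)
      if (length(j) == 1) { m_eff <- m_eff + 1L; next }
      X <- G$dosages[, j, drop = FALSE]
      sds <- apply(X, 2, sd)
      X <- X[, sds > 0, drop = FALSE]
      if (ncol(X) == 0) { m_eff <- m_eff + 1L; next }
      ev <- eigen(cor(X), symmetric = TRUE, only.values = TRUE)$values
      ev <- pmax(ev, 0)
      m_eff <- m_eff +
        which(cumsum(ev) >= variance_fraction * sum(ev))[1]
    }
  }
  structure(list(m_eff = as.integer(m_eff), alpha = alpha,
                 significant_logp = -log10(alpha / m_eff),
                 suggestive_logp = -log10(0.001), mode = mode),
            class = "scan_thresholds")
}

#' @export
print.scan_thresholds <- function(x, ...) {
  cat(sprintf("m_eff = %d (%s); significant -log10(P) = %.3f; suggestive = %.3f\n",
              x$m_eff, x$mode, x$significant_logp, x$suggestive_logp))
  invisible(x)
}

#' Derive haplotype blocks as runs of adjacent high-D' SNPs
#'
#' Adjacent same-chromosome SNPs whose pairwise D' meets `threshold` are
#' chained into one block; chain breaks (or undefined D') start a new block.
#' @param G genotypes object.
#' @param threshold D' bound (default 0.8).
#' @return integer block id per SNP.
#' @export
infer_blocks <- function(G, threshold = 0.8) {
  p <- nrow(G$snps)
  blocks <- integer(p)
  blocks[1] <- 1L
  for (j in seq_len(p - 1)) {
    same_chrom <- G$snps$chrom[j + 1] == G$snps$chrom[j]
    dp <- if (same_chrom)
      dprime_cpp(G$dosages[, j], G$dosages[, j + 1]) else NA_real_
    blocks[j + 1] <- if (!is.na(dp) && dp >= threshold) blocks[j]
                     else blocks[j] + 1L
  }
  blocks
}

#' Read a haplotype block partition from a BED file
#'
#' BED intervals are 0-based half-open; SNPs not covered by any interval
#' become singleton blocks.
#' @param path BED file (chrom, start, end).
#' @param G genotypes object whose SNPs are assigned.
#' @return integer block id per SNP.
#' @export
blocks_from_bed <- function(path, G) {
  bed <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                    comment.char = "#")
  blocks <- rep(NA_integer_, nrow(G$snps))
  for (b in seq_len(nrow(bed))) {
    hit <- G$snps$chrom == bed[b, 1] & G$snps$pos - 1L >= bed[b, 2] &
      G$snps$pos - 1L < bed[b, 3]
    blocks[hit & is.na(blocks)] <- b
  }
  nb <- nrow(bed)
  for (j in which(is.na(blocks))) {
    nb <- nb + 1L
    blocks[j] <- nb
  }
  blocks
}

#' Ranked SNP subset from scan results
#'
#' Selects `ceiling(fraction * p)` SNPs by the chosen criterion — the lowest
#' Wald P values or the largest absolute effect sizes — with ties broken by
#' (chrom, pos) ascending so the selection is deterministic.
#'
#' @param scan `lmm_scan` object (or its `results` data frame).
#' @param fraction fraction of scanned SNPs to keep (default 0.01).
#' @param criterion `"lowest_p"` or `"largest_abs_beta"`.
#' @param signed rank raw (signed) effects instead of |beta|? Default
#'   `FALSE`.
#' @return object of class `"snp_subset"`: list with `name`, `snp_ids`
#'   (ordered by chrom, pos), `table` (id, chrom, pos) and `provenance`.
#' @export
subset_by_rank <- function(scan, fraction = 0.01,
                           criterion = c("lowest_p", "largest_abs_beta"),
                           signed = FALSE) {
  criterion <- match.arg(criterion)
  res <- if (inherits(scan, "lmm_scan")) scan$results else scan
  stopifnot(fraction > 0, fraction <= 1)
  p <- nrow(res)
  k <- ceiling(fraction * p)
  key <- switch(criterion,
                lowest_p = res$p_wald,
                largest_abs_beta = if (signed) -res$beta else -abs(res$beta))
  ord <- order(key, res$chrom, res$pos)
  pick <- ord[seq_len(k)]
  tab <- res[pick, c("id", "chrom", "pos")]
  tab <- tab[order(tab$chrom, tab$pos), , drop = FALSE]
  name <- if (criterion == "lowest_p") sprintf("p_values_%gpct", 100 * fraction)
          else sprintf("effect_size_%gpct", 100 * fraction)
  structure(list(name = name, snp_ids = tab$id, table = tab,
                 provenance = sprintf("%s, fraction %g", criterion, fraction)),
            class = "snp_subset")
}

#' Union of two SNP subsets
#'
#' The "combination" set: the union of the ranked subsets, sorted by
#' (chrom, pos).
#' @param a,b `snp_subset` objects from the same scan.
#' @return `snp_subset` named `"combination"`.
#' @export
subset_union <- function(a, b) {
  tab <- rbind(a$table, b$table)
  tab <- tab[!duplicated(tab$id), , drop = FALSE]
  tab <- tab[order(tab$chrom, tab$pos), , drop = FALSE]
  structure(list(name = "combination", snp_ids = tab$id, table = tab,
                 provenance = sprintf("union(%s, %s)", a$name, b$name)),
            class = "snp_subset")
}

#' @export
print.snp_subset <- function(x, ...) {
  cat(sprintf("snp_subset '%s': %d SNPs (%s)\n", x$name, length(x$snp_ids),
              x$provenance))
  invisible(x)
}

#' @export
print.lmm_scan <- function(x, ...) {
  cat(sprintf("LMM scan of '%s': %d SNPs, %d samples, %d covariate column(s)\n",
              x$trait, nrow(x$results), x$n, x$n_covariates))
  cat(sprintf("  null-model h2 = %.3f (%.3f-%.3f), lambda = %.4g\n",
              x$h2, x$h2_ci[1], x$h2_ci[2], x$lambda_null))
  top <- x$results[order(x$results$p_wald), ][1, ]
  cat(sprintf("  top SNP %s: beta = %.4g, P = %.3g\n", top$id, top$beta,
              top$p_wald))
  invisible(x)
}

#' @export
summary.lmm_scan <- function(object, n_top = 10, ...) {
  res <- object$results[order(object$results$p_wald), ]
  out <- list(h2 = object$h2, h2_ci = object$h2_ci,
              lambda_null = object$lambda_null,
              top = utils::head(res, n_top), n_snps = nrow(res),
              n = object$n)
  class(out) <- "summary.lmm_scan"
  out
}

#' @export
print.summary.lmm_scan <- function(x, ...) {
  cat(sprintf("LMM scan: %d SNPs, %d samples\n", x$n_snps, x$n))
  cat(sprintf("SNP heritability h2 = %.3f (%.3f-%.3f)\n", x$h2, x$h2_ci[1],
              x$h2_ci[2]))
  cat("Top associations:\n")
  print(x$top, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.lmm_scan <- function(object, ...) {
  stats::setNames(object$results$beta, object$results$id)
}

#' Manhattan-style plot of an LMM scan
#'
#' @param x `lmm_scan` object.
#' @param thresholds optional [gao_meff] result; draws the Gao-corrected
#'   (red) and suggestive (blue) lines.
#' @param ... passed to [graphics::plot].
#' @export
plot.lmm_scan <- function(x, thresholds = NULL, ...) {
  res <- x$results
  chrom_f <- factor(res$chrom, levels = unique(res$chrom))
  offs <- c(0, cumsum(tapply(res$pos, chrom_f, max)))
  xpos <- res$pos + offs[as.integer(chrom_f)]
  cols <- c("grey30", "grey60")[1 + as.integer(chrom_f) %% 2]
  graphics::plot(xpos, -log10(res$p_wald), pch = 20, col = cols,
                 xlab = "genome position", ylab = expression(-log[10](P)), ...)
  if (!is.null(thresholds)) {
    graphics::abline(h = thresholds$significant_logp, col = "red")
    graphics::abline(h = thresholds$suggestive_logp, col = "blue")
  }
  invisible(x)
}

#' Write an association table in a GEMMA-compatible layout
#'
#' Tab-delimited columns (chrom, pos, id, maf, beta, se, p_wald, lambda)
#' preceded by `#` header comment lines recording provenance.
#' @param scan `lmm_scan` object.
#' @param path output file.
#' @param meta optional named character vector of extra header fields.
#' @return `path`, invisibly.
#' @export
write_scan <- function(scan, path, meta = NULL) {
  write_table_with_header(scan$results, path, meta)
}
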