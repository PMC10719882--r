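#' Centered relatedness (kinship) matrix
#'
#' K = Xc Xc' / p with each SNP column mean-centered — the centered
#' relatedness estimator commonly used for mixed-model association.
#' Monomorphic SNPs contribute exactly zero after centering.
#'
#' @param G genotypes object with no missing dosages (impute first).
#' @return symmetric n x n matrix with sample IDs as dimnames.
#' @export
centered_kinship <- function(G) {
  X <- G$dosages
  if (anyNA(X)) stop("missing dosages: run impute_missing_mean() first")
  if (ncol(X) < 2) stop("kinship needs at least 2 SNPs")
  Xc <- scale(X, center = TRUE, scale = FALSE)
  if (all(abs(Xc) < 1e-12))
    stop("all SNPs monomorphic: kinship would be identically zero")
  K <- tcrossprod(Xc) / ncol(X)
  K <- (K + t(K)) / 2
  dimnames(K) <- list(G$samples, G$samples)
  K
}

#' Pairwise linkage-disequilibrium D'
#'
#' D' = |D| / Dmax with two-locus haplotype frequencies obtained from
#' unphased dosages by the EM estimate (only the double-heterozygote cell of
#' the 3x3 genotype table is ambiguous). For fully inbred lines there are no
#' heterozygotes, dosage/2 is the haplotype, and the estimate is exact.
#'
#' @param col_a,col_b dosage vectors (0/1/2, `NA` allowed) of equal length.
#' @return D' in `[0, 1]`.
#' @export
ld_dprime <- function(col_a, col_b) {
  dp <- dprime_cpp(as.numeric(col_a), as.numeric(col_b))
  if (is.na(dp))
    stop("D' undefined: a locus is monomorphic among jointly observed calls")
  dp
}

#' Sliding-window LD pruning by D'
#'
#' Within each window of `window_snps` consecutive SNPs (advancing by
#' `step_snps`), every pair with D' >= `threshold` loses its later member
#' (the SNP with the larger position — a stable, reproducible tie-break).
#' Pairs on different chromosomes are never compared.
#'
#' @param G genotypes object (SNPs sorted by chrom, pos).
#' @param window_snps window width in SNPs (default 50).
#' @param step_snps window advance in SNPs (default 5).
#' @param threshold D' bound in (0, 1] (default 0.8).
#' @return sorted integer vector of retained SNP column indices.
#' @export
prune_by_dprime <- function(G, window_snps = 50, step_snps = 5,
                            threshold = 0.8) {
  stopifnot(threshold > 0, threshold <= 1, window_snps >= 2, step_snps >= 1)
  chrom_code <- as.integer(factor(G$snps$chrom, levels = unique(G$snps$chrom)))
  sort(prune_dprime_cpp(G$dosages, chrom_code, as.integer(window_snps),
                        as.integer(step_snps), threshold))
}

#' Principal-component structure covariates
#'
#' PCA of the centered (optionally standardized) dosage matrix, normally of
#' an LD-pruned "independent" SNP set. Returns an intercept column followed
#' by the first `k` principal-component score columns; four PCs is the
#' conventional default for structure correction in this workflow.
#'
#' @param G_pruned genotypes object (no missing dosages).
#' @param k number of PCs (default 4); must be below the matrix rank.
#' @param standardize scale SNP columns to unit variance first? Default
#'   `FALSE`, matching the centered-kinship convention.
#' @return n x (1 + k) matrix, columns `intercept`, `PC1` ... `PCk`;
#'   attribute `"eigenvalues"` carries the full eigenvalue spectrum of the
#'   sample covariance.
#' @export
pca_covariates <- function(G_pruned, k = 4, standardize = FALSE) {
  X <- G_pruned$dosages
  if (anyNA(X)) stop("missing dosages: impute first")
  n <- nrow(X); p <- ncol(X)
  if (k >= min(n, p)) stop("k must be smaller than min(samples, SNPs)")
  keep <- apply(X, 2, function(col) var(col) > 0)
  Xc <- scale(X[, keep, drop = FALSE], center = TRUE, scale = standardize)
  pc <- prcomp(Xc, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2
  if (k >= sum(ev > max(ev) * 1e-12))
    stop("k is at least the rank of the centered dosage matrix")
  W <- cbind(intercept = 1, pc$x[, seq_len(k), drop = FALSE])
  colnames(W) <- c("intercept", paste0("PC", seq_len(k)))
  rownames(W) <- G_pruned$samples
  attr(W, "eigenvalues") <- ev
  W
}
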