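#' Simulation configuration
#'
#' Defaults emulate a small inbred association panel: 300 lines, 1000
#' biallelic SNPs arranged in 20 LD blocks (one block per chromosome) with
#' within-block latent correlation 0.8, allele frequencies drawn uniformly
#' on [0.05, 0.5], and 95\% of heterozygous calls collapsed to homozygotes.
#' The trait defaults mirror an oligogenic-leaning architecture: 10 sparse
#' causal SNPs, half the phenotypic variance explained by genotype
#' (pve_target 0.5) with 80\% of that genetic variance carried by the
#' sparse terms (pge_target 0.8).
#'
#' @param n_samples,n_snps panel dimensions.
#' @param n_blocks number of LD blocks; SNPs are split into contiguous
#'   blocks of near-equal size, one simulated chromosome per block.
#' @param within_block_r latent within-block correlation in `[0, 1)`.
#' @param maf_range `c(lo, hi)` for alt-allele frequencies, inside
#'   `[0.01, 0.5]`.
#' @param inbreeding probability that a sample is a fully inbred line
#'   (its haplotype doubled, so it carries no heterozygous calls).
#' @param n_causal_sparse number of sparse causal SNPs.
#' @param pve_target total proportion of phenotypic variance explained by
#'   genotype, achieved exactly in-sample.
#' @param pge_target proportion of the genetic variance carried by the
#'   sparse causal terms, achieved exactly in-sample.
#' @param pathway_genes optional data frame (chrom, start, end, gene_id) of
#'   intervals to tag as pathway genes in downstream tests.
#' @param seed RNG seed; identical configs give bit-identical output.
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(n_samples = 300, n_snps = 1000, n_blocks = 20,
                       within_block_r = 0.8, maf_range = c(0.05, 0.5),
                       inbreeding = 0.95, n_causal_sparse = 10,
                       pve_target = 0.5, pge_target = 0.8,
                       pathway_genes = NULL, seed = 20231202) {
  stopifnot(n_samples >= 2, n_snps >= 2, n_blocks >= 1,
            n_blocks <= n_snps, inbreeding >= 0, inbreeding <= 1,
            n_causal_sparse <= n_snps, pve_target >= 0, pve_target < 1,
            pge_target >= 0, pge_target <= 1)
  if (within_block_r < 0 || within_block_r >= 1)
    stop("within_block_r must lie in [0, 1)")
  if (maf_range[1] < 0.01 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stop("maf_range must be inside [0.01, 0.5]")
  structure(list(n_samples = n_samples, n_snps = n_snps, n_blocks = n_blocks,
                 within_block_r = within_block_r, maf_range = maf_range,
                 inbreeding = inbreeding, n_causal_sparse = n_causal_sparse,
                 pve_target = pve_target, pge_target = pge_target,
                 pathway_genes = pathway_genes, seed = seed),
            class = "sim_config")
}

#' Simulate block-LD inbred-panel genotypes
#'
#' Per block, each haplotype carries a one-factor equicorrelated latent
#' Gaussian (correlation `within_block_r` between SNPs) thresholded at the
#' allele-frequency quantile, so dosage LD decays with the block structure
#' without coalescent machinery. Each sample receives two haplotypes; with
#' probability `inbreeding` a sample is an inbred line and its first
#' haplotype is doubled instead (whole-haplotype homozygosity, as selfing
#' produces), so heterozygous calls vanish coherently and between-locus LD
#' is preserved — converting heterozygous calls site-by-site would destroy
#' the very block structure the generator exists to produce. One simulated
#' chromosome per block; SNP positions are 1000 bp apart.
#'
#' @param config [sim_config] object.
#' @return a [genotypes] object.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_samples; p <- config$n_snps
  r <- config$within_block_r
  block_of <- sort(rep_len(seq_len(config$n_blocks), p))
  freqs <- runif(p, config$maf_range[1], config$maf_range[2])
  inbred <- runif(n) < config$inbreeding
  dos <- matrix(0, n, p)
  for (b in seq_len(config$n_blocks)) {
    j <- which(block_of == b)
    pb <- length(j)
    thr <- matrix(qnorm(freqs[j]), n, pb, byrow = TRUE)
    hap <- list()
    for (hh in 1:2) {
      shared <- rnorm(n)
      z <- sqrt(r) * shared + sqrt(1 - r) * matrix(rnorm(n * pb), n, pb)
      hap[[hh]] <- (z < thr) + 0
    }
    hap[[2]][inbred, ] <- hap[[1]][inbred, ]
    dos[, j] <- hap[[1]] + hap[[2]]
  }
  chrom <- sprintf("chr%02d", block_of)
  pos <- integer(p)
  for (b in seq_len(config$n_blocks)) {
    j <- which(block_of == b)
    pos[j] <- seq_along(j) * 1000L
  }
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, p, replace = TRUE)
  alt <- vapply(ref, function(x) sample(setdiff(bases, x), 1), "")
  G <- genotypes(dos, chrom = chrom, pos = pos, ref = ref, alt = unname(alt),
                 samples = sprintf("L%03d", seq_len(n)))
  attr(G, "blocks") <- block_of
  attr(G, "alt_freqs") <- freqs
  G
}

#' Simulate a phenotype with sparse plus polygenic plus residual components
#'
#' \eqn{y = X_c\tilde\beta + u + \epsilon}: sparse effects drawn i.i.d.
#' normal on the causal set, a polygenic draw with covariance proportional
#' to the centered kinship of `G`, and i.i.d. residual noise. The three
#' components are orthogonalised in-sample and rescaled so the realised
#' variance fractions hit `pve_target` and `pge_target` exactly (to within
#' floating-point error), which makes parameter-recovery tests sharp at
#' small n: the ground truth is a property of the emitted sample, not of an
#' expectation.
#'
#' @param G genotypes object (typically from [simulate_genotypes]).
#' @param config [sim_config] object.
#' @param causal_ids optional SNP IDs to use as the sparse causal set
#'   (default: sampled uniformly among polymorphic SNPs).
#' @return list with `phenotype` (named vector, trait `"sim_trait"`) and
#'   `truth` (causal_ids, beta, realized_pve, realized_pge,
#'   polygenic_component, residual_component).
#' @export
simulate_phenotype <- function(G, config, causal_ids = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  X <- G$dosages
  n <- nrow(X)
  pve <- config$pve_target; pge <- config$pge_target
  n_causal <- config$n_causal_sparse
  if (pve == 0 && n_causal > 0)
    warning("pve_target = 0 with causal SNPs: effects scaled to zero")
  if (is.null(causal_ids)) {
    poly <- G$snps$id[!is.na(G$snps$maf) & G$snps$maf > 0]
    if (n_causal > length(poly)) stop("not enough polymorphic SNPs for causals")
    causal_ids <- sort(sample(poly, n_causal))
  } else {
    if (!all(causal_ids %in% G$snps$id)) stop("unknown causal SNP id(s)")
    n_causal <- length(causal_ids)
  }

  centre <- function(v) v - mean(v)
  resid_on <- function(v, basis) {
    for (b in basis) {
      nb <- sum(b * b)
      if (nb > 0) v <- v - b * (sum(v * b) / nb)
    }
    v
  }
  svar <- function(v) sum(v * v) / (n - 1)

  beta0 <- rnorm(n_causal)
  gs <- if (n_causal > 0) {
    Xc <- scale(X[, causal_ids, drop = FALSE], center = TRUE, scale = FALSE)
    centre(drop(Xc %*% beta0))
  } else numeric(n)
  if (n_causal > 0 && svar(gs) == 0)
    stop("causal SNPs span no phenotypic variance (monomorphic?)")

  K <- centered_kinship(impute_missing_mean(G))
  ek <- eigen(K, symmetric = TRUE)
  L <- ek$vectors %*% diag(sqrt(pmax(ek$values, 0)))
  gu <- centre(drop(L %*% rnorm(n)))
  gu <- resid_on(gu, list(gs))
  eps <- centre(rnorm(n))
  eps <- resid_on(eps, list(gs, gu))

  v_s_target <- pve * pge
  v_u_target <- pve * (1 - pge)
  v_e_target <- 1 - pve
  scale_to <- function(v, target) {
    vv <- svar(v)
    if (target == 0) return(list(v = numeric(n), f = 0))
    if (vv == 0) stop("cannot scale a zero-variance component to a nonzero target")
    f <- sqrt(target / vv)
    list(v = v * f, f = f)
  }
  if (n_causal == 0 && v_s_target > 0) {
    warning("no causal SNPs: sparse variance target folded into residual")
    v_e_target <- v_e_target + v_s_target
    v_s_target <- 0
  }
  ss <- scale_to(gs, v_s_target)
  su <- scale_to(gu, v_u_target)
  se <- scale_to(eps, v_e_target)
  y <- ss$v + su$v + se$v
  names(y) <- G$samples
  attr(y, "trait_name") <- "sim_trait"

  v_g <- svar(ss$v + su$v)
  truth <- list(causal_ids = causal_ids, beta = beta0 * ss$f,
                realized_pve = v_g / svar(y),
                realized_pge = if (v_g > 0) svar(ss$v) / v_g else 0,
                polygenic_component = su$v, residual_component = se$v)
  list(phenotype = y, truth = truth)
}
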