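test_that("with zero kinship the scan reduces to ordinary least squares", {
  panel <- small_panel()
  n <- length(panel$y)
  G <- panel$G[, 1:25]
  K0 <- matrix(0, n, n)
  scan <- lmm_gwas(G, panel$y, K = K0, lambda = 1)  # lambda irrelevant at K = 0
  for (j in c(1, 10, 25)) {
    f <- summary(stats::lm(panel$y ~ G$dosages[, j]))
    expect_equal(scan$results$beta[j], coef(f)[2, 1], tolerance = 1e-8)
    expect_equal(scan$results$se[j], coef(f)[2, 2], tolerance = 1e-8)
    expect_equal(scan$results$p_wald[j], coef(f)[2, 4], tolerance = 1e-8)
  }
})

test_that("an exact linear phenotype is recovered with a vanishing P value", {
  panel <- small_panel()
  G <- panel$G[, 1:10]
  x <- G$dosages[, 4]
  y <- 3 + 2 * x
  names(y) <- G$samples
  scan <- lmm_gwas(G, y, K = panel$K)
  expect_equal(scan$results$beta[4], 2, tolerance = 1e-6)
  expect_lt(scan$results$p_wald[4], 1e-200)
})

test_that("with lambda fixed at 1 the scan equals dense GLS on (K + I)", {
  set.seed(2024)
  n <- 20
  dos <- matrix(sample(0:2, n * 8, replace = TRUE), nrow = n)
  G <- make_geno(dos)
  K <- centered_kinship(G)
  W <- cbind(intercept = rep(1, n), cov = rnorm(n))
  y <- rnorm(n, sd = 2)
  names(y) <- G$samples
  scan <- lmm_gwas(G, y, K = K, W = W, lambda = 1)
  Sigma <- K + diag(n)
  for (j in seq_len(8)) {
    o <- gls_oracle(y, dos[, j], W, Sigma)
    expect_equal(scan$results$beta[j], o$beta, tolerance = 1e-8)
    expect_equal(scan$results$se[j], o$se, tolerance = 1e-8)
    expect_equal(scan$results$p_wald[j], o$p, tolerance = 1e-8)
  }
})

test_that("REML recovers a strong polygenic variance ratio and pins nulls low", {
  lams <- replicate(5, {
    cfg <- sim_config(n_samples = 250, n_snps = 400, n_blocks = 8,
                      n_causal_sparse = 0, pve_target = 0.8, pge_target = 0,
                      seed = sample.int(1e6, 1))
    G <- impute_missing_mean(simulate_genotypes(cfg))
    sim <- simulate_phenotype(G, cfg)
    ek <- eigen(centered_kinship(G), symmetric = TRUE)
    reml_lambda(sim$phenotype, eigenK = ek)$lambda
  })
  # generating h2 = 0.8 corresponds to lambda = 4; median within +-0.5 in log10
  expect_lt(abs(log10(median(lams)) - log10(4)), 0.5)

  set.seed(99)
  cfg0 <- sim_config(n_samples = 250, n_snps = 400, n_blocks = 8,
                     n_causal_sparse = 0, pve_target = 0, seed = 31)
  G0 <- impute_missing_mean(simulate_genotypes(cfg0))
  y0 <- simulate_phenotype(G0, cfg0)$phenotype
  ek0 <- eigen(centered_kinship(G0), symmetric = TRUE)
  lam0 <- reml_lambda(y0, eigenK = ek0)$lambda
  expect_lt(lam0, 1e-3)  # pinned near the lower search bound
})

test_that("the scan is invariant to a consistent sample reordering", {
  panel <- small_panel()
  G <- panel$G[, 1:40]
  scan <- lmm_gwas(G, panel$y, K = panel$K)
  set.seed(8)
  perm <- sample(length(panel$y))
  Gp <- G[perm, ]
  yp <- panel$y[perm]
  attr(yp, "trait_name") <- "sim_trait"
  Kp <- panel$K[perm, perm]
  scan_p <- lmm_gwas(Gp, yp, K = Kp)
  expect_equal(scan_p$results$beta, scan$results$beta, tolerance = 1e-6)
  expect_equal(scan_p$results$p_wald, scan$results$p_wald, tolerance = 1e-6)
})

test_that("null-model heritability tracks the simulated variance fraction", {
  ok <- vapply(1:10, function(s) {
    cfg <- sim_config(n_samples = 500, n_snps = 400, n_blocks = 10,
                      n_causal_sparse = 0, pve_target = 0.5, pge_target = 0,
                      seed = 400 + s)
    G <- impute_missing_mean(simulate_genotypes(cfg))
    sim <- simulate_phenotype(G, cfg)
    ek <- eigen(centered_kinship(G), symmetric = TRUE)
    lam <- reml_lambda(sim$phenotype, eigenK = ek)$lambda
    h2 <- lam / (1 + lam)
    h2 >= 0.3 && h2 <= 0.7
  }, logical(1))
  expect_gte(sum(ok), 8)
})

test_that("simpleM effective test counts match the full-spectrum eigen oracle", {
  # block of exact duplicates collapses to one effective test
  dup <- matrix(rep(c(0, 2, 0, 2, 2, 0, 0, 2), 10), ncol = 10)
  G_dup <- make_geno(dup)
  thr <- gao_meff(G_dup, blocks = rep(1, 10), mode = "simpleM")
  expect_equal(thr$m_eff, 1L)

  # exactly uncorrelated columns (0/2-coded Hadamard contrasts) keep full count
  H2 <- matrix(c(1, 1, 1, -1), 2)
  H16 <- Reduce(kronecker, rep(list(H2), 4))
  dos_orth <- (H16[, 2:11] + 1)  # 10 balanced orthogonal columns, values 0/2
  thr2 <- gao_meff(make_geno(dos_orth), blocks = rep(1, 10),
                   mode = "simpleM")
  expect_equal(thr2$m_eff, 10L)

  # two correlated blocks against an independent eigen-count oracle
  set.seed(55)
  mk_block <- function(p, n = 300, r = 0.99) {
    base <- rnorm(n)
    sapply(seq_len(p), function(i)
      ifelse(sqrt(r) * base + sqrt(1 - r) * rnorm(n) > 0, 2, 0))
  }
  dos <- cbind(mk_block(4), mk_block(6))
  G <- make_geno(dos)
  blocks <- rep(1:2, c(4, 6))
  thr3 <- gao_meff(G, blocks, mode = "simpleM", variance_fraction = 0.995)
  oracle <- sum(vapply(1:2, function(b) {
    ev <- sort(eigen(cor(dos[, blocks == b]), symmetric = TRUE,
                     only.values = TRUE)$values, decreasing = TRUE)
    which(cumsum(ev) >= 0.995 * sum(ev))[1]
  }, numeric(1)))
  expect_equal(thr3$m_eff, as.integer(oracle))
})

test_that("block-count mode returns the partition size and sets thresholds", {
  G <- small_panel()$G
  blocks <- infer_blocks(G)
  thr <- gao_meff(G, blocks, mode = "block-count")
  expect_equal(thr$m_eff, length(unique(blocks)))
  expect_equal(thr$significant_logp, -log10(0.05 / thr$m_eff))
  expect_equal(thr$suggestive_logp, 3)
  expect_lte(thr$m_eff, nrow(G$snps))
  expect_error(gao_meff(G, integer(0)), "empty")
})

test_that("ranked subsets honour the ceiling rule and ranking criteria", {
  set.seed(14)
  res <- data.frame(chrom = rep("chr01", 1000), pos = 1:1000,
                    id = paste0("s", 1:1000), maf = 0.2,
                    beta = rnorm(1000), se = 0.1,
                    p_wald = runif(1000), lambda = 1)
  res$beta[17] <- 99  # strictly maximal |beta|
  sub_p <- subset_by_rank(res, 0.01, "lowest_p")
  expect_length(sub_p$snp_ids, 10L)
  expect_setequal(sub_p$snp_ids, res$id[order(res$p_wald)][1:10])
  sub_b <- subset_by_rank(res, 0.01, "largest_abs_beta")
  expect_true("s17" %in% sub_b$snp_ids)
  expect_equal(subset_by_rank(res, 1.0)$snp_ids,
               res$id[order(res$chrom, res$pos)])
})

test_that("subset union obeys inclusion-exclusion and idempotence", {
  res <- data.frame(chrom = "chr01", pos = 1:40, id = paste0("s", 1:40),
                    maf = 0.2, beta = 0, se = 1, p_wald = 0.5, lambda = 1)
  mk <- function(ids, nm) structure(
    list(name = nm, snp_ids = res$id[ids],
         table = res[ids, c("id", "chrom", "pos")], provenance = nm),
    class = "snp_subset")
  a <- mk(1:10, "a"); b <- mk(11:20, "b"); c3 <- mk(8:17, "c")
  expect_length(subset_union(a, b)$snp_ids, 20L)
  expect_length(subset_union(a, a)$snp_ids, 10L)
  expect_length(subset_union(a, c3)$snp_ids, 17L)  # overlap of 3
})

test_that("the union of the two ranked subsets is their subset_union", {
  panel <- small_panel()
  scan <- lmm_gwas(panel$G, panel$y, K = panel$K)
  sub_p <- subset_by_rank(scan, 0.02, "lowest_p")
  sub_b <- subset_by_rank(scan, 0.02, "largest_abs_beta")
  u <- subset_union(sub_p, sub_b)
  expect_setequal(u$snp_ids, union(sub_p$snp_ids, sub_b$snp_ids))
  expect_equal(u$name, "combination")
})

test_that("Wald P values are uniform under a permuted (null) phenotype", {
  # independent SNPs (r = 0) so the KS comparison against U(0,1) is valid
  cfg <- sim_config(n_samples = 200, n_snps = 500, n_blocks = 10,
                    within_block_r = 0, seed = 615)
  G <- impute_missing_mean(simulate_genotypes(cfg))
  sim <- simulate_phenotype(G, cfg)
  set.seed(616)
  y_null <- sample(unname(sim$phenotype))
  names(y_null) <- G$samples
  scan <- lmm_gwas(G, y_null, K = centered_kinship(G))
  ks <- suppressWarnings(ks.test(scan$results$p_wald, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})
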