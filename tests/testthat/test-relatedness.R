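test_that("centered kinship equals the direct matrix product", {
  set.seed(101)
  dos <- matrix(sample(0:2, 50, replace = TRUE), nrow = 5)
  G <- make_geno(dos)
  K <- centered_kinship(G)
  Xc <- sweep(dos, 2, colMeans(dos))
  K_direct <- (Xc %*% t(Xc)) / ncol(dos)  # dense oracle
  expect_equal(unname(K), K_direct, tolerance = 1e-12)
  expect_lt(max(abs(K - t(K))), 1e-10)
  expect_gt(min(eigen(K, symmetric = TRUE)$values), -1e-8)
})

test_that("identical genotype rows give identical kinship rows", {
  dos <- rbind(c(0, 1, 2, 0), c(0, 1, 2, 0), c(2, 1, 0, 2))
  K <- centered_kinship(make_geno(dos))
  expect_equal(K[1, ], K[2, ], tolerance = 1e-14,
               ignore_attr = TRUE)
})

test_that("monomorphic SNPs contribute exactly zero to kinship", {
  dos <- cbind(c(0, 1, 2), c(2, 0, 1))
  K_base <- centered_kinship(make_geno(dos))
  dos_mono <- cbind(dos, rep(2, 3))
  K_mono <- centered_kinship(make_geno(dos_mono))
  # adding a monomorphic column only rescales by the SNP count
  expect_equal(unname(K_mono) * 3, unname(K_base) * 2, tolerance = 1e-12)
  expect_error(centered_kinship(make_geno(cbind(rep(1, 3), rep(0, 3)))),
               "monomorphic")
})

test_that("kinship is invariant to SNP column order", {
  panel <- small_panel()
  G <- panel$G
  set.seed(5)
  perm <- sample(nrow(G$snps))
  s <- G$snps[perm, ]
  G_perm <- genotypes(G$dosages[, perm], chrom = s$chrom, pos = s$pos,
                      id = s$id, samples = G$samples)
  expect_equal(centered_kinship(G_perm), centered_kinship(G),
               tolerance = 1e-12)
})

test_that("D' matches the hand-computed value on an 8-haplotype fixture", {
  # haplotype counts AB = 3, Ab = 1, aB = 1, ab = 3 over 8 haplotypes;
  # inbred samples: each sample = one haplotype doubled, so dosages are 2x
  h1 <- c(1, 1, 1, 1, 0, 0, 0, 0)  # allele A (alt at locus 1)
  h2 <- c(1, 1, 1, 0, 1, 0, 0, 0)  # allele B (alt at locus 2)
  # pA = pB = 0.5; f_AB = 3/8; D = 3/8 - 1/4 = 1/8; Dmax = 1/4; D' = 0.5
  dp <- ld_dprime(2 * h1, 2 * h2)
  expect_equal(dp, 0.5, tolerance = 1e-10)
})

test_that("D' is 1 for perfectly co-varying columns and ~0 for independence", {
  x <- c(0, 0, 2, 2, 0, 2, 0, 2)
  expect_equal(ld_dprime(x, x), 1.0)
  expect_equal(ld_dprime(x, 2 - x), 1.0)  # repulsion is still |D|
  set.seed(42)
  a <- 2 * rbinom(5000, 1, 0.4)
  b <- 2 * rbinom(5000, 1, 0.3)
  expect_lt(ld_dprime(a, b), 0.1)
  expect_error(ld_dprime(rep(2, 8), x), "monomorphic")
})

test_that("EM and phased-haplotype D' agree on heterozygous data", {
  set.seed(7)
  n <- 2000
  # explicit haplotype pairs with known joint frequencies
  f <- c(AB = 0.5, Ab = 0.1, aB = 0.1, ab = 0.3)
  draw <- function() sample(names(f), n, replace = TRUE, prob = f)
  hap1 <- draw(); hap2 <- draw()
  a <- (substr(hap1, 1, 1) == "A") + (substr(hap2, 1, 1) == "A")
  b <- (substr(hap1, 2, 2) == "B") + (substr(hap2, 2, 2) == "B")
  # truth from the generating frequencies
  D <- f["AB"] - (f["AB"] + f["Ab"]) * (f["AB"] + f["aB"])
  Dmax <- min((f["AB"] + f["Ab"]) * (1 - (f["AB"] + f["aB"])),
              (1 - (f["AB"] + f["Ab"])) * (f["AB"] + f["aB"]))
  expect_equal(ld_dprime(a, b), unname(abs(D) / Dmax), tolerance = 0.08)
})

test_that("windowed pruning matches the exhaustive greedy oracle", {
  set.seed(12)
  cfg <- sim_config(n_samples = 200, n_snps = 20, n_blocks = 2,
                    within_block_r = 0.9, seed = 13)
  G <- impute_missing_mean(simulate_genotypes(cfg))
  kept_window <- prune_by_dprime(G, window_snps = 20, step_snps = 1,
                                 threshold = 0.8)
  # exhaustive oracle: same greedy rule, all pairs, no windows
  p <- nrow(G$snps)
  keep <- rep(TRUE, p)
  chrom <- G$snps$chrom
  for (i in seq_len(p - 1)) {
    if (!keep[i]) next
    for (j in (i + 1):p) {
      if (!keep[j] || chrom[i] != chrom[j]) next
      dp <- tryCatch(ld_dprime(G$dosages[, i], G$dosages[, j]),
                     error = function(e) NA_real_)
      if (!is.na(dp) && dp >= 0.8) keep[j] <- FALSE
    }
  }
  expect_equal(kept_window, which(keep))
})

test_that("pruning keeps everything when SNPs are independent, drops duplicates", {
  set.seed(3)
  dos <- matrix(2 * rbinom(400 * 10, 1, 0.5), ncol = 10)
  G <- make_geno(dos)
  expect_equal(prune_by_dprime(G, threshold = 0.999), 1:10)
  # duplicate column: exactly one of the pair survives
  dos_dup <- cbind(dos, dos[, 4])
  G2 <- make_geno(dos_dup)
  kept <- prune_by_dprime(G2, threshold = 1.0)
  expect_equal(length(kept), 10L)
  expect_true(xor(4 %in% kept, 11 %in% kept))
})

test_that("PC covariates separate simulated subpopulations and satisfy PCA identities", {
  set.seed(21)
  n <- 60; p <- 120
  freq_a <- runif(p, 0.1, 0.9)
  freq_b <- pmin(pmax(freq_a + sample(c(-0.45, 0.45), p, TRUE), 0.02), 0.98)
  pop <- rep(c("a", "b"), each = n / 2)
  dos <- t(vapply(pop, function(gp) {
    f <- if (gp == "a") freq_a else freq_b
    rbinom(p, 2, f)
  }, numeric(p)))
  rownames(dos) <- paste0("S", 1:n)
  G <- make_geno(dos)
  W <- pca_covariates(G, k = 4)
  expect_equal(colnames(W), c("intercept", paste0("PC", 1:4)))
  expect_equal(unname(W[, 1]), rep(1, n))
  expect_equal(colMeans(W[, -1]), rep(0, 4), tolerance = 1e-10,
               ignore_attr = TRUE)
  # PC1 separates the two pools with no overlap
  pc1 <- W[, "PC1"]
  expect_true(max(pc1[pop == "a"]) < min(pc1[pop == "b"]) ||
                max(pc1[pop == "b"]) < min(pc1[pop == "a"]))
  # trace identity: eigenvalues sum to the total variance
  ev <- attr(W, "eigenvalues")
  Xc <- scale(dos, center = TRUE, scale = FALSE)
  expect_equal(sum(ev), sum(apply(Xc, 2, var)), tolerance = 1e-8)
  # orthogonality of scores
  cp <- crossprod(W[, -1])
  expect_lt(max(abs(cp[upper.tri(cp)])), 1e-8)
  expect_error(pca_covariates(G, k = n), "smaller than")
})
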