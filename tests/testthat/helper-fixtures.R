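# Shared fixtures, all generated in code.

# quick genotypes object from a dosage matrix; one chromosome unless given
make_geno <- function(dos, chrom = NULL, pos = NULL) {
  p <- ncol(dos)
  if (is.null(chrom)) chrom <- rep("chr01", p)
  if (is.null(pos)) pos <- seq_len(p) * 100L
  genotypes(dos, chrom = chrom, pos = pos)
}

# write a small VCF by hand (independent of the package's writer)
write_test_vcf <- function(path, records, samples) {
  header <- c("##fileformat=VCFv4.2",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, records), path)
}

vcf_record <- function(chrom, pos, ref, alt, gts, id = ".") {
  paste(c(chrom, pos, id, ref, alt, ".", "PASS", ".", "GT", gts),
        collapse = "\t")
}

# small default simulated panel shared across tests
small_panel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_samples = 150, n_snps = 300, n_blocks = 6,
                        seed = 20231202)
      G <- impute_missing_mean(simulate_genotypes(cfg))
      sim <- simulate_phenotype(G, cfg)
      cache <<- list(config = cfg, G = G, y = sim$phenotype,
                     truth = sim$truth, K = centered_kinship(G))
    }
    cache
  }
})

# dense GLS oracle: beta, se, Wald P for one SNP given covariance Sigma
gls_oracle <- function(y, x, W, Sigma) {
  Xf <- cbind(W, x)
  Si <- solve(Sigma)
  XtSX <- t(Xf) %*% Si %*% Xf
  XtSXi <- solve(XtSX)
  beta <- XtSXi %*% t(Xf) %*% Si %*% y
  r <- y - Xf %*% beta
  df <- length(y) - ncol(Xf)
  s2 <- drop(t(r) %*% Si %*% r) / df
  q <- ncol(Xf)
  se <- sqrt(s2 * XtSXi[q, q])
  Fst <- (beta[q] / se)^2
  list(beta = beta[q], se = se, p = stats::pf(Fst, 1, df, lower.tail = FALSE))
}
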