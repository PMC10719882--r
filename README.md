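# sparsegwa

Association mapping for quantitative traits in inbred panels, built around
the comparison of two architectures for the same trait:

* a per-SNP **linear mixed model** (LMM) scan — kinship random effect,
  principal-component structure covariates, per-SNP REML estimation of the
  variance ratio on the kinship eigenbasis, Wald tests against
  F(1, n − c − 1), and Gao-corrected significance thresholds from an
  effective number of independent tests over haplotype blocks;
* a **Bayesian sparse linear mixed model** (BSLMM) fitted by MCMC —
  y = Wα + Xβ̃ + u + ε with each SNP's sparse effect β̃ⱼ nonzero with
  probability π and a polygenic term u ~ N(0, σ²ᵦτ⁻¹K), reporting the
  hyperparameter posteriors PVE, PGE, Rho, Pi and N.Gamma, per-SNP posterior
  inclusion probabilities (PIP, γ), sparse effects |β × γ|, and 2.5–97.5%
  posterior intervals, with medians across repeat chains.

Around the two models sit the pieces a full workflow needs: VCF/phenotype
ingestion and filtering (MAF < 5% or heterozygosity > 10% excluded, the
inbred-panel convention), centred kinship, sliding-window D′ pruning for an
independent SNP set, structure PCs, ranked SNP subsets (top 1% P values,
top 1% |β|, and their union), **candidate pathway association** (EC → gene →
SNP curation from a GFF3 annotation, analysed with genome-wide kinship and
thresholds), and a **block-LD simulator** whose phenotypes hit their
variance-explained targets exactly in-sample, so every stage is testable
without external data.

A SNP is called a *major-effect locus* when its PIP ≥ 0.10 and its effect
interval does not overlap zero.

## Worked example

Simulate the package's default panel (300 inbred lines × 1000 SNPs in 20 LD
blocks; 10 sparse causal SNPs; PVE 0.5, PGE 0.8), then run both models:

```r
library(sparsegwa)

cfg  <- sim_config(seed = 7)
G    <- impute_missing_mean(simulate_genotypes(cfg))
sim  <- simulate_phenotype(G, cfg)
K    <- centered_kinship(G)
W    <- pca_covariates(G[, prune_by_dprime(G)], k = 4)

scan <- lmm_gwas(G, sim$phenotype, K = K, W = W)
scan
#> LMM scan of 'sim_trait': 1000 SNPs, 300 samples, 5 covariate column(s)
#>   null-model h2 = 0.578 (0.376-0.757), lambda = 1.368
#>   top SNP chr06:4000: beta = -0.6909, P = 1.77e-16

gao_meff(G, infer_blocks(G), mode = "block-count")
#> m_eff = 578 (block-count); significant -log10(P) = 4.063; suggestive = 3.000

fit <- bslmm(G, sim$phenotype, K = K, W = W, burn_in = 20000,
             steps = 200000, record_pace = 20, chains = 3, seed = 7)
summary(fit)
#> BSLMM of 'sim_trait': 300 samples x 1000 SNPs, 3 chain(s)
#>   pve        0.4194  (0.2992-0.5478)
#>   pge        0.6378  (0.3516-0.9662)
#>   rho        0.7236  (0.3205-0.9743)
#>   pi        0.00313  (0.001039-0.01116)
#>   n_gamma     2.899  (1-11)
#>   h          0.4823  (0.2264-0.797)
#> 3 major-effect SNP(s) at PIP >= 0.1 with interval off zero
```

Reading the output: the LMM's null-model SNP heritability (0.58) and the
BSLMM's PVE (0.42, interval 0.30–0.55) both bracket the generating value
0.5; rho near 0.72 says the posterior leans oligogenic, consistent with the
sparse-heavy generating architecture (PGE 0.8); and the top major-effect
call is a true causal SNP:

```r
head(classify_major(fit)[, c("snp_id", "pip", "sparse_effect", "is_major")], 3)
#>          snp_id   pip sparse_effect is_major
#> 254  chr06:4000 1.000        0.6723     TRUE
#> 664 chr14:14000 0.140        0.0297     TRUE
#> 572 chr12:22000 0.101        0.0224     TRUE
```

The full workflow — filter → kinship/PCs → LMM → thresholds → subsets →
BSLMM per subset → pathway stage → summary tables — is one call:

```r
res <- run_pipeline(run_config(seed = 7), "run_dir")
```

and `inst/cli/sparsegwa` exposes the same stages as shell subcommands
(`pipeline`, `simulate`, `kinship`, `lmm`). Every output file carries `#`
header lines with the package version, a config hash and the seed;
rerunning an identical config is bit-identical.

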