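---
title: "Models and methods in sparsegwa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in sparsegwa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

sparsegwa compares two views of the genetic architecture of a quantitative
trait in an inbred association panel: a per-SNP linear mixed model (LMM) scan,
and a Bayesian sparse linear mixed model (BSLMM) that partitions the trait's
heritable variance into a handful of major-effect SNPs plus a diffuse
polygenic background. A candidate pathway association (CPA) stage reruns both
models on only the SNPs inside genes encoding a biosynthetic pathway's
enzymes, so a hypothesis grounded in biochemistry can be confronted with the
genome-wide picture. This vignette documents the models, the tunable
parameters, the simulator used as the test surface, and the numerical and
design choices a maintainer would want spelled out.

## The linear mixed model scan

For each SNP with dosage column $x$ the scan fits

$$ y = W\alpha + x\beta + u + \epsilon, \qquad
   u \sim N(0, \lambda \tau^{-1} K), \quad \epsilon \sim N(0, \tau^{-1} I), $$

where $K$ is the centred relatedness matrix $X_c X_c^\top / p$ and $W$ holds
an intercept plus principal-component structure covariates (four PCs of an
LD-pruned SNP set by default — the convention for this workflow). The
variance ratio $\lambda$ is estimated per SNP by restricted maximum
likelihood: $K$ is eigendecomposed once, every restricted-likelihood
evaluation is then a diagonal reweighting, and the optimum is located by a
100-point grid on $\log_{10}\lambda \in [-5, 5]$ followed by golden-section
refinement. These bounds and the grid density follow the defaults of the
standard mixed-model association software this scan is modelled on. The Wald
statistic for $\beta$ is referred to $F(1,\, n - c - 1)$ with $c$ the number
of fixed-effect columns including the SNP, again matching that tool rather
than the asymptotic normal. When a phenotype is an exact linear function of
a SNP, the residual quadratic form is clamped at $10^{-280}$ so the P value
saturates near zero instead of becoming undefined.

SNP-based heritability is reported from the null model (no SNP term) as
$h^2 = \hat\lambda / (1 + \hat\lambda)$, with an interval from the curvature
of the restricted likelihood in $\log\lambda$, because the scan has to
report a comparison value for the BSLMM's PVE and the null mixed model is
the estimator that uses exactly the same kinship.

### Multiple testing

Significance lines use an effective number of independent tests $m_\mathrm{eff}$
over a haplotype-block partition, with the family-wise line at
$-\log_{10}(\alpha / m_\mathrm{eff})$ and a suggestive line at
$-\log_{10}(0.001)$. Two modes are provided because the block-based
correction is used in two ways in practice: `block-count` takes
$m_\mathrm{eff}$ to be the size of the supplied partition (the usage when a
precomputed multi-SNP haplotype block map defines the test count), and
`simpleM` computes, per block, the smallest number of leading eigenvalues of
the SNP correlation matrix reaching 99.5% of the total variance — the
eigenvalue-based definition of the correction. Blocks can be supplied as a
BED file or derived internally by chaining adjacent SNPs whose pairwise
D′ ≥ 0.8.

### LD pruning and D′

The "independent" SNP set feeding the structure PCA is obtained by a sliding
window (50 SNPs wide, advancing by 5, both exposed in the configuration; the
window geometry is a package choice since only the D′ < 0.8 rule is
standard). Within a window, the later SNP of any pair with D′ at or above
the threshold is dropped — a stable, position-based tie-break. D′ is
computed from unphased dosages by the EM haplotype-frequency estimate; the
only ambiguous cell of the two-locus genotype table is the double
heterozygote, so for a panel of inbred lines (no heterozygotes) the estimate
is exact.

## The Bayesian sparse linear mixed model

The BSLMM adds to the polygenic term a sparse set of SNP effects:

$$ y = W\alpha + X\tilde\beta + u + \epsilon, $$

where each SNP's effect $\tilde\beta_j$ is nonzero with probability $\pi$,
nonzero effects are $N(0, \sigma_a^2 \tau^{-1})$, and
$u \sim N(0, \sigma_b^2 \tau^{-1} K)$. Hyperparameters are parameterised
through $h$ (approximate proportion of phenotypic variance explained, PVE)
and $\rho$ (approximate fraction of that genetic variance carried by the
sparse terms, PGE):

$$ \sigma_a^2 = \frac{h\rho}{(1-h)\,\pi\, p\, \bar s_a}, \qquad
   \sigma_b^2 = \frac{h(1-\rho)}{(1-h)\, \bar s_b}, $$

with $\bar s_a$ the mean SNP dosage variance and $\bar s_b = \mathrm{tr}(K)/n$.
Priors are the conventional defaults: $h, \rho \sim U(0,1)$ and
$\log\pi \sim U(\log(1/p), 0)$.

### Sampler

Sampling is Metropolis-within-Gibbs on $(\gamma, h, \rho, \log\pi)$ with the
sparse effects and the residual precision integrated out of every acceptance
ratio (the scale-invariant prior $p(\tau) \propto 1/\tau$ makes the
integrated likelihood a simple determinant-plus-quadratic-form expression on
the eigenbasis of $K$). The inclusion set $\gamma$ moves by add/delete/swap
proposals — uniform over eligible SNPs, with a geometric number of repeats
per sweep (success probability 0.7, capped at 4) — and $h$, $\rho$,
$\log\pi$ by reflected uniform random walks (half-widths 0.1, 0.1 and 1.0).
The sparse-set size is capped at 300. Fixed covariates are projected out of
$y$ and $X$ before sampling, the standard equivalent of including them as
fixed effects, and the integrated likelihood uses $n' = n - \mathrm{rank}(W)$
degrees of freedom.

Per recorded iteration the sampler draws $\tau$, the included effects and
the polygenic values from their exact conditionals and records the realised
variance fractions
$\mathrm{PVE} = V(X\tilde\beta + u) / (V(X\tilde\beta + u) + \tau^{-1})$ and
$\mathrm{PGE} = V(X\tilde\beta) / V(X\tilde\beta + u)$ (clamped to [0, 1]:
with correlated components a sampled ratio can stray outside the unit
interval), alongside $h$, $\rho$, $\pi$ and the inclusion count. A SNP's
posterior inclusion probability (PIP, $\gamma$) is the fraction of recorded
iterations that include it; its reported effect is the sparse effect
$|\beta \times \gamma|$.

All randomness flows through R's RNG, so a seed fixes a chain exactly; chain
$i$ of a repeat-run fit uses `seed + i - 1`. Reference chain settings for a
full analysis are burn-in 500,000, 5,000,000 steps, thinning 100 and 10
repeat chains with medians of per-chain point estimates reported; tests and
examples use reduced schedules (documented below) because the model mixes
quickly at desk scale.

### Reporting rules

A SNP is called a major-effect locus when its PIP is at least 0.10 *and*
its effect interval does not overlap zero. Intervals default to the central
2.5–97.5% quantiles — the bounds these models conventionally report, even
under the name HPDI — with a true shortest-interval (`"hpd"`) mode also
implemented. Effect intervals are computed from the effect draws
*conditional on inclusion*: unconditional intervals would mechanically
include zero for any SNP with PIP below ~0.98, which would empty the rule
of content. SNPs with fewer than 10 conditional draws get `NA` bounds and
are never called major.

When chains are combined (`aggregate_chains`), hyperparameter point
estimates are medians of per-chain posterior means, PIPs are per-SNP
medians across chains, and effect intervals are recomputed on the pooled
draws by default; a median-of-per-chain-bounds option exists because the
repeat-run reporting convention does not pin this choice down.

### Behaviour on null data

A property worth knowing: when a phenotype carries no genetic signal, the
$h$ posterior collapses towards zero, which drives $\sigma_a^2 \to 0$ — at
which point *inclusion costs nothing* and the indicators roam under their
prior (whose log-uniform $\pi$ has appreciable mass at large values). PIPs
of 0.1–0.3 on a few SNPs, with essentially zero effects attached, are
therefore an expected feature of the null posterior, not a sampler defect.
The meaningful null guarantees — verified in the test suite — are that the
PVE posterior concentrates low and that the PIP-plus-interval rule calls
nothing major, because the conditional effect draws of such prior-driven
inclusions straddle zero.

## Candidate pathway association

The pathway stage consumes a three-column table (EC number, enzyme name,
gene ID) — a versioned file rather than a live database query, so runs are
network-free — resolves gene IDs against the `gene` features of a GFF3
annotation, and takes all SNPs whose positions fall inside a gene span
(1-based inclusive bounds; strand recorded but never used; flanking
sequence off by default, configurable, since the pathway definition speaks
of SNPs *within* the enzyme genes). Both models then run on that subset
with the *genome-wide* kinship, covariates and Gao threshold: the pathway
hypothesis does not earn a more lenient multiple-testing budget, and
relatedness is a property of the panel, not of the subset. Enzymes with no
resolvable or polymorphic gene are reported as counts, mirroring how such
pathways are described in practice.

## The simulator

`simulate_genotypes()` emulates an inbred biallelic panel: SNPs are split
into contiguous blocks (one simulated chromosome per block), each haplotype
carries a one-factor equicorrelated latent Gaussian per block (correlation
`within_block_r`) thresholded at allele-frequency quantiles drawn from
`maf_range`, and a sample is, with probability `inbreeding`, an inbred line
whose first haplotype is doubled. Doubling whole haplotypes (rather than
flipping heterozygous calls site by site) is deliberate: site-wise flips
destroy between-locus LD — in measurements on this generator, adjacent-SNP
D′ dropped from about 0.76 to 0.36 — whereas selfing preserves the
haplotype structure exactly, which is both what real inbred panels look
like and what the LD-dependent stages need to be testable.

`simulate_phenotype()` composes sparse, polygenic and residual components
and rescales them so the realised in-sample variance fractions equal
`pve_target` and `pge_target` exactly (the three components are
orthogonalised first; without that, sampling covariance between components
would leave the realised fractions off target by $O(n^{-1/2})$ and
parameter-recovery tests would be blunt at small $n$). The ground truth —
causal IDs, scaled effects, component vectors, realised fractions — is
returned alongside the phenotype.

Defaults (300 samples, 1000 SNPs, 20 blocks, latent correlation 0.8,
allele frequencies in [0.05, 0.5], 95% inbred lines, 10 sparse causals,
PVE 0.5, PGE 0.8) describe a small oligogenic-leaning inbred panel of the
kind this workflow targets. What the simulator does *not* model: coalescent
or demographic realism, LD decay within blocks (correlation is flat inside
a block and zero across), selection, genotyping error, and multi-allelic
variation. Passing tests on these data therefore demonstrate correctness of
the estimators under the stated generative model, not robustness to every
feature of real resequencing panels.

## Numerical choices and degenerate inputs

* Kinship must be symmetric to 1e-10 and positive semidefinite to -1e-8
  (relative); eigenvalues are clamped at zero after decomposition.
* Monomorphic SNPs: contribute zeros to kinship; are rejected by `ld_dprime`
  (D′ undefined); produce `NA` scan rows rather than aborting a whole scan.
* Mean imputation never updates the stored per-SNP statistics, which always
  describe observed calls.
* `h` and `rho` random walks reflect at [1e-5, 1 - 1e-5], so the variance
  scales stay finite; `log pi` reflects at [log(1/p), 0].
* Ranked subsets break ties by (chromosome, position) so selection is
  deterministic; pruning drops the later SNP of a tied pair for the same
  reason.
* Output tables format numerics with `%.10g`, which is what makes rerun
  outputs bit-identical.

## Problem sizes used by the test suite

The suite exercises every stage on simulated panels of 120–500 samples and
200–2000 SNPs, with BSLMM chains of 10k–200k steps after 1k–20k burn-in —
sizes at which the statistical properties under test (calibration, prior
recovery, PVE coverage, architecture discrimination, pathway ranking) are
already sharp. The acceptance script runs the same workflow at 500 samples
by 1000 SNPs with three repeat chains and reports the recomputed headline
quantities.

## Known limitations

* The BSLMM is the quantitative-trait (Gaussian) form only; no probit
  variant, and no genomic prediction of unphenotyped individuals.
* Multi-locus fixed-effect scans (stepwise/iterative single-SNP models) are
  out of scope; the LMM and BSLMM are the two architectures compared.
* `read_vcf`'s `"split"` policy keeps the most frequent alternate allele of
  a multi-allelic site rather than expanding all alternates, preserving the
  one-SNP-per-position invariant of the container.
* Gene membership is by position only; a SNP in an intron counts the same
  as a coding variant, and regulatory context is invisible to the CPA
  stage.
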