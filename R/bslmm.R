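#' Fit a Bayesian sparse linear mixed model by MCMC
#'
#' The BSLMM decomposes a quantitative trait into a sparse set of
#' major-effect SNP terms plus a polygenic random effect structured by
#' kinship:
#' \deqn{y = W\alpha + X\tilde\beta + u + \epsilon,\quad
#'   u \sim N(0, \sigma_b^2 \tau^{-1} K),\ \epsilon \sim N(0, \tau^{-1} I)}
#' where each SNP's sparse effect is nonzero with prior probability
#' \eqn{\pi}. Hyperparameters follow the conventional defaults: h (the
#' approximate proportion of variance explained, PVE) and rho (the
#' approximate proportion of the genetic variance carried by sparse terms,
#' PGE) are uniform on (0,1) and \eqn{\log\pi} is uniform on
#' \eqn{[\log(1/p), 0]}.
#'
#' Sampling is Metropolis-within-Gibbs: the sparse inclusion set is updated
#' by add/delete/swap proposals (with a geometric number of repeats), and h,
#' rho, \eqn{\log\pi} by reflected random walks, with the sparse effects and
#' the residual precision integrated out of every acceptance ratio. Fixed
#' covariates `W` are projected out of `y` and `X` before sampling. Each
#' chain uses R's RNG, so results are reproducible given `seed`; chain i
#' runs with seed `seed + i - 1`.
#'
#' Per recorded iteration the sampler draws the sparse effects, polygenic
#' values and residual precision and records the realised PVE
#' (\eqn{V(X\tilde\beta + u) / (V(X\tilde\beta + u) + \tau^{-1})}) and PGE
#' (\eqn{V(X\tilde\beta)/V(X\tilde\beta+u)}), alongside h, rho, \eqn{\pi}
#' and the sparse-set size n_gamma.
#'
#' @param G genotypes object, no missing dosages.
#' @param y aligned phenotype vector.
#' @param K kinship matrix; default [centered_kinship] of `G`.
#' @param W covariate matrix with leading intercept (default intercept
#'   only).
#' @param burn_in,steps,record_pace MCMC schedule. The reference settings
#'   for a full analysis are 500000 / 5000000 / 100; reduce for desk-scale
#'   data.
#' @param chains number of independent repeat chains (reference setting:
#'   10); point estimates are medians across chains.
#' @param seed base RNG seed.
#' @param smax cap on the sparse-set size (default 300).
#' @param h_step,rho_step,logpi_step random-walk half-widths.
#' @param geom_p success probability of the geometric repeat count for
#'   sparse-set moves.
#' @param prior_only replace the likelihood by a constant so the chain
#'   samples the prior (sampler diagnostics only).
#' @return object of class `"bslmm"`; see [summary.bslmm],
#'   [classify_major], [aggregate_chains].
#' @export
bslmm <- function(G, y, K = NULL, W = NULL, burn_in = 500000, steps = 5000000,
                  record_pace = 100, chains = 10, seed = 1, smax = 300,
                  h_step = 0.1, rho_step = 0.1, logpi_step = 1.0,
                  geom_p = 0.7, prior_only = FALSE) {
  stopifnot(burn_in >= 1, steps >= 1, record_pace >= 1, chains >= 1)
  X <- G$dosages
  n <- nrow(X); p <- ncol(X)
  if (p < 2) stop("BSLMM needs at least 2 SNPs")
  if (anyNA(X)) stop("missing dosages: impute first")
  if (length(y) != n) stop("phenotype length does not match sample count")
  if (anyNA(y)) stop("missing phenotype values")
  if (is.null(K)) K <- centered_kinship(G)
  .check_kinship(K, n)
  if (is.null(W)) W <- matrix(1, n, 1)
  W <- as.matrix(W)
  qrW <- qr(W)
  if (qrW$rank < ncol(W)) stop("singular covariate matrix W")
  Q <- qr.Q(qrW)[, seq_len(qrW$rank), drop = FALSE]
  yp <- y - Q %*% crossprod(Q, y)
  Xp <- X - Q %*% crossprod(Q, X)
  nprime <- n - qrW$rank

  ek <- eigen(K, symmetric = TRUE)
  d <- pmax(ek$values, 0)
  Ut <- t(ek$vectors)
  ytil <- drop(Ut %*% yp)
  UtX <- Ut %*% Xp
  u1 <- drop(Ut %*% rep(1, n))
  s_a <- mean(apply(X, 2, var))
  if (s_a <= 0) stop("all SNPs monomorphic")
  s_b <- sum(diag(K)) / n
  if (s_b <= 0) stop("kinship has zero trace")

  fits <- vector("list", chains)
  for (i in seq_len(chains)) {
    set.seed(seed + i - 1L)
    raw <- bslmm_mcmc_cpp(d, ytil, UtX, u1, s_a, s_b, nprime,
                          as.integer(burn_in), as.integer(steps),
                          as.integer(record_pace), h_step, rho_step,
                          logpi_step, as.integer(smax), prior_only, geom_p)
    hyp <- as.data.frame(raw$hyp)
    colnames(hyp) <- c("h", "rho", "pi", "n_gamma", "pve", "pge")
    hyp$chain <- i
    fits[[i]] <- list(hyp = hyp, pip = drop(raw$pip),
                      beta_samples = raw$beta_samples, alpha = drop(raw$alpha),
                      accept = raw$accept, tries = raw$tries)
  }

  hyp_all <- do.call(rbind, lapply(fits, `[[`, "hyp"))
  pip_chain <- vapply(fits, `[[`, numeric(p), "pip")
  beta_samples <- lapply(seq_len(p), function(j)
    unlist(lapply(fits, function(f) f$beta_samples[[j]]), use.names = FALSE))
  pip <- apply(pip_chain, 1, median)
  beta_mean <- vapply(beta_samples, function(s)
    if (length(s)) mean(s) else 0, numeric(1))
  alpha <- rowMeans(vapply(fits, `[[`, numeric(p), "alpha"))

  structure(list(
    snps = G$snps[, c("chrom", "pos", "id")],
    n = n, p = p, nprime = nprime,
    config = list(burn_in = burn_in, steps = steps, record_pace = record_pace,
                  chains = chains, seed = seed, smax = smax,
                  prior_only = prior_only),
    hyp = hyp_all, pip = pip, pip_chain = pip_chain,
    beta_mean = beta_mean, beta_samples = beta_samples, alpha = alpha,
    trait = attr(y, "trait_name") %||% "trait",
    call = match.call()), class = "bslmm")
}

#' Sparse effect of a SNP
#'
#' The absolute product of a SNP's posterior mean effect and its posterior
#' inclusion probability, |beta x gamma| — the effect measure used to rank
#' SNPs from a sparse model.
#' @param beta_mean posterior mean sparse effect.
#' @param pip posterior inclusion probability in `[0, 1]`.
#' @return nonnegative effect magnitude.
#' @export
sparse_effect <- function(beta_mean, pip) {
  stopifnot(all(pip >= 0 & pip <= 1))
  abs(beta_mean * pip)
}

#' Posterior interval from MCMC samples
#'
#' `"central"` returns the 2.5\%/97.5\% (for `mass = 0.95`) quantile
#' interval — the bounds conventionally reported for these models;
#' `"hpd"` returns the shortest interval containing `mass`.
#' @param samples numeric vector of at least 10 posterior draws.
#' @param mass interval mass (default 0.95).
#' @param mode `"central"` or `"hpd"`.
#' @return numeric `c(lo, hi)`.
#' @export
hpdi <- function(samples, mass = 0.95, mode = c("central", "hpd")) {
  mode <- match.arg(mode)
  samples <- samples[is.finite(samples)]
  if (length(samples) < 10) stop("need at least 10 samples for an interval")
  if (mode == "central") {
    lo <- (1 - mass) / 2
    unname(quantile(samples, c(lo, 1 - lo)))
  } else {
    s <- sort(samples)
    n <- length(s)
    k <- ceiling(mass * n)
    if (k >= n) return(c(s[1], s[n]))
    widths <- s[(k + 1):n] - s[1:(n - k)]
    i <- which.min(widths)
    c(s[i], s[i + k])
  }
}

#' Classify major-effect SNPs from a fitted BSLMM
#'
#' A SNP is a major-effect locus when its posterior inclusion probability
#' reaches `pip_threshold` (default 10\%) AND its effect interval does not
#' overlap zero — a consistent directional effect across sampled genomic
#' backgrounds. Effect intervals are computed from the sparse-effect draws
#' conditional on inclusion; SNPs with fewer than 10 such draws get `NA`
#' bounds and are never called major.
#'
#' @param fit `bslmm` object.
#' @param pip_threshold inclusion-probability threshold (default 0.10).
#' @param mass interval mass (default 0.95, i.e. 2.5-97.5\% bounds).
#' @param hpdi_mode `"central"` (default) or `"hpd"`.
#' @return data frame (snp_id, chrom, pos, pip, beta_mean, sparse_effect,
#'   hpdi_lo, hpdi_hi, is_major), sorted by sparse effect descending.
#' @export
classify_major <- function(fit, pip_threshold = 0.10, mass = 0.95,
                           hpdi_mode = c("central", "hpd")) {
  hpdi_mode <- match.arg(hpdi_mode)
  p <- fit$p
  lo <- hi <- rep(NA_real_, p)
  for (j in seq_len(p)) {
    s <- fit$beta_samples[[j]]
    if (length(s) >= 10) {
      b <- hpdi(s, mass, hpdi_mode)
      lo[j] <- b[1]; hi[j] <- b[2]
    }
  }
  eff <- sparse_effect(fit$beta_mean, fit$pip)
  is_major <- fit$pip >= pip_threshold & !is.na(lo) & !(lo <= 0 & hi >= 0)
  out <- data.frame(snp_id = fit$snps$id, chrom = fit$snps$chrom,
                    pos = fit$snps$pos, pip = fit$pip,
                    beta_mean = fit$beta_mean, sparse_effect = eff,
                    hpdi_lo = lo, hpdi_hi = hi, is_major = is_major,
                    stringsAsFactors = FALSE)
  out[order(-out$sparse_effect, out$chrom, out$pos), ]
}

#' Combine repeat BSLMM chains
#'
#' Point estimates become the median of per-chain point estimates (the
#' repeat-run reporting convention); per-SNP PIPs the median of per-chain
#' PIPs. Effect intervals are recomputed either on the pooled samples
#' (default) or as the median of per-chain bounds.
#'
#' @param posteriors list of `bslmm` objects fitted on identical data with
#'   distinct seeds.
#' @param hpdi_combine `"pooled"` or `"median_bounds"`.
#' @return a single `bslmm` object whose `hyp` table carries re-numbered
#'   chain ids and whose `config$hpdi_combine` records the choice.
#' @export
aggregate_chains <- function(posteriors, hpdi_combine = c("pooled",
                                                          "median_bounds")) {
  hpdi_combine <- match.arg(hpdi_combine)
  stopifnot(length(posteriors) >= 1)
  ids <- lapply(posteriors, function(f) f$snps$id)
  if (!all(vapply(ids, identical, logical(1), ids[[1]])))
    stop("chains were fitted on different SNP sets")
  base <- posteriors[[1]]
  p <- base$p
  hyp <- do.call(rbind, lapply(seq_along(posteriors), function(i) {
    h <- posteriors[[i]]$hyp
    h$chain <- h$chain + 1000L * (i - 1L)  # keep chains distinct
    h
  }))
  hyp$chain <- as.integer(factor(hyp$chain, levels = unique(hyp$chain)))
  pip_chain <- do.call(cbind, lapply(posteriors, `[[`, "pip_chain"))
  pip <- apply(pip_chain, 1, median)
  beta_samples <- lapply(seq_len(p), function(j)
    unlist(lapply(posteriors, function(f) f$beta_samples[[j]]),
           use.names = FALSE))
  beta_mean <- vapply(beta_samples, function(s)
    if (length(s)) mean(s) else 0, numeric(1))
  out <- base
  out$hyp <- hyp
  out$pip <- pip
  out$pip_chain <- pip_chain
  out$beta_samples <- beta_samples
  out$beta_mean <- beta_mean
  out$alpha <- rowMeans(vapply(posteriors, `[[`, numeric(p), "alpha"))
  out$config$chains <- ncol(pip_chain)
  out$config$hpdi_combine <- hpdi_combine
  if (hpdi_combine == "median_bounds") {
    # per-chain central bounds, median across chains, attached for reports
    nchain <- length(posteriors)
    lo <- hi <- matrix(NA_real_, p, nchain)
    for (i in seq_len(nchain)) {
      for (j in seq_len(p)) {
        s <- posteriors[[i]]$beta_samples[[j]]
        if (length(s) >= 10) {
          b <- hpdi(s)
          lo[j, i] <- b[1]; hi[j, i] <- b[2]
        }
      }
    }
    out$hpdi_bounds <- cbind(lo = apply(lo, 1, median, na.rm = TRUE),
                             hi = apply(hi, 1, median, na.rm = TRUE))
  }
  out
}

#' Hyperparameter point estimates and intervals for a fitted BSLMM
#'
#' Per chain, the point estimate of each hyperparameter (pve, pge, rho, pi,
#' n_gamma, h) is its posterior mean; the reported point estimate is the
#' median across chains and the interval the central 2.5-97.5\% bounds of
#' the pooled samples.
#' @param object `bslmm` object.
#' @param mass interval mass (default 0.95).
#' @param ... ignored.
#' @return `summary.bslmm` object: data frame `hyperparameters` plus
#'   top SNP calls.
#' @export
summary.bslmm <- function(object, mass = 0.95, ...) {
  pars <- c("pve", "pge", "rho", "pi", "n_gamma", "h")
  hyp <- object$hyp
  est <- vapply(pars, function(pp) {
    per_chain <- tapply(hyp[[pp]], hyp$chain, mean, na.rm = TRUE)
    median(per_chain)
  }, numeric(1))
  ci <- vapply(pars, function(pp) {
    s <- hyp[[pp]][is.finite(hyp[[pp]])]
    if (length(s) >= 10) hpdi(s, mass) else c(NA_real_, NA_real_)
  }, numeric(2))
  tab <- data.frame(parameter = pars, estimate = est, lo = ci[1, ],
                    hi = ci[2, ], row.names = NULL)
  major <- classify_major(object)
  out <- list(hyperparameters = tab, major = major[major$is_major, ],
              top = utils::head(major, 5), config = object$config,
              n = object$n, p = object$p, trait = object$trait)
  class(out) <- "summary.bslmm"
  out
}

#' @export
print.summary.bslmm <- function(x, ...) {
  cat(sprintf("BSLMM of '%s': %d samples x %d SNPs, %d chain(s)\n", x$trait,
              x$n, x$p, x$config$chains))
  tab <- x$hyperparameters
  for (i in seq_len(nrow(tab)))
    cat(sprintf("  %-8s %8.4g  (%.4g-%.4g)\n", tab$parameter[i],
                tab$estimate[i], tab$lo[i], tab$hi[i]))
  cat(sprintf("%d major-effect SNP(s) at PIP >= 0.1 with interval off zero\n",
              nrow(x$major)))
  invisible(x)
}

#' @export
print.bslmm <- function(x, ...) {
  print(summary(x))
  invisible(x)
}

#' @export
coef.bslmm <- function(object, ...) {
  stats::setNames(object$beta_mean, object$snps$id)
}

#' PIP plot of a fitted BSLMM
#'
#' Posterior inclusion probability per SNP along the genome; point size
#' scales with the sparse effect |beta x gamma|. The dotted line marks the
#' PIP = 0.1 reporting threshold.
#' @param x `bslmm` object.
#' @param pip_threshold horizontal reference (default 0.1).
#' @param ... passed to [graphics::plot].
#' @export
plot.bslmm <- function(x, pip_threshold = 0.1, ...) {
  s <- x$snps
  chrom_f <- factor(s$chrom, levels = unique(s$chrom))
  offs <- c(0, cumsum(tapply(s$pos, chrom_f, max)))
  xpos <- s$pos + offs[as.integer(chrom_f)]
  eff <- sparse_effect(x$beta_mean, x$pip)
  cex <- 0.5 + 1.5 * if (max(eff) > 0) eff / max(eff) else 0
  cols <- c("grey30", "grey60")[1 + as.integer(chrom_f) %% 2]
  graphics::plot(xpos, x$pip, pch = 20, col = cols, cex = cex,
                 xlab = "genome position", ylab = "PIP", ylim = c(0, 1), ...)
  graphics::abline(h = pip_threshold, lty = 3)
  invisible(x)
}

#' Write BSLMM outputs in GEMMA-compatible layouts
#'
#' `write_bslmm_hyp` writes one row per recorded iteration (h, pve, rho,
#' pge, pi, n_gamma); `write_bslmm_param` writes per-SNP (chrom, pos, id,
#' alpha, beta, gamma).
#' @param fit `bslmm` object.
#' @param path output file.
#' @param meta optional named character vector of extra header fields.
#' @return `path`, invisibly.
#' @export
write_bslmm_hyp <- function(fit, path, meta = NULL) {
  h <- fit$hyp[, c("h", "pve", "rho", "pge", "pi", "n_gamma")]
  write_table_with_header(h, path, meta)
}

#' @rdname write_bslmm_hyp
#' @export
write_bslmm_param <- function(fit, path, meta = NULL) {
  tab <- data.frame(chrom = fit$snps$chrom, pos = fit$snps$pos,
                    id = fit$snps$id, alpha = fit$alpha,
                    beta = fit$beta_mean, gamma = fit$pip,
                    stringsAsFactors = FALSE)
  write_table_with_header(tab, path, meta)
}
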