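#' Construct a genotype matrix object
#'
#' The central data container of the package: an n samples x p SNPs dosage
#' matrix (alt-allele counts 0/1/2, `NA` for missing calls) together with
#' per-SNP metadata. Per-SNP minor allele frequency, observed heterozygosity
#' and missing rate are always recomputed from the dosage columns, so they
#' can never drift out of sync with the data. SNP columns are sorted by
#' (chromosome, position); chromosome labels are ordered lexicographically.
#'
#' @param dosages numeric matrix, samples in rows, SNPs in columns; entries
#'   in \{0, 1, 2\} or `NA`.
#' @param chrom,pos chromosome label and 1-based physical position per SNP.
#' @param id SNP identifiers; default `"chrom:pos"`.
#' @param ref,alt single-character reference / alternate alleles.
#' @param samples sample identifiers; default taken from `rownames(dosages)`.
#' @return An object of class `"genotypes"`: a list with elements `dosages`
#'   (dimnamed matrix), `snps` (data frame with columns chrom, pos, id, ref,
#'   alt, maf, het, missing_rate) and `samples`.
#' @export
genotypes <- function(dosages, chrom, pos, id = NULL, ref = NULL, alt = NULL,
                      samples = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  p <- ncol(dosages)
  n <- nrow(dosages)
  if (length(chrom) != p || length(pos) != p)
    stop("chrom/pos length must equal the number of SNP columns")
  chrom <- as.character(chrom)
  pos <- as.integer(pos)
  if (any(pos < 1L)) stop("SNP positions must be >= 1")
  if (is.null(id)) id <- paste0(chrom, ":", pos)
  if (is.null(ref)) ref <- rep("A", p)
  if (is.null(alt)) alt <- rep("T", p)
  if (any(ref == alt)) stop("ref and alt alleles must differ")
  if (is.null(samples)) samples <- rownames(dosages)
  if (is.null(samples)) samples <- paste0("S", seq_len(n))
  samples <- as.character(samples)
  if (anyDuplicated(samples)) stop("sample IDs must be unique")
  key <- paste(chrom, pos)
  if (anyDuplicated(key)) stop("duplicate SNP (chrom, pos) pairs")
  ok <- dosages[!is.na(dosages)]
  if (length(ok) && (any(ok < 0) || any(ok > 2)))
    stop("dosages must lie in [0, 2]")
  o <- order(chrom, pos)
  dosages <- dosages[, o, drop = FALSE]
  chrom <- chrom[o]; pos <- pos[o]; id <- id[o]; ref <- ref[o]; alt <- alt[o]
  if (anyDuplicated(id)) stop("SNP ids must be unique")
  dimnames(dosages) <- list(samples, id)
  st <- snp_stats(dosages)
  obj <- list(
    dosages = dosages,
    snps = data.frame(chrom = chrom, pos = pos, id = id, ref = ref, alt = alt,
                      maf = st$maf, het = st$het, missing_rate = st$missing_rate,
                      stringsAsFactors = FALSE),
    samples = samples)
  class(obj) <- "genotypes"
  obj
}

#' Per-SNP summary statistics from a dosage matrix
#'
#' @param dosages samples x SNPs dosage matrix (0/1/2/NA).
#' @return list with numeric vectors `maf`, `het`, `missing_rate`.
#' @export
snp_stats <- function(dosages) {
  n_obs <- colSums(!is.na(dosages))
  alt_freq <- colMeans(dosages, na.rm = TRUE) / 2
  alt_freq[n_obs == 0] <- NA_real_
  maf <- pmin(alt_freq, 1 - alt_freq)
  het <- colMeans(dosages == 1, na.rm = TRUE)
  het[n_obs == 0] <- NA_real_
  list(maf = maf, het = het, missing_rate = 1 - n_obs / nrow(dosages))
}

#' @export
print.genotypes <- function(x, ...) {
  cat(sprintf("genotypes: %d samples x %d SNPs on %d chromosome(s)\n",
              length(x$samples), nrow(x$snps), length(unique(x$snps$chrom))))
  cat(sprintf("  MAF range %.3f-%.3f, median het %.3f, missing %.2f%%\n",
              min(x$snps$maf, na.rm = TRUE), max(x$snps$maf, na.rm = TRUE),
              median(x$snps$het, na.rm = TRUE),
              100 * mean(x$snps$missing_rate)))
  invisible(x)
}

#' @export
dim.genotypes <- function(x) c(length(x$samples), nrow(x$snps))

#' Subset a genotypes object by samples and/or SNPs
#'
#' Per-SNP statistics are recomputed on the subset.
#' @param x genotypes object.
#' @param i sample index (integer, logical, or character IDs).
#' @param j SNP index (integer, logical, or character IDs).
#' @param ... ignored.
#' @export
`[.genotypes` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_along(x$samples)
  if (missing(j)) j <- seq_len(nrow(x$snps))
  if (is.character(i)) i <- match(i, x$samples)
  if (is.character(j)) j <- match(j, x$snps$id)
  if (anyNA(i) || anyNA(j)) stop("unknown sample or SNP identifier")
  s <- x$snps[j, , drop = FALSE]
  genotypes(x$dosages[i, j, drop = FALSE], chrom = s$chrom, pos = s$pos,
            id = s$id, ref = s$ref, alt = s$alt, samples = x$samples[i])
}

#' Read biallelic SNP genotypes from a VCF file
#'
#' Parsing is delegated to \pkg{vcfR}; genotype strings are converted to
#' alt-allele dosages (phased and unphased calls are treated identically).
#' Multi-allelic records are handled per `multiallelic`: `"reject"` errors
#' naming the first offending site; `"split"` decomposes the site into one
#' biallelic dosage per alternate allele and retains the most frequent
#' alternate (so the one-SNP-per-position invariant holds); `"drop"`
#' discards the record. Indel alleles are skipped.
#'
#' @param path VCF file (plain or bgzipped).
#' @param region optional `"chrom:start-end"` restriction applied after
#'   parsing.
#' @param multiallelic policy for records with more than one ALT allele.
#' @return a [genotypes] object.
#' @export
read_vcf <- function(path, region = NULL,
                     multiallelic = c("reject", "split", "drop")) {
  multiallelic <- match.arg(multiallelic)
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) stop("malformed VCF '", path, "': ",
                                           conditionMessage(e)))
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0) stop("no SNP records in VCF '", path, "'")
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) {
    gt <- matrix(gt, nrow = nrow(fix))
    colnames(gt) <- colnames(vcf@gt)[-1]
  }
  samples <- colnames(gt)
  chrom <- unname(fix[, "CHROM"]); pos <- as.integer(fix[, "POS"])
  ref <- unname(fix[, "REF"]); alt <- unname(fix[, "ALT"])
  vid <- unname(fix[, "ID"])

  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi) && multiallelic == "reject")
    stop("multi-allelic site at ", chrom[multi][1], ":", pos[multi][1],
         " (policy 'reject')")

  # dosage of allele index a from a GT string; NA on missing
  gt_dosage <- function(g, a) {
    vapply(strsplit(g, "[/|]"), function(al) {
      if (length(al) == 0 || any(al == "." | al == "")) return(NA_real_)
      sum(al == as.character(a))
    }, numeric(1))
  }

  keep <- logical(length(pos))
  dosages <- matrix(NA_real_, nrow = length(samples), ncol = length(pos))
  alt_used <- alt
  bi_map <- c("0/0" = 0, "0|0" = 0, "0/1" = 1, "1/0" = 1, "0|1" = 1,
              "1|0" = 1, "1/1" = 2, "1|1" = 2, "./." = NA, ".|." = NA,
              "." = NA, "0" = 0, "1" = 1)
  for (r in seq_along(pos)) {
    alts <- strsplit(alt[r], ",", fixed = TRUE)[[1]]
    if (length(alts) > 1) {
      if (multiallelic == "drop") next
      snv <- which(nchar(alts) == 1 & nchar(ref[r]) == 1)
      if (!length(snv)) next
      counts <- vapply(snv, function(a) sum(gt_dosage(gt[r, ], a), na.rm = TRUE),
                       numeric(1))
      a_best <- snv[which.max(counts)]
      dosages[, r] <- gt_dosage(gt[r, ], a_best)
      alt_used[r] <- alts[a_best]
      keep[r] <- TRUE
    } else {
      if (nchar(ref[r]) != 1 || nchar(alts) != 1) next  # indel
      g <- gt[r, ]
      d <- unname(bi_map[g])
      unknown <- !is.na(g) & !(g %in% names(bi_map))
      if (any(unknown)) d[unknown] <- gt_dosage(g[unknown], 1)
      d[is.na(g)] <- NA_real_
      dosages[, r] <- d
      keep[r] <- TRUE
    }
  }
  if (!any(keep)) stop("zero biallelic SNPs in VCF '", path, "'")
  ids <- ifelse(is.na(vid) | vid == ".", paste0(chrom, ":", pos), vid)
  G <- genotypes(dosages[, keep, drop = FALSE], chrom = chrom[keep],
                 pos = pos[keep], id = ids[keep], ref = ref[keep],
                 alt = alt_used[keep], samples = samples)
  if (!is.null(region)) {
    m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
    if (length(m) != 4) stop("region must be 'chrom:start-end'")
    sel <- G$snps$chrom == m[2] & G$snps$pos >= as.integer(m[3]) &
      G$snps$pos <= as.integer(m[4])
    if (!any(sel)) stop("no SNPs in region ", region)
    G <- G[, which(sel)]
  }
  G
}

#' Write genotypes to a plain-text VCF
#'
#' Dosages must be integral (0/1/2 or missing); imputed fractional dosages
#' cannot be represented as genotype calls.
#' @param G genotypes object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(G, path) {
  dos <- G$dosages
  ok <- dos[!is.na(dos)]
  if (any(abs(ok - round(ok)) > 0)) stop("non-integral dosages cannot be written as VCF genotypes")
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               paste0("##source=sparsegwa-", .sparsegwa_version()),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", G$samples), collapse = "\t")), con)
  s <- G$snps
  for (j in seq_len(nrow(s))) {
    calls <- ifelse(is.na(dos[, j]), "./.", gt_code[as.character(dos[, j])])
    writeLines(paste(c(s$chrom[j], s$pos[j], s$id[j], s$ref[j], s$alt[j], ".",
                       "PASS", ".", "GT", calls), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a plain dosage matrix
#'
#' Samples as rows (first column = sample ID), SNP IDs of the form
#' `chrom:pos` as the remaining column names.
#' @param path delimited file (tab or whitespace).
#' @return a [genotypes] object.
#' @export
read_dosage <- function(path) {
  tab <- read.table(path, header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, comment.char = "#")
  samples <- as.character(tab[[1]])
  dos <- as.matrix(tab[, -1, drop = FALSE])
  ids <- colnames(dos)
  parts <- strsplit(ids, ":", fixed = TRUE)
  bad <- lengths(parts) < 2
  if (any(bad)) stop("dosage column names must be 'chrom:pos' (got '",
                     ids[bad][1], "')")
  chrom <- vapply(parts, `[`, "", 1)
  pos <- as.integer(vapply(parts, `[`, "", 2))
  genotypes(dos, chrom = chrom, pos = pos, id = ids, samples = samples)
}

#' Read a phenotype table
#'
#' Two-column delimited table (sample_id, value) with a header; the second
#' column name is taken as the trait name.
#' @param path file path.
#' @return named numeric vector with attribute `trait_name`.
#' @export
read_phenotype <- function(path) {
  tab <- read.table(path, header = TRUE, stringsAsFactors = FALSE,
                    comment.char = "#")
  if (ncol(tab) < 2) stop("phenotype table needs (sample_id, value) columns")
  y <- as.numeric(tab[[2]])
  names(y) <- as.character(tab[[1]])
  attr(y, "trait_name") <- colnames(tab)[2]
  y
}

#' Align genotypes and phenotype to their shared samples
#'
#' Both objects are restricted to the sample intersection in the genotype
#' object's order. Samples with missing phenotype values are dropped, with a
#' message giving the count — they are never silently imputed.
#'
#' @param G genotypes object.
#' @param y named phenotype vector (see [read_phenotype]).
#' @return list with elements `genotypes` and `phenotype`.
#' @export
align_samples <- function(G, y) {
  if (is.null(names(y))) stop("phenotype vector must carry sample names")
  miss <- names(y)[is.na(y)]
  if (length(miss)) {
    message(length(miss), " sample(s) dropped for missing phenotype")
    y <- y[!is.na(y)]
  }
  shared <- intersect(G$samples, names(y))
  if (length(shared) == 0) stop("no samples shared between genotypes and phenotype")
  if (length(shared) < 2) stop("fewer than 2 shared samples")
  dropped <- (length(G$samples) - length(shared)) + (length(y) - length(shared))
  if (dropped > 0) message(dropped, " unmatched sample entrie(s) dropped at alignment")
  tn <- attr(y, "trait_name")
  y2 <- y[shared]
  attr(y2, "trait_name") <- tn
  list(genotypes = G[shared, ], phenotype = y2)
}

#' Filter SNPs on allele frequency, heterozygosity and missingness
#'
#' Retains SNPs with `maf >= maf_min`, `het <= het_max` and
#' `missing_rate <= miss_max`. The defaults encode the panel-construction
#' rule for an inbred association panel: SNPs with minor allele frequency
#' below 5\% or observed heterozygosity above 10\% are excluded.
#'
#' @param G genotypes object.
#' @param maf_min minimum minor allele frequency (default 0.05).
#' @param het_max maximum observed heterozygosity (default 0.10).
#' @param miss_max maximum missing-call rate (default 1, i.e. off).
#' @return filtered [genotypes] object; attribute `"removed"` holds
#'   per-criterion removal counts.
#' @export
filter_snps <- function(G, maf_min = 0.05, het_max = 0.10, miss_max = 1) {
  stopifnot(maf_min >= 0, maf_min <= 0.5, het_max >= 0, het_max <= 1,
            miss_max >= 0, miss_max <= 1)
  s <- G$snps
  fail_maf <- is.na(s$maf) | s$maf < maf_min
  fail_het <- !is.na(s$het) & s$het > het_max
  fail_mis <- s$missing_rate > miss_max
  keep <- !(fail_maf | fail_het | fail_mis)
  removed <- c(maf = sum(fail_maf), het = sum(fail_het), missing = sum(fail_mis))
  if (!any(keep))
    stop("all SNPs removed by filters (maf: ", removed["maf"], ", het: ",
         removed["het"], ", missing: ", removed["missing"], ")")
  out <- G[, which(keep)]
  attr(out, "removed") <- removed
  out
}

#' Replace missing dosages by the per-SNP mean of observed calls
#'
#' @param G genotypes object.
#' @return genotypes-like object with no missing entries. Because imputed
#'   dosages are fractional, per-SNP statistics retain their pre-imputation
#'   values.
#' @export
impute_missing_mean <- function(G) {
  dos <- G$dosages
  nmiss <- colSums(is.na(dos))
  if (any(colSums(!is.na(dos)) == 0))
    stop("SNP with zero observed calls cannot be mean-imputed: ",
         G$snps$id[which(colSums(!is.na(dos)) == 0)[1]])
  if (any(nmiss > 0)) {
    mu <- colMeans(dos, na.rm = TRUE)
    idx <- which(is.na(dos), arr.ind = TRUE)
    dos[idx] <- mu[idx[, 2]]
  }
  out <- G
  out$dosages <- dos
  out
}
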