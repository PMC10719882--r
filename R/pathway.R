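#' Read a pathway definition table
#'
#' Three delimited columns — ec_number, enzyme_name, gene_id — with one row
#' per EC-to-gene pairing (a gene column may repeat when an enzyme has
#' paralogs; gene_id may be empty for enzymes absent from the annotation).
#' EC numbers must have four dot-separated fields (digits, `n` or `-`).
#'
#' @param path delimited file with header.
#' @return data frame with the three columns above.
#' @export
read_pathway_table <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, comment.char = "#",
                    fill = TRUE)
  need <- c("ec_number", "enzyme_name", "gene_id")
  if (!all(need %in% colnames(tab)))
    stop("pathway table needs columns: ", paste(need, collapse = ", "))
  ok <- grepl("^[0-9]+\\.[0-9n-]+\\.[0-9n-]+\\.[0-9n-]+$", tab$ec_number)
  if (!all(ok))
    stop("malformed EC number(s): ", paste(unique(tab$ec_number[!ok]),
                                           collapse = ", "))
  tab[, need]
}

#' Locate pathway enzyme genes in a genome annotation
#'
#' Resolves the gene IDs of a pathway definition against the `gene`
#' features of a GFF3 annotation (parsed with \pkg{rtracklayer}). Gene IDs
#' are matched against the `ID` attribute, falling back to `Name`.
#' Unresolved IDs and enzymes with no located gene are reported via
#' messages, not errors — pathway enzymes genuinely absent from an
#' annotation are an expected outcome.
#'
#' @param annotation GFF3 file path.
#' @param pathway data frame from [read_pathway_table].
#' @return data frame of gene intervals (gene_id, chrom, start, end, strand,
#'   ec_number, enzyme_name); 1-based inclusive coordinates. Attribute
#'   `"unresolved"` lists gene IDs not found; attribute
#'   `"enzymes_without_genes"` counts ECs with no located gene.
#' @export
load_pathway_genes <- function(annotation, pathway) {
  gr <- rtracklayer::import(annotation)
  feat <- as.data.frame(gr)
  genes <- feat[feat$type == "gene", , drop = FALSE]
  if (nrow(genes) == 0) stop("no 'gene' features in ", annotation)
  gid <- as.character(genes$ID)
  if (all(is.na(gid)) && "Name" %in% colnames(genes))
    gid <- as.character(genes$Name)
  rows <- pathway[!is.na(pathway$gene_id) & pathway$gene_id != "", ,
                  drop = FALSE]
  hit <- match(rows$gene_id, gid)
  if (any(is.na(hit))) {
    nm <- "Name" %in% colnames(genes)
    if (nm) hit[is.na(hit)] <- match(rows$gene_id[is.na(hit)],
                                     as.character(genes$Name))
  }
  unresolved <- rows$gene_id[is.na(hit)]
  if (length(unresolved))
    message(length(unresolved), " pathway gene ID(s) not in annotation: ",
            paste(unresolved, collapse = ", "))
  res <- rows[!is.na(hit), , drop = FALSE]
  g <- genes[hit[!is.na(hit)], , drop = FALSE]
  if (nrow(res) == 0) stop("no pathway gene IDs resolvable against the annotation")
  out <- data.frame(gene_id = res$gene_id,
                    chrom = as.character(g$seqnames),
                    start = as.integer(g$start), end = as.integer(g$end),
                    strand = as.character(g$strand),
                    ec_number = res$ec_number,
                    enzyme_name = res$enzyme_name, stringsAsFactors = FALSE)
  ec_located <- unique(out$ec_number)
  n_missing <- length(setdiff(unique(pathway$ec_number), ec_located))
  if (n_missing > 0)
    message(n_missing, " enzyme(s) with no located gene in the annotation")
  attr(out, "unresolved") <- unresolved
  attr(out, "enzymes_without_genes") <- n_missing
  out
}

#' Extract the SNPs falling inside pathway genes
#'
#' Membership is 1-based inclusive on the annotated gene span, optionally
#' widened by `flank_bp` on both sides; strand never affects membership.
#' SNPs shared by overlapping genes appear once.
#'
#' @param G genotypes object.
#' @param genes gene-interval data frame from [load_pathway_genes] (or any
#'   frame with chrom, start, end).
#' @param flank_bp flank width in bp (default 0: gene body only).
#' @return `snp_subset` named `"pathway"`.
#' @export
extract_pathway_snps <- function(G, genes, flank_bp = 0) {
  stopifnot(flank_bp >= 0)
  sel <- rep(FALSE, nrow(G$snps))
  for (i in seq_len(nrow(genes))) {
    sel <- sel | (G$snps$chrom == genes$chrom[i] &
                    G$snps$pos >= genes$start[i] - flank_bp &
                    G$snps$pos <= genes$end[i] + flank_bp)
  }
  tab <- G$snps[sel, c("id", "chrom", "pos")]
  structure(list(name = "pathway", snp_ids = tab$id, table = tab,
                 provenance = sprintf("%d gene interval(s), flank %d bp",
                                      nrow(genes), flank_bp)),
            class = "snp_subset")
}

#' Candidate pathway association
#'
#' Runs the LMM scan and the BSLMM on the SNPs inside annotated pathway
#' enzyme genes, reusing the kinship matrix and structure covariates
#' computed from the genome-wide data, and judging LMM significance against
#' the genome-wide Gao-corrected threshold (the pathway subset does not get
#' its own, more lenient, multiple-testing budget).
#'
#' @param G genotypes object (genome-wide, aligned and imputed).
#' @param y aligned phenotype vector.
#' @param K genome-wide kinship matrix.
#' @param W structure covariates (genome-wide).
#' @param genes gene intervals from [load_pathway_genes].
#' @param thresholds genome-wide [gao_meff] result.
#' @param flank_bp flank width for SNP membership (default 0).
#' @param bslmm_args list of arguments forwarded to [bslmm] (chain
#'   schedule, seed, ...).
#' @param pip_threshold major-effect PIP threshold (default 0.1).
#' @return object of class `"cpa"`: list with the SNP `subset`, `lmm` scan,
#'   `bslmm` fit, `major` calls, per-`gene` table and the `thresholds`
#'   used.
#' @export
run_cpa <- function(G, y, K, W, genes, thresholds = NULL, flank_bp = 0,
                    bslmm_args = list(), pip_threshold = 0.1) {
  subset <- extract_pathway_snps(G, genes, flank_bp)
  if (length(subset$snp_ids) == 0)
    stop("no SNPs inside the pathway gene intervals")
  Gs <- G[, subset$snp_ids]
  scan <- lmm_gwas(Gs, y, K = K, W = W)
  fit <- do.call(bslmm, c(list(G = Gs, y = y, K = K, W = W), bslmm_args))
  major <- classify_major(fit, pip_threshold = pip_threshold)
  gene_rows <- lapply(seq_len(nrow(genes)), function(i) {
    gsel <- major$chrom == genes$chrom[i] &
      major$pos >= genes$start[i] - flank_bp &
      major$pos <= genes$end[i] + flank_bp
    m <- major[gsel, , drop = FALSE]
    if (nrow(m) == 0)
      return(data.frame(gene_id = genes$gene_id[i], chrom = genes$chrom[i],
                        start = genes$start[i], end = genes$end[i],
                        n_snps = 0L, top_snp = NA_character_,
                        sparse_effect = NA_real_, pip = NA_real_,
                        hpdi_lo = NA_real_, hpdi_hi = NA_real_,
                        stringsAsFactors = FALSE))
    top <- m[1, ]  # major table is sorted by sparse effect
    data.frame(gene_id = genes$gene_id[i], chrom = genes$chrom[i],
               start = genes$start[i], end = genes$end[i], n_snps = nrow(m),
               top_snp = top$snp_id, sparse_effect = top$sparse_effect,
               pip = top$pip, hpdi_lo = top$hpdi_lo, hpdi_hi = top$hpdi_hi,
               stringsAsFactors = FALSE)
  })
  structure(list(subset = subset, lmm = scan, bslmm = fit, major = major,
                 genes = do.call(rbind, gene_rows), thresholds = thresholds),
            class = "cpa")
}

#' @export
print.cpa <- function(x, ...) {
  cat(sprintf("Candidate pathway association: %d SNPs in %d gene(s)\n",
              length(x$subset$snp_ids), nrow(x$genes)))
  n_major <- sum(x$major$is_major)
  cat(sprintf("  %d major-effect call(s)", n_major))
  if (!is.null(x$thresholds)) {
    n_sig <- sum(-log10(x$lmm$results$p_wald) >= x$thresholds$significant_logp,
                 na.rm = TRUE)
    cat(sprintf("; %d LMM SNP(s) above the genome-wide Gao threshold", n_sig))
  }
  cat("\n")
  invisible(x)
}
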