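#' Genotype matrix container
#'
#' Bundles an n x m hard-call dosage matrix (counts of the second/BIM-A2
#' allele, \code{NA} for missing) with per-SNP and per-sample metadata.
#' Positions are 1-based base pairs, as in PLINK BIM files; all interval
#' work elsewhere in the package uses half-open \code{[start, end)} windows.
#'
#' @param dosage integer matrix, n samples x m SNPs, entries in
#'   \{0, 1, 2, NA\}.
#' @param snp_meta data.frame with columns \code{chrom}, \code{id},
#'   \code{pos_bp}, \code{allele1}, \code{allele2}; one row per SNP.
#'   \code{maf} and \code{missing_rate} are (re)computed from \code{dosage}.
#' @param sample_meta data.frame with columns \code{fid}, \code{iid} and
#'   optionally \code{sex}, \code{phenotype}; one row per sample.
#'
#' @return An object of class \code{"genotype_matrix"}: a list with elements
#'   \code{dosage}, \code{snp_meta}, \code{sample_meta}.
#' @export
genotype_matrix <- function(dosage, snp_meta, sample_meta = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  n <- nrow(dosage); m <- ncol(dosage)
  if (n < 1L || m < 1L) stop("genotype matrix must have at least one sample and one SNP")
  if (any(!is.na(dosage) & (dosage < 0L | dosage > 2L)))
    stop("dosages must be 0, 1, 2 or NA")
  if (nrow(snp_meta) != m) stop("snp_meta rows must match number of SNPs")
  req <- c("chrom", "id", "pos_bp", "allele1", "allele2")
  miss <- setdiff(req, names(snp_meta))
  if (length(miss)) stop("snp_meta missing columns: ", paste(miss, collapse = ", "))
  if (is.null(sample_meta)) {
    sample_meta <- data.frame(fid = paste0("F", seq_len(n)), iid = paste0("I", seq_len(n)),
                              sex = 0L, phenotype = -9, stringsAsFactors = FALSE)
  }
  if (nrow(sample_meta) != n) stop("sample_meta rows must match number of samples")
  if (anyDuplicated(sample_meta$iid)) stop("sample iids must be unique")
  snp_meta$chrom <- as.integer(snp_meta$chrom)
  snp_meta$pos_bp <- as.integer(snp_meta$pos_bp)
  # sort by (chrom, pos); dosage columns follow
  o <- order(snp_meta$chrom, snp_meta$pos_bp)
  if (any(o != seq_len(m))) {
    snp_meta <- snp_meta[o, , drop = FALSE]
    dosage <- dosage[, o, drop = FALSE]
  }
  rownames(snp_meta) <- NULL
  colnames(dosage) <- snp_meta$id
  rownames(dosage) <- sample_meta$iid
  geno <- structure(list(dosage = dosage, snp_meta = snp_meta,
                         sample_meta = sample_meta),
                    class = "genotype_matrix")
  update_snp_stats(geno)
}

#' Recompute per-SNP MAF and missingness
#'
#' @param geno a \code{genotype_matrix}.
#' @return \code{geno} with \code{snp_meta$maf} (minor-allele frequency,
#'   in \code{[0, 0.5]}) and \code{snp_meta$missing_rate} refreshed.
#' @export
update_snp_stats <- function(geno) {
  d <- geno$dosage
  n <- nrow(d)
  nmiss <- colSums(is.na(d))
  ntyped <- n - nmiss
  f2 <- ifelse(ntyped > 0, colSums(d, na.rm = TRUE) / (2 * pmax(ntyped, 1L)), NA_real_)
  geno$snp_meta$maf <- pmin(f2, 1 - f2)
  geno$snp_meta$missing_rate <- nmiss / n
  geno
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosage), "samples x", ncol(x$dosage), "SNPs\n")
  cat("  chromosomes:", paste(unique(x$snp_meta$chrom), collapse = ", "), "\n")
  cat(sprintf("  MAF range: %.4f-%.4f; mean missingness: %.4g\n",
              min(x$snp_meta$maf), max(x$snp_meta$maf),
              mean(x$snp_meta$missing_rate)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix
#'
#' @param geno a \code{genotype_matrix}.
#' @param samples sample indices, logical mask, or iids (default: all).
#' @param snps SNP indices, logical mask, or ids (default: all).
#' @return the subsetted \code{genotype_matrix} with stats recomputed.
#' @export
subset_geno <- function(geno, samples = NULL, snps = NULL) {
  si <- .resolve_idx(samples, geno$sample_meta$iid, nrow(geno$dosage), "sample")
  vi <- .resolve_idx(snps, geno$snp_meta$id, ncol(geno$dosage), "SNP")
  genotype_matrix(geno$dosage[si, vi, drop = FALSE],
                  geno$snp_meta[vi, , drop = FALSE],
                  geno$sample_meta[si, , drop = FALSE])
}

.resolve_idx <- function(key, ids, n, what) {
  if (is.null(key)) return(seq_len(n))
  if (is.logical(key)) {
    if (length(key) != n) stop("logical ", what, " mask has wrong length")
    return(which(key))
  }
  if (is.character(key)) {
    idx <- match(key, ids)
    if (anyNA(idx)) stop("unknown ", what, " ids: ", paste(key[is.na(idx)], collapse = ", "))
    return(idx)
  }
  idx <- as.integer(key)
  if (any(idx < 1L | idx > n)) stop(what, " index out of range")
  idx
}

#' Normalize genotypes to z-scores
#'
#' Mean-imputes missing dosages per SNP, then centers and scales each SNP to
#' empirical mean 0 and variance 1. SNPs with zero variance after imputation
#' yield all-zero columns (callers exclude or warn as appropriate).
#'
#' @param geno a \code{genotype_matrix} or a raw dosage matrix.
#' @return numeric n x m matrix of normalized genotypes.
#' @export
normalize_genotypes <- function(geno) {
  d <- if (inherits(geno, "genotype_matrix")) geno$dosage else geno
  d <- matrix(as.numeric(d), nrow(d), ncol(d), dimnames = dimnames(d))
  if (anyNA(d)) {
    mu <- colMeans(d, na.rm = TRUE)
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- mu[idx[, 2L]]
  }
  ctr <- sweep(d, 2L, colMeans(d), "-")
  sdv <- sqrt(colSums(ctr^2) / (nrow(d) - 1L))
  keep_sd <- ifelse(sdv > 0, sdv, Inf)   # zero-variance SNPs -> zero column
  sweep(ctr, 2L, keep_sd, "/")
}
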