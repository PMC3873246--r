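# GCTA binary GRM triple: <prefix>.grm.bin (row-major lower triangle incl.
# diagonal, float32), <prefix>.grm.N.bin (same layout, per-pair SNP counts),
# <prefix>.grm.id (FID IID, tab-separated).

#' Read a GCTA-format binary GRM
#'
#' @param prefix path prefix of the \code{.grm.bin/.grm.N.bin/.grm.id} triple.
#' @return a \code{grm} object (see \code{\link{standard_grm}}); the
#'   \code{n_pairs} element holds the per-pair SNP counts if the
#'   \code{.grm.N.bin} file is present.
#' @export
read_grm_gcta <- function(prefix) {
  id_path <- paste0(prefix, ".grm.id")
  bin_path <- paste0(prefix, ".grm.bin")
  ids <- utils::read.table(id_path, header = FALSE, stringsAsFactors = FALSE)
  n <- nrow(ids)
  ntri <- n * (n + 1) / 2
  sz <- file.size(bin_path)
  vals <- readBin(bin_path, "numeric", n = sz / 4 + 8, size = 4L)
  if (length(vals) != ntri)
    stop(sprintf("GRM binary has %d elements; %d ids imply n(n+1)/2 = %d",
                 length(vals), n, ntri))
  A <- matrix(0, n, n)
  A[upper.tri(A, diag = TRUE)] <- vals       # row-major lower tri == col-major upper tri
  A <- A + t(A) - diag(diag(A))
  dimnames(A) <- list(ids[[2L]], ids[[2L]])
  npair <- NULL
  n_path <- paste0(prefix, ".grm.N.bin")
  if (file.exists(n_path)) {
    nv <- readBin(n_path, "numeric", n = file.size(n_path) / 4 + 8, size = 4L)
    if (length(nv) == ntri) {
      npair <- matrix(0, n, n)
      npair[upper.tri(npair, diag = TRUE)] <- nv
      npair <- npair + t(npair) - diag(diag(npair))
    }
  }
  new_grm(A, sample_ids = ids[[2L]], snp_variances = NULL,
          norm_constant = NA_real_, method = "imported", n_pairs = npair)
}

#' Write a GRM as a GCTA-format binary triple
#'
#' @param grm a \code{grm} object.
#' @param prefix output path prefix.
#' @param n_snps SNP count recorded per pair in \code{.grm.N.bin}; defaults
#'   to the GRM's normalization constant (rounded) or 1.
#' @return invisibly, the three file paths.
#' @export
write_grm_gcta <- function(grm, prefix, n_snps = NULL) {
  A <- grm$A
  n <- nrow(A)
  tri <- A[upper.tri(A, diag = TRUE)]
  writeBin(as.numeric(tri), paste0(prefix, ".grm.bin"), size = 4L)
  if (is.null(n_snps)) {
    n_snps <- if (is.finite(grm$norm_constant)) max(1, round(grm$norm_constant)) else 1
  }
  writeBin(rep(as.numeric(n_snps), length(tri)), paste0(prefix, ".grm.N.bin"), size = 4L)
  fid <- if (!is.null(grm$sample_fids)) grm$sample_fids else grm$sample_ids
  utils::write.table(data.frame(fid, grm$sample_ids),
                     paste0(prefix, ".grm.id"), quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(paste0(prefix, c(".grm.bin", ".grm.N.bin", ".grm.id")))
}
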