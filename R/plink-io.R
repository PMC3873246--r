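# PLINK BED/BIM/FAM and text phenotype/covariate I/O.
# Only SNP-major BED (mode byte 0x01) is supported; dosages count the BIM
# allele2 (PLINK A2). 2-bit codes: 00 = hom A1 (0), 01 = missing, 10 = het,
# 11 = hom A2 (2), packed low-bits-first within each byte.

.bed_magic <- as.raw(c(0x6c, 0x1b))

# 256 x 4 lookup: dosage of each of the 4 samples packed in a byte
.bed_decode_table <- local({
  tab <- matrix(NA_integer_, 256L, 4L)
  code_map <- c(`0` = 0L, `1` = NA_integer_, `2` = 1L, `3` = 2L)
  for (b in 0:255) {
    for (k in 0:3) {
      code <- bitwAnd(bitwShiftR(b, 2L * k), 3L)
      tab[b + 1L, k + 1L] <- code_map[[as.character(code)]]
    }
  }
  tab
})

#' Read a PLINK BED/BIM/FAM triple
#'
#' @param prefix path prefix, or explicit \code{bed_path}/\code{bim_path}/
#'   \code{fam_path}.
#' @param bed_path,bim_path,fam_path explicit file paths (override
#'   \code{prefix}).
#' @return a \code{\link{genotype_matrix}} with dosages counting the BIM
#'   allele2.
#' @export
read_plink <- function(prefix = NULL, bed_path = NULL, bim_path = NULL, fam_path = NULL) {
  if (!is.null(prefix)) {
    if (is.null(bed_path)) bed_path <- paste0(prefix, ".bed")
    if (is.null(bim_path)) bim_path <- paste0(prefix, ".bim")
    if (is.null(fam_path)) fam_path <- paste0(prefix, ".fam")
  }
  fam <- utils::read.table(fam_path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("fid", "iid", "pat", "mat", "sex", "phenotype"))
  bim <- utils::read.table(bim_path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chrom", "id", "cm", "pos_bp", "allele1", "allele2"))
  n <- nrow(fam); m <- nrow(bim)
  sz <- file.size(bed_path)
  raw <- readBin(bed_path, "raw", n = sz)
  if (length(raw) < 3L || !identical(raw[1:2], .bed_magic))
    stop("not a PLINK BED file (bad magic bytes): ", bed_path)
  if (raw[3L] != as.raw(0x01))
    stop("unsupported BED mode 0x", format(raw[3L]), " (only SNP-major 0x01 is supported)")
  bps <- ceiling(n / 4)                      # bytes per SNP
  if (length(raw) - 3L != bps * m)
    stop(sprintf("BED payload is %d bytes; expected ceil(%d/4) x %d = %d (truncated or wrong n/m?)",
                 length(raw) - 3L, n, m, bps * m))
  bytes <- as.integer(raw[-(1:3)]) + 1L
  # decode all bytes to a (4*bps) x m dosage block, then trim to n samples
  dos <- matrix(t(.bed_decode_table[bytes, , drop = FALSE]), nrow = 4L * bps, ncol = m)
  dos <- dos[seq_len(n), , drop = FALSE]
  snp_meta <- bim[, c("chrom", "id", "pos_bp", "allele1", "allele2")]
  sample_meta <- fam[, c("fid", "iid", "sex", "phenotype")]
  genotype_matrix(dos, snp_meta, sample_meta)
}

#' Write a PLINK BED/BIM/FAM triple
#'
#' @param geno a \code{\link{genotype_matrix}}.
#' @param prefix output path prefix; \code{.bed/.bim/.fam} are appended.
#' @return invisibly, the three file paths.
#' @export
write_plink <- function(geno, prefix) {
  d <- geno$dosage
  n <- nrow(d); m <- ncol(d)
  code <- matrix(3L, n, m)                   # 11 = hom A2 (dosage 2)
  code[is.na(d)] <- 1L                       # 01 = missing
  code[!is.na(d) & d == 0L] <- 0L
  code[!is.na(d) & d == 1L] <- 2L            # 10 = het
  bps <- ceiling(n / 4)
  pad <- 4L * bps - n
  if (pad > 0L) code <- rbind(code, matrix(0L, pad, m))
  k <- rep(c(1L, 4L, 16L, 64L), bps)         # shift factors, low bits first
  bytes <- as.integer(colSums(matrix(code * k, nrow = 4L)))
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(c(.bed_magic, as.raw(0x01)), con)
  writeBin(as.raw(bytes), con)
  sm <- geno$sample_meta
  fam <- data.frame(sm$fid, sm$iid, 0L, 0L,
                    if (!is.null(sm$sex)) sm$sex else 0L,
                    if (!is.null(sm$phenotype)) sm$phenotype else -9)
  utils::write.table(fam, paste0(prefix, ".fam"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  bim <- data.frame(geno$snp_meta$chrom, geno$snp_meta$id, 0,
                    geno$snp_meta$pos_bp, geno$snp_meta$allele1, geno$snp_meta$allele2)
  utils::write.table(bim, paste0(prefix, ".bim"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(paste0(prefix, c(".bed", ".bim", ".fam")))
}

#' Read a PLINK-format phenotype/covariate table aligned to a sample set
#'
#' Parses the PLINK text dialect (\code{FID IID value [value ...]},
#' whitespace-separated, optional header), honours the \code{-9} missing
#' code in the phenotype column, and reorders rows to the order of
#' \code{ids}. For covariate tables an affine term (column of 1s) is
#' prepended so the returned matrix can be used directly as fixed effects.
#'
#' @param path file path.
#' @param ids character vector of sample iids defining the target order
#'   (typically \code{geno$sample_meta$iid}).
#' @param kind \code{"pheno"} (single value column; -9 mapped to \code{NA})
#'   or \code{"covar"} (all value columns kept; affine term prepended).
#' @return For \code{kind = "pheno"}: list with \code{y} (numeric, named by
#'   iid) and \code{missing} (logical). For \code{kind = "covar"}: list with
#'   \code{X} (n x (1+k) matrix, first column the affine term).
#' @export
read_pheno_covar <- function(path, ids, kind = c("pheno", "covar")) {
  kind <- match.arg(kind)
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (is.character(tab[[3L]])) {             # header row present
    tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  }
  iid <- as.character(tab[[2L]])
  idx <- match(ids, iid)
  if (anyNA(idx)) {
    stop("phenotype/covariate file does not cover samples: ",
         paste(utils::head(ids[is.na(idx)], 5L), collapse = ", "),
         if (sum(is.na(idx)) > 5L) ", ..." else "")
  }
  extra <- setdiff(iid, ids)
  if (length(extra))
    warning(length(extra), " file rows have no matching sample and were dropped")
  tab <- tab[idx, , drop = FALSE]
  vals <- as.matrix(tab[, -(1:2), drop = FALSE])
  storage.mode(vals) <- "double"
  if (kind == "pheno") {
    y <- vals[, 1L]
    missing <- !is.na(y) & y == -9
    y[missing] <- NA_real_
    names(y) <- ids
    list(y = y, missing = missing | is.na(y))
  } else {
    if (anyNA(vals)) stop("missing covariate entries after alignment")
    X <- cbind(affine = 1, vals)
    rownames(X) <- ids
    colnames(X) <- c("affine", paste0("C", seq_len(ncol(vals))))
    list(X = X)
  }
}
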