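# Genetic relatedness matrices: the standard normalized cross-product and
# the LD-adjusted variants (pruning, LD-residual regression, neighbour-count
# shrinkage), plus per-locus construction for local heritability.

#' LD-adjustment parameters
#'
#' @param residual_window_bp window (bp) of preceding markers each SNP is
#'   regressed on for the LD-residual transform; 100 kbp for array-density
#'   panels (500 kbp is appropriate for imputed-density panels).
#' @param residual_r2_cap predictor pairs with squared correlation at or
#'   above this are reduced to one (leftmost kept) before the regression so
#'   the normal equations are solvable.
#' @param prune_r2 r-squared threshold for LD-pruning.
#' @param prune_window_snps,prune_step_snps sliding window (SNPs) and step
#'   for LD-pruning.
#' @param shrink_neighbors number of nearest markers (by index, split evenly
#'   around each SNP) examined by the LD-shrink weighting.
#' @param shrink_r2_threshold r-squared above which a neighbour counts
#'   towards a SNP's shrink weight.
#' @param reverse process SNPs right-to-left in the LD-residual transform
#'   (order-robustness check; results should change only negligibly).
#' @return a list of class \code{"ld_params"}.
#' @export
ld_params <- function(residual_window_bp = 100000, residual_r2_cap = 0.95,
                      prune_r2 = 0.3, prune_window_snps = 50L, prune_step_snps = 5L,
                      shrink_neighbors = 150L, shrink_r2_threshold = 0.2,
                      reverse = FALSE) {
  stopifnot(residual_window_bp > 0, residual_r2_cap > 0, residual_r2_cap <= 1,
            prune_r2 > 0, prune_r2 < 1, shrink_r2_threshold > 0, shrink_r2_threshold < 1,
            shrink_neighbors >= 1)
  structure(list(residual_window_bp = residual_window_bp,
                 residual_r2_cap = residual_r2_cap, prune_r2 = prune_r2,
                 prune_window_snps = as.integer(prune_window_snps),
                 prune_step_snps = as.integer(prune_step_snps),
                 shrink_neighbors = as.integer(shrink_neighbors),
                 shrink_r2_threshold = shrink_r2_threshold,
                 reverse = isTRUE(reverse)),
            class = "ld_params")
}

new_grm <- function(A, sample_ids, snp_variances, norm_constant, method,
                    n_pairs = NULL, sample_fids = NULL) {
  structure(list(A = A, sample_ids = sample_ids, snp_variances = snp_variances,
                 norm_constant = norm_constant, method = method,
                 n_pairs = n_pairs, sample_fids = sample_fids),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("grm (%s): %d samples, norm constant %.4g, mean diagonal %.4g\n",
              x$method, nrow(x$A), x$norm_constant, mean(diag(x$A))))
  invisible(x)
}

.drop_monomorphic <- function(geno) {
  mono <- geno$snp_meta$maf <= 0 | is.na(geno$snp_meta$maf)
  if (any(mono)) {
    warning(sum(mono), " monomorphic SNP(s) excluded from GRM construction")
    geno <- subset_geno(geno, snps = !mono)
  }
  geno
}

#' Standard GRM
#'
#' Each SNP is mean-imputed, centered and scaled to unit variance; the GRM is
#' the cross-product of the normalized matrix divided by the SNP count:
#' \eqn{A = Z Z^T / m}.
#'
#' @param geno a \code{\link{genotype_matrix}} (monomorphic SNPs are
#'   excluded with a warning).
#' @return a \code{grm} object with unit \code{snp_variances} and
#'   \code{norm_constant = m}.
#' @export
standard_grm <- function(geno) {
  geno <- .drop_monomorphic(geno)
  Z <- normalize_genotypes(geno)
  m <- ncol(Z)
  A <- tcrossprod(Z) / m
  new_grm(A, geno$sample_meta$iid, stats::setNames(rep(1, m), geno$snp_meta$id),
          m, "standard", sample_fids = geno$sample_meta$fid)
}

#' Greedy LD-pruning
#'
#' Slides a window across each chromosome; within each placement the marker
#' in the most pairs above the r-squared threshold is removed greedily (ties
#' broken by leftmost position) until no offending pair remains in any
#' window placement.
#'
#' @param geno a \code{\link{genotype_matrix}}.
#' @param params an \code{\link{ld_params}} (uses \code{prune_r2},
#'   \code{prune_window_snps}, \code{prune_step_snps}).
#' @return character vector of retained SNP ids.
#' @export
ld_prune <- function(geno, params = ld_params()) {
  Z <- normalize_genotypes(geno)
  meta <- geno$snp_meta
  keep <- rep(TRUE, ncol(Z))
  for (chr in unique(meta$chrom)) {
    cidx <- which(meta$chrom == chr)
    repeat {
      removed_any <- FALSE
      alive <- cidx[keep[cidx]]
      if (length(alive) < 2L) break
      starts <- seq(1L, max(1L, length(alive) - 1L), by = params$prune_step_snps)
      for (s in starts) {
        w <- alive[s:min(s + params$prune_window_snps - 1L, length(alive))]
        w <- w[keep[w]]
        while (length(w) > 1L) {
          R2 <- stats::cor(Z[, w, drop = FALSE])^2
          diag(R2) <- 0
          deg <- colSums(R2 > params$prune_r2)
          if (max(deg) == 0L) break
          drop <- w[which.max(deg)]          # which.max: leftmost on ties
          keep[drop] <- FALSE
          removed_any <- TRUE
          w <- setdiff(w, drop)
        }
      }
      if (!removed_any) break
    }
  }
  meta$id[keep]
}

# Predictor retention under the r2 cap: scanning in window order, a SNP
# joins the retained predictor set unless it has r2 >= cap with an
# already-retained SNP inside its trailing window (leftmost kept).
.residual_chrom <- function(Zc, pos, params) {
  m <- ncol(Zc)
  ord <- if (params$reverse) rev(seq_len(m)) else seq_len(m)
  pos_o <- pos[ord]
  R <- matrix(0, nrow(Zc), m)
  retained <- logical(m)                     # in scan order
  for (jj in seq_len(m)) {
    j <- ord[jj]
    if (jj == 1L) {
      win <- integer(0)
    } else {
      prev <- seq_len(jj - 1L)
      dist <- abs(pos_o[jj] - pos_o[prev])
      win <- prev[retained[prev] & dist < params$residual_window_bp & dist > 0]
    }
    zj <- Zc[, j]
    if (length(win)) {
      Zw <- Zc[, ord[win], drop = FALSE]
      fit <- stats::lm.fit(Zw, zj)
      r <- fit$residuals
      if (anyNA(fit$coefficients)) {         # rank deficiency despite the cap
        warning("singular LD-residual window system; ridge fallback used")
        G <- crossprod(Zw) + diag(1e-6 * ncol(Zw), ncol(Zw))
        r <- zj - Zw %*% solve(G, crossprod(Zw, zj))
      }
      R[, j] <- r
      r2max <- max(stats::cor(zj, Zw)^2)
      retained[jj] <- r2max < params$residual_r2_cap
    } else {
      R[, j] <- zj
      retained[jj] <- TRUE
    }
  }
  R
}

#' LD-residual transform
#'
#' Each normalized marker is regressed on the retained normalized markers in
#' the preceding window (same chromosome) and replaced by the least-squares
#' residual; highly collinear predictors (r-squared at or above the cap) are
#' reduced to one so the regression is well-posed. The first marker on each
#' chromosome is returned unchanged.
#'
#' @param geno a \code{\link{genotype_matrix}}.
#' @param params an \code{\link{ld_params}}.
#' @return list with \code{residuals} (n x m matrix) and
#'   \code{snp_variances} (empirical variance of each residual, named).
#' @export
ld_residual <- function(geno, params = ld_params()) {
  geno <- .drop_monomorphic(geno)
  Z <- normalize_genotypes(geno)
  meta <- geno$snp_meta
  R <- matrix(0, nrow(Z), ncol(Z), dimnames = dimnames(Z))
  for (chr in unique(meta$chrom)) {
    cidx <- which(meta$chrom == chr)
    R[, cidx] <- .residual_chrom(Z[, cidx, drop = FALSE], meta$pos_bp[cidx], params)
  }
  v <- apply(R, 2L, stats::var)
  v[v < .Machine$double.eps * nrow(Z)] <- 0   # numerically exact collinearity
  list(residuals = R, snp_variances = stats::setNames(v, meta$id))
}

#' GRM from LD residuals
#'
#' \eqn{A = R R^T / \sum_j var(r_j)}: because residuals no longer have unit
#' variance, the cross-product is normalized by the summed empirical
#' residual variances rather than the SNP count.
#'
#' @param residuals n x m residual matrix from \code{\link{ld_residual}}.
#' @param snp_variances per-SNP residual variances.
#' @param sample_ids optional sample ids.
#' @return a \code{grm} object with \code{method = "ld_residual"}.
#' @export
grm_from_residuals <- function(residuals, snp_variances, sample_ids = NULL) {
  s <- sum(snp_variances)
  if (s <= 0) stop("all residual variances are zero; GRM undefined")
  A <- tcrossprod(residuals) / s
  if (is.null(sample_ids)) sample_ids <- rownames(residuals)
  new_grm(A, sample_ids, snp_variances, s, "ld_residual")
}

#' LD-shrink weights
#'
#' Down-weights each SNP by its count of high-LD neighbours among the
#' \code{shrink_neighbors} nearest markers (by SNP index, split evenly
#' around it, same chromosome): \eqn{w_j = 1 / (1 + \#\{r^2_{jk} > c\})}.
#' A SNP and its perfect proxy each get weight 1/2, jointly contributing one
#' SNP's worth of variance.
#'
#' @param geno a \code{\link{genotype_matrix}}.
#' @param params an \code{\link{ld_params}}.
#' @return named numeric vector of per-SNP weights in (0, 1].
#' @export
ld_shrink_weights <- function(geno, params = ld_params()) {
  Z <- normalize_genotypes(geno)
  meta <- geno$snp_meta
  half <- params$shrink_neighbors %/% 2L
  w <- numeric(ncol(Z))
  for (chr in unique(meta$chrom)) {
    cidx <- which(meta$chrom == chr)
    mc <- length(cidx)
    for (k in seq_len(mc)) {
      nb <- setdiff(seq(max(1L, k - half), min(mc, k + half)), k)
      if (!length(nb)) { w[cidx[k]] <- 1; next }
      r2 <- as.vector(stats::cor(Z[, cidx[k]], Z[, cidx[nb], drop = FALSE]))^2
      w[cidx[k]] <- 1 / (1 + sum(r2 > params$shrink_r2_threshold))
    }
  }
  stats::setNames(w, meta$id)
}

#' LD-shrink GRM
#'
#' Columns of the normalized genotype matrix are scaled by the square root
#' of their shrink weight; the GRM is normalized by the summed weights.
#'
#' @inheritParams ld_shrink_weights
#' @return a \code{grm} object with \code{method = "ld_shrink"}.
#' @export
ld_shrink_grm <- function(geno, params = ld_params()) {
  geno <- .drop_monomorphic(geno)
  w <- ld_shrink_weights(geno, params)
  Z <- normalize_genotypes(geno)
  Zw <- sweep(Z, 2L, sqrt(w), "*")
  A <- tcrossprod(Zw) / sum(w)
  new_grm(A, geno$sample_meta$iid, w, sum(w), "ld_shrink",
          sample_fids = geno$sample_meta$fid)
}

#' Build a GRM by method name
#'
#' @param geno a \code{\link{genotype_matrix}}.
#' @param method one of \code{"standard"}, \code{"pruned"},
#'   \code{"ld_residual"}, \code{"ld_shrink"}.
#' @param params an \code{\link{ld_params}}.
#' @return a \code{grm} object.
#' @export
build_grm <- function(geno, method = c("standard", "pruned", "ld_residual", "ld_shrink"),
                      params = ld_params()) {
  method <- match.arg(method)
  switch(method,
    standard = standard_grm(geno),
    pruned = {
      keep <- ld_prune(geno, params)
      g <- standard_grm(subset_geno(geno, snps = keep))
      g$method <- "pruned"
      g
    },
    ld_residual = {
      res <- ld_residual(geno, params)
      g <- grm_from_residuals(res$residuals, res$snp_variances,
                              geno$sample_meta$iid)
      g$sample_fids <- geno$sample_meta$fid
      g
    },
    ld_shrink = ld_shrink_grm(geno, params))
}

#' Per-locus GRM construction
#'
#' LD adjustment is performed on each locus independently (regression
#' windows never cross locus boundaries); the adjusted blocks are combined
#' into one GRM normalized by the summed post-adjustment variances across
#' all loci.
#'
#' @param geno a \code{\link{genotype_matrix}}.
#' @param locus_set a \code{\link{locus_set}} (or data.frame of intervals
#'   with \code{chrom,start_bp,end_bp}).
#' @param method GRM method, as in \code{\link{build_grm}}.
#' @param params an \code{\link{ld_params}}.
#' @return a \code{grm} object; empty loci are dropped with a warning and
#'   recorded in \code{attr(, "dropped_loci")}.
#' @export
local_grm <- function(geno, locus_set,
                      method = c("standard", "pruned", "ld_residual", "ld_shrink"),
                      params = ld_params()) {
  method <- match.arg(method)
  ints <- if (inherits(locus_set, "locus_set")) locus_set$intervals else locus_set
  meta <- geno$snp_meta
  blocks <- list(); vars <- list(); dropped <- integer(0)
  for (i in seq_len(nrow(ints))) {
    inside <- meta$chrom == ints$chrom[i] &
      meta$pos_bp >= ints$start_bp[i] & meta$pos_bp < ints$end_bp[i]
    inside <- inside & meta$maf > 0
    if (!any(inside)) { dropped <- c(dropped, i); next }
    sub <- subset_geno(geno, snps = which(inside))
    piece <- switch(method,
      standard = {
        Z <- normalize_genotypes(sub)
        list(M = Z, v = stats::setNames(rep(1, ncol(Z)), sub$snp_meta$id))
      },
      pruned = {
        keep <- ld_prune(sub, params)
        Z <- normalize_genotypes(subset_geno(sub, snps = keep))
        list(M = Z, v = stats::setNames(rep(1, ncol(Z)), keep))
      },
      ld_residual = {
        r <- ld_residual(sub, params)
        list(M = r$residuals, v = r$snp_variances)
      },
      ld_shrink = {
        w <- ld_shrink_weights(sub, params)
        Z <- normalize_genotypes(sub)
        list(M = sweep(Z, 2L, sqrt(w), "*"), v = w)
      })
    blocks[[length(blocks) + 1L]] <- piece$M
    vars[[length(vars) + 1L]] <- piece$v
  }
  if (length(dropped))
    warning(length(dropped), " locus/loci contained no polymorphic SNPs and were dropped")
  if (!length(blocks)) stop("no locus contains any polymorphic SNP")
  v <- unlist(vars)
  s <- sum(v)
  if (s <= 0) stop("total post-adjustment SNP variance is zero")
  M <- do.call(cbind, blocks)
  A <- tcrossprod(M) / s
  g <- new_grm(A, geno$sample_meta$iid, v, s, method,
               sample_fids = geno$sample_meta$fid)
  attr(g, "dropped_loci") <- dropped
  g
}

#' Fraction of LD-residual SNP variance in a locus set
#'
#' The third genome-fraction metric: summed post-adjustment SNP variances in
#' the loci divided by the genome-wide sum.
#'
#' @param snp_variances_local,snp_variances_global numeric vectors of
#'   per-SNP post-adjustment variances.
#' @return a fraction in [0, 1].
#' @export
effective_snp_fraction <- function(snp_variances_local, snp_variances_global) {
  s <- sum(snp_variances_global)
  if (s <= 0) stop("genome-wide SNP variance sum is zero")
  sum(snp_variances_local) / s
}
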