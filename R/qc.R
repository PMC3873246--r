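# Quality control: per-SNP filters (MAF, missingness, exact Hardy-Weinberg,
# differential missingness), relatedness pruning on the standard GRM,
# iterative PCA outlier removal, and PCA-based greedy case-control matching.

#' QC thresholds
#'
#' Defaults follow the common array-QC protocol for heritability analysis:
#' MAF >= 0.01, missingness <= 0.002, Hardy-Weinberg exact p >= 0.01,
#' differential-missingness p >= 0.05, 20 eigenvectors, 6 SD outlier limit,
#' 5 removal rounds.
#'
#' @param maf_min minimum minor-allele frequency.
#' @param miss_max maximum per-SNP missingness.
#' @param hwe_p_min minimum Hardy-Weinberg exact-test p-value (evaluated in
#'   controls only when case-control status is supplied).
#' @param diffmiss_p_min minimum differential-missingness p-value.
#' @param relatedness_cov_max maximum off-diagonal GRM entry between
#'   retained samples (0.05 by default; exposed because protocols vary).
#' @param pca_sd,pca_rounds,n_evec outlier-removal parameters.
#' @return a list of class \code{"qc_thresholds"}.
#' @export
qc_thresholds <- function(maf_min = 0.01, miss_max = 0.002, hwe_p_min = 0.01,
                          diffmiss_p_min = 0.05, relatedness_cov_max = 0.05,
                          pca_sd = 6, pca_rounds = 5L, n_evec = 20L) {
  stopifnot(hwe_p_min > 0, hwe_p_min < 1, diffmiss_p_min > 0, diffmiss_p_min < 1,
            pca_rounds >= 1, n_evec >= 1)
  structure(list(maf_min = maf_min, miss_max = miss_max, hwe_p_min = hwe_p_min,
                 diffmiss_p_min = diffmiss_p_min,
                 relatedness_cov_max = relatedness_cov_max,
                 pca_sd = pca_sd, pca_rounds = as.integer(pca_rounds),
                 n_evec = as.integer(n_evec)),
            class = "qc_thresholds")
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact (mid-p-free) test: conditioning on the observed allele counts, the
#' p-value is the summed probability of all heterozygote counts whose
#' conditional probability does not exceed that of the observed table.
#'
#' @param n_AA,n_Aa,n_aa genotype counts.
#' @return p-value in (0, 1].
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("HWE test undefined for zero genotyped samples")
  n_a <- 2L * min(n_AA, n_aa) + n_Aa          # minor-allele count
  if (n_a == 0L) return(1)
  # possible heterozygote counts share the parity of the minor allele count
  hets <- seq(n_a %% 2L, min(n_a, 2L * n - n_a), by = 2L)
  # log P(het = h | n, n_a) up to a shared constant
  logp <- vapply(hets, function(h) {
    hom_min <- (n_a - h) / 2
    hom_maj <- n - h - hom_min
    h * log(2) - lfactorial(h) - lfactorial(hom_min) - lfactorial(hom_maj)
  }, numeric(1L))
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_Aa, hets)]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

#' Differential missingness test
#'
#' Two-sided test of the 2x2 (missing vs typed) x (case vs control) table:
#' Fisher's exact test when any expected cell count is below 5, otherwise a
#' chi-square test without continuity correction.
#'
#' @param miss_case,n_case missing and total genotype calls in cases.
#' @param miss_ctrl,n_ctrl same in controls.
#' @return p-value in (0, 1].
#' @export
diff_missingness_test <- function(miss_case, n_case, miss_ctrl, n_ctrl) {
  stopifnot(miss_case <= n_case, miss_ctrl <= n_ctrl)
  tab <- matrix(c(miss_case, n_case - miss_case,
                  miss_ctrl, n_ctrl - miss_ctrl), 2L, 2L)
  if (sum(tab[1L, ]) == 0L || sum(tab[2L, ]) == 0L) return(1)   # degenerate margin
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    stats::fisher.test(tab)$p.value
  } else {
    unname(stats::chisq.test(tab, correct = FALSE)$p.value)
  }
}

#' Per-SNP QC filters
#'
#' Applies, in order, the MAF, missingness, Hardy-Weinberg (controls only
#' when \code{pheno_status} is given) and differential-missingness rules;
#' each removed SNP is reported with its first failing rule.
#'
#' @param geno a \code{\link{genotype_matrix}}.
#' @param pheno_status optional 0/1 per-sample case-control status (enables
#'   the differential-missingness rule and restricts HWE to controls).
#' @param thresholds a \code{\link{qc_thresholds}}.
#' @return list with \code{geno} (retained SNPs) and \code{drop_report}
#'   (data.frame: snp_id, rule, statistic, p).
#' @export
filter_snps <- function(geno, pheno_status = NULL, thresholds = qc_thresholds()) {
  geno <- update_snp_stats(geno)
  meta <- geno$snp_meta
  d <- geno$dosage
  n <- nrow(d); m <- ncol(d)
  rule <- rep(NA_character_, m)
  statv <- rep(NA_real_, m)
  pv <- rep(NA_real_, m)

  fail <- meta$maf < thresholds$maf_min | is.na(meta$maf)
  rule[fail] <- "maf"; statv[fail] <- meta$maf[fail]

  idx <- is.na(rule) & meta$missing_rate > thresholds$miss_max
  rule[idx] <- "missingness"; statv[idx] <- meta$missing_rate[idx]

  hwe_rows <- if (is.null(pheno_status)) seq_len(n) else which(pheno_status == 0)
  for (j in which(is.na(rule))) {
    x <- d[hwe_rows, j]
    x <- x[!is.na(x)]
    if (!length(x)) next
    p <- hwe_test(sum(x == 0L), sum(x == 1L), sum(x == 2L))
    if (p < thresholds$hwe_p_min) { rule[j] <- "hwe"; pv[j] <- p }
  }

  if (!is.null(pheno_status)) {
    case <- pheno_status == 1
    for (j in which(is.na(rule))) {
      p <- diff_missingness_test(sum(is.na(d[case, j])), sum(case),
                                 sum(is.na(d[!case, j])), sum(!case))
      if (p < thresholds$diffmiss_p_min) { rule[j] <- "diffmiss"; pv[j] <- p }
    }
  }

  dropped <- !is.na(rule)
  if (all(dropped)) stop("QC removed every SNP in the panel")
  report <- data.frame(snp_id = meta$id[dropped], rule = rule[dropped],
                       statistic = statv[dropped], p = pv[dropped],
                       stringsAsFactors = FALSE)
  list(geno = subset_geno(geno, snps = !dropped), drop_report = report)
}

#' Prune related samples
#'
#' Removes one of any pair of samples whose standard-GRM off-diagonal entry
#' exceeds the threshold, greedily dropping the sample participating in the
#' most offending pairs (ties broken by input order) until no pair remains.
#'
#' @param geno a \code{\link{genotype_matrix}}.
#' @param cov_max maximum allowed normalized SNP covariance.
#' @return character vector of retained sample iids.
#' @export
prune_related <- function(geno, cov_max = 0.05) {
  A <- standard_grm(geno)$A
  diag(A) <- 0
  keep <- rep(TRUE, nrow(A))
  repeat {
    off <- A > cov_max
    off[!keep, ] <- FALSE; off[, !keep] <- FALSE
    deg <- rowSums(off)
    if (max(deg) == 0L) break
    keep[which.max(deg)] <- FALSE            # which.max: first index on ties
  }
  geno$sample_meta$iid[keep]
}

#' Iterative PCA outlier removal
#'
#' Computes the top eigenvectors of the standard GRM, removes every sample
#' more than \code{sd_limit} standard deviations from the mean along any of
#' them, and repeats (recomputing eigenvectors) for up to \code{rounds}
#' rounds or until no outlier remains.
#'
#' @param geno a \code{\link{genotype_matrix}}.
#' @param n_evec number of top eigenvectors examined.
#' @param sd_limit outlier threshold in per-axis standard deviations.
#' @param rounds maximum removal rounds.
#' @return list with \code{eigenvectors} (final retained set, one column
#'   per axis, rownames = iid), \code{retained_ids}, \code{n_rounds},
#'   \code{removed} (iids per round).
#' @export
pca_outlier_loop <- function(geno, n_evec = 20L, sd_limit = 6, rounds = 5L) {
  retained <- geno$sample_meta$iid
  removed <- list()
  evec <- NULL
  r <- 0L
  repeat {
    r <- r + 1L
    sub <- subset_geno(geno, samples = retained)
    if (n_evec >= length(retained))
      stop("n_evec must be smaller than the number of retained samples")
    A <- standard_grm(sub)$A
    ed <- eigen(A, symmetric = TRUE)
    evec <- ed$vectors[, seq_len(n_evec), drop = FALSE]
    rownames(evec) <- retained
    zs <- scale(evec)
    zs[is.na(zs)] <- 0                       # constant axis: no outliers on it
    out <- rowSums(abs(zs) > sd_limit) > 0
    if (!any(out) || r >= rounds) {
      if (any(out) && r >= rounds) {
        removed[[r]] <- retained[out]
        retained <- retained[!out]
        evec <- evec[!out, , drop = FALSE]
      }
      break
    }
    removed[[r]] <- retained[out]
    retained <- retained[!out]
  }
  list(eigenvectors = evec, retained_ids = retained, n_rounds = r,
       removed = removed)
}

#' Greedy PCA-based case-control pair matching
#'
#' Each eigenvector is weighted by its squared correlation with the
#' phenotype; controls are visited in input order and each is paired with
#' the nearest unused case in the reweighted Euclidean metric (ties broken
#' by case input order) until either pool is exhausted.
#'
#' @param evecs matrix of eigenvectors (samples x axes; rownames used as
#'   ids when present).
#' @param pheno_status 0/1 per sample.
#' @return data.frame with columns \code{case_id}, \code{control_id},
#'   \code{distance}.
#' @export
pc_match <- function(evecs, pheno_status) {
  evecs <- as.matrix(evecs)
  ids <- rownames(evecs)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(evecs)))
  status <- as.integer(pheno_status)
  cases <- which(status == 1L); ctrls <- which(status == 0L)
  if (!length(cases) || !length(ctrls)) {
    warning("zero cases or zero controls: empty pairing")
    return(data.frame(case_id = character(0), control_id = character(0),
                      distance = numeric(0)))
  }
  w <- apply(evecs, 2L, function(e) {
    if (stats::sd(e) == 0) return(0)
    stats::cor(e, status)^2
  })
  E <- sweep(evecs, 2L, sqrt(w), "*")
  used <- logical(length(cases))
  pairs <- vector("list", min(length(cases), length(ctrls)))
  k <- 0L
  for (ci in ctrls) {
    if (all(used)) break
    free <- which(!used)
    d2 <- colSums((t(E[cases[free], , drop = FALSE]) - E[ci, ])^2)
    pick <- free[which.min(d2)]              # which.min: first on ties
    used[pick] <- TRUE
    k <- k + 1L
    pairs[[k]] <- data.frame(case_id = ids[cases[pick]], control_id = ids[ci],
                             distance = sqrt(min(d2)), stringsAsFactors = FALSE)
  }
  do.call(rbind, pairs[seq_len(k)])
}
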