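# Local heritability at known GWAS loci: locus definition with genome
# fraction (rho) metrics, the shrunk linear-model estimates (h2_gwas and the
# stepwise joint/conditional h2_joint), variance-component local estimates,
# the local expectation, analytic and empirical significance, and power.

# ---- locus sets ------------------------------------------------------------

.merge_intervals <- function(ints) {
  if (!nrow(ints)) return(ints)
  ints <- ints[order(ints$chrom, ints$start_bp), , drop = FALSE]
  out <- ints[1L, , drop = FALSE]
  for (i in seq_len(nrow(ints))[-1L]) {
    last <- nrow(out)
    if (ints$chrom[i] == out$chrom[last] && ints$start_bp[i] <= out$end_bp[last]) {
      out$end_bp[last] <- max(out$end_bp[last], ints$end_bp[i])
    } else {
      out <- rbind(out, ints[i, , drop = FALSE])
    }
  }
  rownames(out) <- NULL
  out
}

.subtract_intervals <- function(ints, excl) {
  if (is.null(excl) || !nrow(excl) || !nrow(ints)) return(ints)
  pieces <- list()
  for (i in seq_len(nrow(ints))) {
    segs <- data.frame(start_bp = ints$start_bp[i], end_bp = ints$end_bp[i])
    for (e in seq_len(nrow(excl))) {
      if (excl$chrom[e] != ints$chrom[i]) next
      new <- list()
      for (s in seq_len(nrow(segs))) {
        a <- segs$start_bp[s]; b <- segs$end_bp[s]
        ea <- excl$start_bp[e]; eb <- excl$end_bp[e]
        if (eb <= a || ea >= b) { new[[length(new) + 1L]] <- c(a, b); next }
        if (ea > a) new[[length(new) + 1L]] <- c(a, ea)
        if (eb < b) new[[length(new) + 1L]] <- c(eb, b)
      }
      if (!length(new)) { segs <- segs[0L, ]; break }
      segs <- data.frame(start_bp = vapply(new, `[`, 0, 1L),
                         end_bp = vapply(new, `[`, 0, 2L))
    }
    if (nrow(segs))
      pieces[[length(pieces) + 1L]] <- data.frame(chrom = ints$chrom[i], segs)
  }
  if (!length(pieces)) return(ints[0L, ])
  do.call(rbind, pieces)
}

#' The MHC exclusion region (chr6:26-34 Mbp)
#'
#' Routinely excluded from autoimmune-trait analyses for its complex LD and
#' many strong heterogeneous effects.
#' @return one-row data.frame (chrom, start_bp, end_bp).
#' @export
mhc_region <- function() data.frame(chrom = 6L, start_bp = 26e6, end_bp = 34e6)

#' Construct a locus set over a genotype panel
#'
#' Merges overlapping intervals, resolves SNP membership, and computes the
#' three genome-fraction metrics: physical bp fraction, SNP-count fraction,
#' and (when per-SNP LD-residual variances are supplied) the fraction of
#' post-adjustment SNP variance.
#'
#' @param intervals data.frame with \code{chrom}, \code{start_bp},
#'   \code{end_bp} (half-open, bp).
#' @param geno the \code{\link{genotype_matrix}} the fractions refer to.
#' @param snp_variances optional named per-SNP LD-residual variances for the
#'   whole panel (enables \code{rho_ldvar}).
#' @param provenance free-text provenance note.
#' @return an object of class \code{"locus_set"}: intervals, per-interval
#'   \code{member_snps}, \code{rho_physical}, \code{rho_snp},
#'   \code{rho_ldvar}, \code{provenance}.
#' @export
locus_set <- function(intervals, geno, snp_variances = NULL, provenance = "") {
  ints <- .merge_intervals(intervals[, c("chrom", "start_bp", "end_bp")])
  meta <- geno$snp_meta
  member <- lapply(seq_len(nrow(ints)), function(i)
    meta$id[meta$chrom == ints$chrom[i] &
              meta$pos_bp >= ints$start_bp[i] & meta$pos_bp < ints$end_bp[i]])
  genome_bp <- sum(vapply(split(meta$pos_bp, meta$chrom),
                          function(p) diff(range(p)) + 1, numeric(1L)))
  # clip each interval to the observed span of its chromosome
  covered <- vapply(seq_len(nrow(ints)), function(i) {
    p <- meta$pos_bp[meta$chrom == ints$chrom[i]]
    if (!length(p)) return(0)
    max(0, min(ints$end_bp[i], max(p) + 1) - max(ints$start_bp[i], min(p)))
  }, numeric(1L))
  rho_ldvar <- NA_real_
  if (!is.null(snp_variances)) {
    ids <- unlist(member)
    rho_ldvar <- effective_snp_fraction(snp_variances[intersect(ids, names(snp_variances))],
                                        snp_variances)
  }
  structure(list(intervals = ints, member_snps = member,
                 rho_physical = sum(covered) / genome_bp,
                 rho_snp = length(unlist(member)) / nrow(meta),
                 rho_ldvar = rho_ldvar, provenance = provenance),
            class = "locus_set")
}

#' @export
print.locus_set <- function(x, ...) {
  cat("locus_set:", nrow(x$intervals), "merged interval(s),",
      length(unlist(x$member_snps)), "member SNPs\n")
  cat(sprintf("  rho: physical %.4g, snp %.4g, ldvar %.4g\n",
              x$rho_physical, x$rho_snp, x$rho_ldvar))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Define GWAS loci from a catalog
#'
#' Centers a window on each catalog SNP resolvable in the panel, merges
#' overlapping windows, subtracts exclusion regions (the MHC by default for
#' chromosome-6 hits), and records the index-SNP list; in multi-hit merged
#' regions only the leading SNP (smallest \code{p} column if present,
#' otherwise the first catalog entry) is kept as index.
#'
#' @param catalog data.frame with a \code{snp_id} column (and optionally
#'   \code{trait}, \code{p}); ids are resolved against the panel,
#'   unresolvable entries are dropped with a message.
#' @param geno a \code{\link{genotype_matrix}}.
#' @param window_bp window size centered on each index SNP (default 1 Mbp).
#' @param exclude data.frame of exclusion intervals (default
#'   \code{\link{mhc_region}()}); \code{NULL} for none.
#' @param snp_variances optional LD-residual variances for
#'   \code{rho_ldvar}.
#' @return a \code{\link{locus_set}}; index SNP ids in
#'   \code{attr(, "index_snps")}.
#' @export
define_loci <- function(catalog, geno, window_bp = 1000000,
                        exclude = mhc_region(), snp_variances = NULL) {
  meta <- geno$snp_meta
  idx <- match(catalog$snp_id, meta$id)
  if (anyNA(idx)) {
    message(sum(is.na(idx)), " catalog SNP(s) not present in the panel were dropped")
    catalog <- catalog[!is.na(idx), , drop = FALSE]
    idx <- idx[!is.na(idx)]
  }
  if (!nrow(catalog)) stop("no catalog SNP resolves against the panel")
  ints <- data.frame(chrom = meta$chrom[idx],
                     start_bp = meta$pos_bp[idx] - window_bp / 2,
                     end_bp = meta$pos_bp[idx] + window_bp / 2)
  merged <- .merge_intervals(ints)
  merged <- .subtract_intervals(merged, exclude)
  if (!nrow(merged)) stop("all loci fall inside exclusion regions")
  ls <- locus_set(merged, geno, snp_variances = snp_variances,
                  provenance = paste0("catalog of ", nrow(catalog), " SNPs, ",
                                      window_bp / 1000, " kbp windows"))
  # leading index SNP per merged interval
  ord <- if ("p" %in% names(catalog)) order(catalog$p) else seq_len(nrow(catalog))
  index <- character(0)
  taken <- rep(FALSE, nrow(ls$intervals))
  for (k in ord) {
    pos <- meta$pos_bp[idx[k]]; chr <- meta$chrom[idx[k]]
    hit <- which(ls$intervals$chrom == chr & ls$intervals$start_bp <= pos &
                   ls$intervals$end_bp > pos)
    if (length(hit) && !taken[hit[1L]]) {
      taken[hit[1L]] <- TRUE
      index <- c(index, catalog$snp_id[k])
    }
  }
  attr(ls, "index_snps") <- index
  ls
}

# ---- linear-model estimates ------------------------------------------------

.covar_matrix <- function(covars, n) {
  if (is.null(covars)) return(matrix(1, n, 1L, dimnames = list(NULL, "affine")))
  X <- as.matrix(covars)
  if (!any(apply(X, 2L, function(c) stats::sd(c) == 0))) X <- cbind(affine = 1, X)
  X
}

.model_r2 <- function(y, X) {
  fit <- stats::lm.fit(X, y)
  1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
}

#' Variance explained by known GWAS index SNPs (shrunk)
#'
#' Joint linear model of all index SNPs plus covariates; the R-squared
#' attributed to the SNPs beyond the covariate-only model is shrunk by
#' subtracting 1/N per fitted SNP (the expected chance contribution of each
#' predictor) and floored at zero.
#'
#' @param geno a \code{\link{genotype_matrix}}.
#' @param y phenotype vector.
#' @param covars covariate matrix (affine term added if absent);
#'   \code{NULL} for intercept only.
#' @param index_snps character vector of index SNP ids.
#' @return list with \code{estimate}, \code{n_snps_used}, \code{r2_raw}.
#' @export
h2_gwas <- function(geno, y, covars = NULL, index_snps) {
  n <- length(y)
  X0 <- .covar_matrix(covars, n)
  Zi <- normalize_genotypes(subset_geno(geno, snps = index_snps))
  r2_0 <- .model_r2(y, X0)
  r2_1 <- .model_r2(y, cbind(X0, Zi))
  k <- length(index_snps)
  list(estimate = max(0, (r2_1 - r2_0) - k / n), n_snps_used = k,
       r2_raw = r2_1 - r2_0)
}

#' Stepwise joint/conditional variance explained (shrunk)
#'
#' Index SNPs are forced predictors; all other SNPs inside the loci are
#' univariately pre-screened at 0.05/m (m = number of candidates), then the
#' conditionally most associated surviving candidate is added iteratively
#' while its conditional p-value stays below 0.05/m. The final model
#' R-squared (beyond covariates) is shrunk by (#predictors)/N and floored
#' at zero. Collinear candidates are skipped with a log entry.
#'
#' @inheritParams h2_gwas
#' @param locus_set a \code{\link{locus_set}} giving the candidate pool.
#' @param alpha base significance level (default 0.05; Bonferroni-corrected
#'   by the candidate count).
#' @return list with \code{estimate}, \code{model_snps}, \code{n_added},
#'   \code{skipped}.
#' @export
h2_joint <- function(geno, y, covars = NULL, index_snps, locus_set, alpha = 0.05) {
  n <- length(y)
  X0 <- .covar_matrix(covars, n)
  candidates <- setdiff(unlist(locus_set$member_snps), index_snps)
  m <- length(candidates)
  thr <- if (m > 0) alpha / m else 0
  Zi <- normalize_genotypes(subset_geno(geno, snps = index_snps))
  model_snps <- index_snps
  Xcur <- cbind(X0, Zi)
  skipped <- character(0)
  if (m > 0) {
    Zc <- normalize_genotypes(subset_geno(geno, snps = candidates))
    # univariate screen (covariates included)
    pscreen <- vapply(seq_len(m), function(j) {
      f <- stats::lm(y ~ 0 + X0 + Zc[, j])
      cf <- summary(f)$coefficients
      cf[nrow(cf), 4L]
    }, numeric(1L))
    pool <- which(pscreen <= thr)
    while (length(pool)) {
      pcond <- vapply(pool, function(j) {
        Xj <- cbind(Xcur, Zc[, j])
        if (qr(Xj)$rank < ncol(Xj)) return(NA_real_)
        f <- stats::lm(y ~ 0 + Xj)
        cf <- summary(f)$coefficients
        cf[nrow(cf), 4L]
      }, numeric(1L))
      bad <- is.na(pcond)
      if (any(bad)) {
        skipped <- c(skipped, candidates[pool[bad]])
        pool <- pool[!bad]; pcond <- pcond[!bad]
        if (!length(pool)) break
      }
      best <- which.min(pcond)
      if (pcond[best] >= thr) break
      Xcur <- cbind(Xcur, Zc[, pool[best]])
      model_snps <- c(model_snps, candidates[pool[best]])
      pool <- pool[-best]
    }
  }
  r2 <- .model_r2(y, Xcur) - .model_r2(y, X0)
  list(estimate = max(0, r2 - length(model_snps) / n),
       model_snps = model_snps, n_added = length(model_snps) - length(index_snps),
       skipped = skipped)
}

# ---- variance-component local estimate and expectation ---------------------

#' Local variance-component heritability
#'
#' Builds a per-locus (optionally LD-adjusted) GRM over the locus SNPs and
#' fits a single-component REML model with covariates.
#'
#' @inheritParams h2_gwas
#' @param locus_set a \code{\link{locus_set}}.
#' @param adjustment GRM method (default \code{"ld_residual"}).
#' @param params an \code{\link{ld_params}}.
#' @param ... passed to \code{\link{greml}}.
#' @return a \code{\link{greml}} fit.
#' @export
h2_local <- function(geno, y, covars = NULL, locus_set,
                     adjustment = c("ld_residual", "standard", "pruned", "ld_shrink"),
                     params = ld_params(), ...) {
  adjustment <- match.arg(adjustment)
  g <- local_grm(geno, locus_set, method = adjustment, params = params)
  greml(y, list(local = g), X = .covar_matrix(covars, length(y)), ...)
}

#' Expected local heritability under the no-enrichment null
#'
#' The chance contribution of the genome landing inside the loci, on top of
#' the known associations: \code{h2_gwas + (h2_global - h2_gwas) * rho}
#' (with \code{h2_gwas = 0} this reduces to the pure \code{h2_global * rho}
#' form used for cross-trait loci; with \code{rho = 1} it equals
#' \code{h2_global}). With a genic adjustment, rho is split into genic and
#' non-genic parts, each scaled by the per-class heritability density of a
#' two-component genome-wide fit.
#'
#' @param h2_global genome-wide heritability estimate.
#' @param h2_gwas shrunk index-SNP estimate (0 for cross-trait loci).
#' @param locus_set a \code{\link{locus_set}} (or a bare rho value).
#' @param metric which genome fraction to use: \code{"physical"},
#'   \code{"snp"}, or \code{"ldvar"}.
#' @param composition \code{"additive"} (default; the form above) or
#'   \code{"rho_only"} (\code{h2_global * rho}, ignoring h2_gwas).
#' @param genic optional list with \code{rho_genic}, \code{rho_nongenic}
#'   (partition of the loci's rho), \code{h2_genic}, \code{h2_nongenic}
#'   (two-component genome-wide fit), \code{genic_frac} (genome-wide genic
#'   fraction).
#' @return the expected local heritability.
#' @export
local_expectation <- function(h2_global, h2_gwas = 0, locus_set,
                              metric = c("physical", "snp", "ldvar"),
                              composition = c("additive", "rho_only"),
                              genic = NULL) {
  metric <- match.arg(metric)
  composition <- match.arg(composition)
  rho <- if (inherits(locus_set, "locus_set")) {
    switch(metric, physical = locus_set$rho_physical,
           snp = locus_set$rho_snp, ldvar = locus_set$rho_ldvar)
  } else as.numeric(locus_set)
  if (!is.finite(rho)) stop("requested rho metric is not available")
  base <- if (composition == "rho_only") 0 else h2_gwas
  chance_scale <- if (composition == "rho_only") h2_global else h2_global - h2_gwas
  if (is.null(genic)) return(base + chance_scale * rho)
  stopifnot(all(c("rho_genic", "rho_nongenic", "h2_genic", "h2_nongenic",
                  "genic_frac") %in% names(genic)))
  weighted <- genic$h2_genic * genic$rho_genic / genic$genic_frac +
    genic$h2_nongenic * genic$rho_nongenic / (1 - genic$genic_frac)
  base + chance_scale * weighted / (genic$h2_genic + genic$h2_nongenic)
}

#' Flag SNPs as genic
#'
#' A marker is genic when it lies within \code{flank_bp} of an exon.
#'
#' @param geno a \code{\link{genotype_matrix}}.
#' @param exons data.frame of exon intervals (\code{chrom},
#'   \code{start_bp}, \code{end_bp}, half-open bp) or a BED file path
#'   (0-based half-open; converted).
#' @param flank_bp flank added to each exon (default 10 kbp).
#' @return logical vector over panel SNPs.
#' @export
genic_snps <- function(geno, exons, flank_bp = 10000) {
  if (is.character(exons)) {
    tab <- utils::read.table(exons, header = FALSE, stringsAsFactors = FALSE)
    exons <- data.frame(chrom = as.integer(sub("^chr", "", tab[[1L]])),
                        start_bp = tab[[2L]] + 1L, end_bp = tab[[3L]] + 1L)
  }
  meta <- geno$snp_meta
  out <- logical(nrow(meta))
  for (e in seq_len(nrow(exons))) {
    out <- out | (meta$chrom == exons$chrom[e] &
                    meta$pos_bp >= exons$start_bp[e] - flank_bp &
                    meta$pos_bp < exons$end_bp[e] + flank_bp)
  }
  out
}

# ---- empirical significance and power --------------------------------------

#' Empirical significance of local-heritability excess
#'
#' Repeatedly draws random locus sets of the same size as the observed one
#' (\code{n_loci} windows of \code{locus_span_bp}, drawn with replacement
#' across draws, optionally avoiding exclusion regions), estimates the local
#' heritability of each draw, and compares each draw's excess over its own
#' chance expectation (conservatively taking the sampled h2_gwas as 0) with
#' the observed excess. The empirical p-value uses the (r+1)/(R+1)
#' convention.
#'
#' @inheritParams h2_gwas
#' @param n_loci,locus_span_bp random locus-set geometry.
#' @param n_draws number of draws (values below 100 trigger a resolution
#'   warning).
#' @param exclusions data.frame of intervals random draws must not overlap
#'   (e.g. the focal trait's own GWAS loci in cross-trait mode).
#' @param observed_excess the observed \code{h2_local - expected}.
#' @param h2_global genome-wide estimate used for the draw expectations.
#' @param adjustment,params GRM construction for the draws.
#' @param metric rho metric for the draw expectations.
#' @param seed integer seed.
#' @return list with \code{p_empirical} and \code{draws} (data.frame of
#'   per-draw h2, rho, excess).
#' @export
empirical_null <- function(geno, y, covars = NULL, n_loci, locus_span_bp,
                           n_draws = 1000L, exclusions = NULL,
                           observed_excess, h2_global,
                           adjustment = "ld_residual", params = ld_params(),
                           metric = "physical", seed = 1L) {
  if (n_draws < 100L)
    warning("fewer than 100 draws: empirical p-value resolution is only 1/",
            n_draws + 1L)
  meta <- geno$snp_meta
  set.seed(as.integer(seed))
  X <- .covar_matrix(covars, length(y))
  draws <- data.frame(h2 = numeric(n_draws), rho = numeric(n_draws),
                      excess = numeric(n_draws))
  for (r in seq_len(n_draws)) {
    ints <- NULL
    tries <- 0L
    while (is.null(ints) && tries < 200L) {
      tries <- tries + 1L
      anchors <- sample.int(nrow(meta), n_loci, replace = TRUE)
      cand <- data.frame(chrom = meta$chrom[anchors],
                         start_bp = meta$pos_bp[anchors] - locus_span_bp / 2,
                         end_bp = meta$pos_bp[anchors] + locus_span_bp / 2)
      if (!is.null(exclusions) && nrow(exclusions)) {
        bad <- FALSE
        for (e in seq_len(nrow(exclusions))) {
          bad <- bad | (cand$chrom == exclusions$chrom[e] &
                          cand$start_bp < exclusions$end_bp[e] &
                          cand$end_bp > exclusions$start_bp[e])
        }
        if (any(bad)) next
      }
      ints <- cand
    }
    if (is.null(ints)) stop("could not draw loci avoiding the exclusion regions")
    ls <- locus_set(ints, geno, provenance = "empirical_null draw")
    fit <- h2_local(geno, y, covars = X, locus_set = ls,
                    adjustment = adjustment, params = params)
    rho <- switch(metric, physical = ls$rho_physical, snp = ls$rho_snp,
                  ldvar = ls$rho_ldvar)
    exp_r <- local_expectation(h2_global, 0, rho)
    draws$h2[r] <- fit$h2[["total"]]
    draws$rho[r] <- rho
    draws$excess[r] <- fit$h2[["total"]] - exp_r
  }
  list(p_empirical = (sum(draws$excess >= observed_excess) + 1) / (n_draws + 1),
       draws = draws)
}

#' Power of the local-heritability increase test
#'
#' Fraction of simulation replicates in which the local estimate is
#' significantly above its reference by one-sided z-test at level
#' \code{alpha} using the analytical standard error.
#'
#' @param sim_fn \code{function(rep)} returning a list with \code{h2_est},
#'   \code{se_est}, \code{expected}.
#' @param n_reps number of replicates.
#' @param alpha significance level (default 0.05).
#' @return list with \code{power}, \code{p_values}.
#' @export
power_curve <- function(sim_fn, n_reps = 100L, alpha = 0.05) {
  pv <- vapply(seq_len(n_reps), function(r) {
    s <- sim_fn(r)
    ztest_increase(s$h2_est, s$se_est, s$expected)$p
  }, numeric(1L))
  list(power = mean(pv < alpha), p_values = pv)
}

#' End-to-end local-heritability analysis
#'
#' Convenience pipeline: defines loci from a catalog, computes the shrunk
#' index-SNP estimate, the stepwise joint estimate, the (LD-adjusted) local
#' variance-component estimate, the chance expectation, and the one-sided
#' z-test of the increase.
#'
#' @inheritParams h2_gwas
#' @param catalog GWAS catalog data.frame (see \code{\link{define_loci}}).
#' @param h2_global genome-wide heritability (a \code{greml} fit or a
#'   number; when a fit, its SE is carried through).
#' @param window_bp,exclude locus-definition parameters.
#' @param adjustment,params,metric estimation parameters.
#' @return list of class \code{"local_result"}: \code{h2_gwas},
#'   \code{h2_joint}, \code{h2_local} (fit), \code{expected}, \code{gain},
#'   \code{z}, \code{p_analytic}, \code{loci}.
#' @export
analyze_local <- function(geno, y, covars = NULL, catalog, h2_global,
                          window_bp = 1000000, exclude = mhc_region(),
                          adjustment = "ld_residual", params = ld_params(),
                          metric = "physical") {
  ls <- define_loci(catalog, geno, window_bp = window_bp, exclude = exclude)
  index <- attr(ls, "index_snps")
  hg <- h2_gwas(geno, y, covars, index)
  hj <- h2_joint(geno, y, covars, index, ls)
  fit <- h2_local(geno, y, covars, ls, adjustment = adjustment, params = params)
  h2g <- if (inherits(h2_global, "greml")) h2_global$h2[["total"]] else h2_global
  expected <- local_expectation(h2g, hg$estimate, ls, metric = metric)
  zt <- ztest_increase(fit$h2[["total"]], fit$se_h2[["total"]], expected)
  structure(list(h2_gwas = hg$estimate, h2_joint = hj$estimate,
                 h2_local = fit, expected = expected, gain = zt$gain,
                 z = zt$z, p_analytic = zt$p, loci = ls,
                 joint_model_snps = hj$model_snps),
            class = "local_result")
}

#' @export
print.local_result <- function(x, ...) {
  cat("Local heritability at GWAS loci\n")
  cat(sprintf("  h2_gwas  = %.4f\n  h2_joint = %.4f\n", x$h2_gwas, x$h2_joint))
  cat(sprintf("  h2_local = %.4f (SE %.4f)\n", x$h2_local$h2[["total"]],
              x$h2_local$se_h2[["total"]]))
  cat(sprintf("  expected = %.4f; gain = %.2f; z = %.2f; p = %.3g\n",
              x$expected, x$gain, x$z, x$p_analytic))
  invisible(x)
}
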