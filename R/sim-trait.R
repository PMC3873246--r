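# Polygenic trait simulators: a genome-wide architecture (many causal SNPs
# drawn across minor-allele-frequency classes) and a local architecture
# (a fixed number of 1 Mbp loci, each centered on a small causal cluster),
# plus the idealized best-tag "GWAS SNP" computation and liability-threshold
# case-control ascertainment.

#' Trait simulator configuration
#'
#' @param n_causal number of causal SNPs (genome-wide mode: total; local
#'   mode: per locus).
#' @param frac_lowfreq genome-wide mode: fraction of causals drawn from the
#'   low-frequency class (MAF < 0.05); the remainder are drawn from
#'   MAF >= 0.05.
#' @param maf_class local mode: \code{"low"} (MAF in [0.01, 0.05)) or
#'   \code{"common"} (MAF > 0.10). SNPs with MAF in [0.05, 0.10] are never
#'   drawn as causal in class-restricted designs.
#' @param effect_model \code{"equal_variance"} (fixed-magnitude effect on
#'   the normalized-genotype scale with random sign, i.e. allelic effect
#'   variance 1/(2p(1-p)); every causal contributes equal phenotypic
#'   variance), \code{"normalized_normal"} (standard-normal effects on the
#'   normalized scale; equal contribution in expectation only), or
#'   \code{"allelic_normal"} (standard-normal allelic effects).
#' @param target_h2 heritability induced in the realized sample (noise is
#'   orthogonalized against the genetic values and rescaled so
#'   Var(g)/Var(y) equals this exactly).
#' @param n_loci,locus_span_bp local mode: number of disjoint loci and
#'   their span (defaults 180 and 1 Mbp, the architecture scale reported
#'   for adult height).
#' @param seed integer seed.
#' @return a list of class \code{"trait_sim_config"}.
#' @export
trait_sim_config <- function(n_causal = 5000L, frac_lowfreq = 0.5,
                             maf_class = c("common", "low"),
                             effect_model = c("equal_variance", "normalized_normal",
                                              "allelic_normal"),
                             target_h2 = 0.8, n_loci = 180L,
                             locus_span_bp = 1000000, seed = 1L) {
  effect_model <- match.arg(effect_model)
  maf_class <- match.arg(maf_class)
  stopifnot(target_h2 > 0, target_h2 < 1, frac_lowfreq >= 0, frac_lowfreq <= 1,
            n_causal >= 1, n_loci >= 1, locus_span_bp > 0)
  structure(list(n_causal = as.integer(n_causal), frac_lowfreq = frac_lowfreq,
                 maf_class = maf_class, effect_model = effect_model,
                 target_h2 = target_h2, n_loci = as.integer(n_loci),
                 locus_span_bp = locus_span_bp, seed = as.integer(seed)),
            class = "trait_sim_config")
}

.maf_class_mask <- function(maf, class) {
  switch(class,
         low = maf >= 0.01 & maf < 0.05,
         common = maf > 0.10,
         stop("unknown MAF class: ", class))
}

.draw_effects <- function(model, k, sdv) {
  # returns effects on the normalized-genotype scale; allelic = u / sd
  switch(model,
         equal_variance = sample(c(-1, 1), k, replace = TRUE),
         normalized_normal = stats::rnorm(k),
         allelic_normal = stats::rnorm(k) * sdv)
}

.finish_trait <- function(g, target_h2, seed) {
  # noise orthogonalized against g and scaled so Var(g)/Var(y) == target_h2
  .substream(seed, "noise")
  n <- length(g)
  e <- stats::rnorm(n)
  vg <- stats::var(g)
  if (vg <= 0) stop("genetic values have zero variance; cannot scale noise")
  e <- e - mean(e)
  gc <- g - mean(g)
  e <- e - gc * sum(e * gc) / sum(gc^2)
  e <- e * sqrt(vg * (1 - target_h2) / target_h2 / stats::var(e))
  y <- g + e
  list(y = y, realized_h2 = vg / stats::var(y))
}

#' Simulate a genome-wide polygenic trait
#'
#' Draws \code{n_causal} causal SNPs without replacement such that a
#' fraction \code{frac_lowfreq} is low-frequency (MAF < 0.05), assigns
#' effects under the chosen model, and adds Gaussian noise scaled so the
#' realized-sample heritability equals \code{target_h2} exactly.
#'
#' @param geno a \code{\link{genotype_matrix}}.
#' @param config a \code{\link{trait_sim_config}}.
#' @return an object of class \code{"trait_truth"}: list with \code{y},
#'   \code{g}, \code{causal_ids}, \code{beta_allelic}, \code{beta_norm},
#'   \code{realized_h2}, \code{target_h2}.
#' @export
simulate_trait_genomewide <- function(geno, config) {
  stopifnot(inherits(config, "trait_sim_config"))
  maf <- geno$snp_meta$maf
  low <- which(maf >= 0.01 & maf < 0.05)
  high <- which(maf >= 0.05)
  n_low <- round(config$frac_lowfreq * config$n_causal)
  n_high <- config$n_causal - n_low
  if (length(low) < n_low)
    stop(sprintf("need %d low-frequency SNPs (MAF < 0.05), panel has %d", n_low, length(low)))
  if (length(high) < n_high)
    stop(sprintf("need %d SNPs with MAF >= 0.05, panel has %d", n_high, length(high)))
  .substream(config$seed, "causals")
  causal <- c(if (n_low > 0) sample(low, n_low),
              if (n_high > 0) sample(high, n_high))
  causal <- sort(causal)
  Zc <- normalize_genotypes(subset_geno(geno, snps = causal))
  d <- geno$dosage[, causal, drop = FALSE]
  sdv <- apply(d, 2L, function(x) stats::sd(ifelse(is.na(x), mean(x, na.rm = TRUE), x)))
  .substream(config$seed, "effects")
  u <- .draw_effects(config$effect_model, length(causal), sdv)
  g <- drop(Zc %*% u)
  tr <- .finish_trait(g, config$target_h2, config$seed)
  structure(list(y = tr$y, g = g, causal_ids = geno$snp_meta$id[causal],
                 beta_norm = stats::setNames(u, geno$snp_meta$id[causal]),
                 beta_allelic = stats::setNames(u / sdv, geno$snp_meta$id[causal]),
                 realized_h2 = tr$realized_h2, target_h2 = config$target_h2,
                 effect_model = config$effect_model, loci = NULL),
            class = "trait_truth")
}

#' Simulate a local (GWAS-locus) trait architecture
#'
#' Places \code{n_loci} disjoint windows of \code{locus_span_bp}, each
#' centered (up to a uniform jitter of 10% of the span) on a cluster of
#' \code{n_causal} causal variants drawn from the requested MAF class, and
#' generates a trait whose realized heritability equals \code{target_h2}
#' exactly.
#'
#' @inheritParams simulate_trait_genomewide
#' @return a \code{"trait_truth"} whose \code{loci} element is a
#'   \code{\link{locus_set}}; \code{locus_table} holds per-locus causal ids,
#'   normalized effects and realized per-locus genetic variance.
#' @export
simulate_trait_local <- function(geno, config) {
  stopifnot(inherits(config, "trait_sim_config"))
  meta <- geno$snp_meta
  span <- config$locus_span_bp
  eligible <- which(.maf_class_mask(meta$maf, config$maf_class))
  if (!length(eligible))
    stop("no SNPs in the requested MAF class (", config$maf_class, ")")
  .substream(config$seed, "loci")
  ints <- data.frame(chrom = integer(0), start_bp = numeric(0), end_bp = numeric(0))
  causal_sets <- list()
  pool <- eligible
  tries <- 0L; max_tries <- 80L * config$n_loci
  while (nrow(ints) < config$n_loci && tries < max_tries && length(pool)) {
    tries <- tries + 1L
    anchor <- pool[sample.int(length(pool), 1L)]
    jitter <- stats::runif(1L, -0.1, 0.1) * span
    start <- meta$pos_bp[anchor] - span / 2 + jitter
    end <- start + span
    chr <- meta$chrom[anchor]
    cpos <- meta$pos_bp[meta$chrom == chr]
    if (start < min(cpos) || end > max(cpos)) next
    same <- ints$chrom == chr
    if (any(same & ints$start_bp < end & ints$end_bp > start)) next
    inside <- eligible[meta$chrom[eligible] == chr &
                         meta$pos_bp[eligible] >= start & meta$pos_bp[eligible] < end]
    if (length(inside) < config$n_causal) next
    others <- setdiff(inside, anchor)
    cset <- c(anchor, if (config$n_causal > 1L)
      others[sample.int(length(others), config$n_causal - 1L)])
    ints <- rbind(ints, data.frame(chrom = chr, start_bp = start, end_bp = end))
    causal_sets[[nrow(ints)]] <- sort(cset)
    pool <- pool[!(meta$chrom[pool] == chr &
                     meta$pos_bp[pool] >= start & meta$pos_bp[pool] < end)]
  }
  if (nrow(ints) < config$n_loci)
    stop(sprintf("could only place %d of %d disjoint %g-bp loci on this panel",
                 nrow(ints), config$n_loci, span))
  o <- order(ints$chrom, ints$start_bp)
  ints <- ints[o, , drop = FALSE]; rownames(ints) <- NULL
  causal_sets <- causal_sets[o]
  causal <- unlist(causal_sets)
  Zc <- normalize_genotypes(subset_geno(geno, snps = causal))
  d <- geno$dosage[, causal, drop = FALSE]
  sdv <- apply(d, 2L, function(x) stats::sd(ifelse(is.na(x), mean(x, na.rm = TRUE), x)))
  .substream(config$seed, "effects")
  u <- .draw_effects(config$effect_model, length(causal), sdv)
  names(u) <- meta$id[causal]
  g_locus <- matrix(0, nrow(geno$dosage), nrow(ints))
  k0 <- 0L
  for (l in seq_len(nrow(ints))) {
    kl <- length(causal_sets[[l]])
    g_locus[, l] <- Zc[, k0 + seq_len(kl), drop = FALSE] %*% u[k0 + seq_len(kl)]
    k0 <- k0 + kl
  }
  g <- rowSums(g_locus)
  tr <- .finish_trait(g, config$target_h2, config$seed)
  loci <- locus_set(ints, geno, provenance = "simulate_trait_local")
  locus_table <- data.frame(locus = seq_len(nrow(ints)),
                            chrom = ints$chrom, start_bp = ints$start_bp,
                            end_bp = ints$end_bp,
                            n_causal = vapply(causal_sets, length, integer(1L)),
                            var_g = apply(g_locus, 2L, stats::var))
  locus_table$causal_ids <- lapply(causal_sets, function(s) meta$id[s])
  structure(list(y = tr$y, g = g, g_locus = g_locus,
                 causal_ids = meta$id[causal], beta_norm = u,
                 beta_allelic = u / sdv,
                 realized_h2 = tr$realized_h2, target_h2 = config$target_h2,
                 effect_model = config$effect_model, loci = loci,
                 locus_table = locus_table),
            class = "trait_truth")
}

#' @export
print.trait_truth <- function(x, ...) {
  cat("trait_truth:", length(x$y), "samples,", length(x$causal_ids),
      "causal SNPs,", if (is.null(x$loci)) "genome-wide" else
        paste0(nrow(x$loci$intervals), " loci"), "\n")
  cat(sprintf("  realized h2 = %.6f (target %.3f), effect model %s\n",
              x$realized_h2, x$target_h2, x$effect_model))
  invisible(x)
}

#' Idealized GWAS SNP of one locus
#'
#' The single best tag of a locus's causal variants: for each candidate tag
#' t the noise-free marginal effect is \eqn{\sum_c \beta_c r(t, c)} over the
#' causal set (effects and correlations on the normalized-genotype scale,
#' correlations from the full sample); the tag maximizing the squared
#' marginal effect is returned. This is the variance a GWAS would attribute
#' to the locus's lead SNP with no sampling noise.
#'
#' @param geno a \code{\link{genotype_matrix}}.
#' @param causal_effects named vector of normalized-scale causal effects
#'   (names are SNP ids present in \code{geno}).
#' @param tag_panel character vector of candidate tag SNP ids.
#' @return list with \code{snp_id}, \code{marginal_effect},
#'   \code{captured_variance} (its square).
#' @export
ideal_gwas_snp <- function(geno, causal_effects, tag_panel) {
  if (!length(tag_panel)) stop("empty tag panel")
  Zc <- normalize_genotypes(subset_geno(geno, snps = names(causal_effects)))
  Zt <- normalize_genotypes(subset_geno(geno, snps = tag_panel))
  n <- nrow(Zc)
  r <- crossprod(Zt, Zc) / (n - 1L)          # tags x causals correlations
  marg <- drop(r %*% causal_effects)
  best <- which.max(marg^2)
  list(snp_id = tag_panel[best], marginal_effect = unname(marg[best]),
       captured_variance = unname(marg[best]^2))
}

#' Idealized GWAS SNPs for every locus of a simulated local trait
#'
#' @param geno a \code{\link{genotype_matrix}}.
#' @param truth a \code{"trait_truth"} from
#'   \code{\link{simulate_trait_local}}.
#' @param tag_panel candidate tag ids (default: all panel SNPs); per locus,
#'   tags are restricted to SNPs inside the locus.
#' @param hide_causals exclude the causal variants from the tag panel (the
#'   realistic untyped-causal scenario).
#' @return list with \code{per_locus} (data.frame: locus, snp_id, effect,
#'   captured, var_g), \code{h2gwas_true} (summed captured variance over
#'   Var(y)), and \code{capture_fraction} (summed captured variance over the
#'   summed per-locus genetic variances).
#' @export
ideal_gwas <- function(geno, truth, tag_panel = NULL, hide_causals = FALSE) {
  if (is.null(truth$loci)) stop("truth must come from simulate_trait_local")
  if (is.null(tag_panel)) tag_panel <- geno$snp_meta$id
  if (hide_causals) tag_panel <- setdiff(tag_panel, truth$causal_ids)
  lt <- truth$locus_table
  members <- truth$loci$member_snps
  out <- lapply(seq_len(nrow(lt)), function(l) {
    tags <- intersect(members[[l]], tag_panel)
    if (!length(tags))
      return(data.frame(locus = l, snp_id = NA_character_, effect = 0,
                        captured = 0, var_g = lt$var_g[l]))
    eff <- truth$beta_norm[lt$causal_ids[[l]]]
    b <- ideal_gwas_snp(geno, eff, tags)
    data.frame(locus = l, snp_id = b$snp_id, effect = b$marginal_effect,
               captured = b$captured_variance, var_g = lt$var_g[l])
  })
  per_locus <- do.call(rbind, out)
  list(per_locus = per_locus,
       h2gwas_true = sum(per_locus$captured) / stats::var(truth$y),
       capture_fraction = sum(per_locus$captured) / sum(per_locus$var_g))
}

#' Liability-threshold case-control ascertainment
#'
#' Liability is the genetic value plus Gaussian noise; samples in the upper
#' \code{K} tail are cases. A study sample of \code{n_target} individuals is
#' then drawn with case fraction \code{P} (over-sampling cases relative to
#' the population when P > K).
#'
#' @param g genetic values.
#' @param noise_var environmental variance on the liability scale.
#' @param K population prevalence (upper-tail fraction of liability).
#' @param P target in-sample case fraction.
#' @param n_target study sample size.
#' @param seed integer seed.
#' @return list with \code{status} (0/1 for the full population),
#'   \code{sampled_ids} (indices of the ascertained study sample) and
#'   \code{threshold}.
#' @export
ascertain_case_control <- function(g, noise_var, K, P, n_target, seed = 1L) {
  stopifnot(K > 0, K < 1, P > 0, P < 1, n_target >= 2)
  .substream(seed, "ascertain")
  liab <- g + stats::rnorm(length(g), 0, sqrt(noise_var))
  thr <- stats::quantile(liab, 1 - K, names = FALSE)
  status <- as.integer(liab > thr)
  n_case <- round(P * n_target)
  n_ctrl <- n_target - n_case
  if (sum(status) < n_case || sum(!status) < n_ctrl)
    stop("population too small for the requested ascertainment")
  ids <- c(sample(which(status == 1L), n_case),
           sample(which(status == 0L), n_ctrl))
  list(status = status, sampled_ids = sort(ids), threshold = thr)
}
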