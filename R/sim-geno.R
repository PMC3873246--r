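# Synthetic genotype panels: a latent-Gaussian haplotype model with
# first-order Markov (AR(1)) dependence along each chromosome, thresholded
# per SNP to a drawn minor-allele frequency. Two haplotypes are summed per
# sample. Closed-form control of LD decay makes this adequate for studying
# the LD-driven biases of GRM-based heritability estimation; it is not a
# coalescent model and carries no mutation/recombination history.

#' Genotype simulator configuration
#'
#' @param n_samples,n_snps panel dimensions.
#' @param maf_spectrum allele-frequency spectrum over (0.01, 0.5):
#'   \code{"uniform"}, \code{"sfs"} (density proportional to 1/f, mimicking
#'   the skew towards low-frequency variants of a neutral site-frequency
#'   spectrum), a numeric vector of length \code{n_snps}, or a
#'   \code{function(m)} returning one.
#' @param ld_rho adjacent-site correlation of the latent haplotype Gaussian:
#'   a scalar in [0, 1) (0 gives independent SNPs), or a
#'   \code{function(maf)} returning a per-site value, which emulates
#'   frequency-dependent LD (low-frequency alleles are younger and carry
#'   less LD with their neighbours than common alleles, the mechanism
#'   behind the LD-induced bias of standard-GRM heritability estimates).
#'   Genotype-scale r-squared is lower after thresholding, and attenuates
#'   further between SNPs of unequal frequency.
#' @param bp_spacing mean inter-SNP spacing in bp (geometric draws).
#' @param n_chrom number of chromosomes (SNPs split evenly).
#' @param miss_rate per-genotype missingness rate (default 0).
#' @param seed integer seed; all downstream randomness derives from it.
#' @return a list of class \code{"geno_sim_config"}.
#' @export
geno_sim_config <- function(n_samples, n_snps, maf_spectrum = "uniform",
                            ld_rho = 0, bp_spacing = 3000, n_chrom = 1L,
                            miss_rate = 0, seed = 1L) {
  if (!is.function(ld_rho)) stopifnot(ld_rho >= 0, ld_rho < 1)
  stopifnot(n_samples >= 1, n_snps >= 1,
            bp_spacing >= 1, n_chrom >= 1, miss_rate >= 0, miss_rate < 1)
  structure(list(n_samples = as.integer(n_samples), n_snps = as.integer(n_snps),
                 maf_spectrum = maf_spectrum, ld_rho = ld_rho,
                 bp_spacing = bp_spacing, n_chrom = as.integer(n_chrom),
                 miss_rate = miss_rate, seed = as.integer(seed)),
            class = "geno_sim_config")
}

# named substreams off one base seed, so any stage can be re-rolled alone
.substream <- function(seed, name) {
  offs <- c(genotypes = 101L, causals = 211L, effects = 307L, noise = 401L,
            missing = 503L, loci = 601L, permute = 701L, ascertain = 811L)
  if (!name %in% names(offs)) stop("unknown substream: ", name)
  set.seed((as.integer(seed) %% 1000000L) * 1000L + offs[[name]])
}

.draw_mafs <- function(spec, m) {
  if (is.function(spec)) {
    maf <- spec(m)
  } else if (is.numeric(spec)) {
    if (length(spec) != m) stop("numeric maf_spectrum must have length n_snps")
    maf <- spec
  } else if (identical(spec, "uniform")) {
    maf <- stats::runif(m, 0.01, 0.5)
  } else if (identical(spec, "sfs")) {
    maf <- 0.01 * (0.5 / 0.01)^stats::runif(m)   # log-uniform, density ~ 1/f
  } else stop("unknown maf_spectrum: ", spec)
  if (any(maf < 0.01 - 1e-12 | maf > 0.5 + 1e-12)) {
    warning("maf_spectrum values outside (0.01, 0.5) were clipped")
    maf <- pmin(pmax(maf, 0.01), 0.5)
  }
  maf
}

#' Simulate an LD-structured genotype panel
#'
#' Haplotypes are latent Gaussian AR(1) chains along each chromosome with
#' adjacent-site correlation \code{ld_rho}, thresholded so site j carries
#' the minor allele with probability \code{maf[j]}; a sample's dosage is the
#' sum of its two haplotypes. Positions accumulate geometric gaps with mean
#' \code{bp_spacing}. Fully reproducible from \code{config$seed}.
#'
#' @param config a \code{\link{geno_sim_config}}.
#' @return a \code{\link{genotype_matrix}} (allele1 "A", allele2 "B";
#'   dosages count "B", the designated minor allele).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "geno_sim_config"))
  n <- config$n_samples; m <- config$n_snps
  .substream(config$seed, "genotypes")
  maf <- .draw_mafs(config$maf_spectrum, m)
  thr <- stats::qnorm(maf)
  chrom <- rep(seq_len(config$n_chrom), length.out = m)
  chrom <- sort(chrom)
  dos <- matrix(0L, n, m)
  nh <- 2L * n
  rho_site <- if (is.function(config$ld_rho)) {
    r <- config$ld_rho(maf)
    if (any(r < 0 | r >= 1)) {
      warning("per-site ld_rho values outside [0, 1) were clipped")
      r <- pmin(pmax(r, 0), 1 - 1e-9)
    }
    r
  } else rep(config$ld_rho, m)
  z <- stats::rnorm(nh)
  for (j in seq_len(m)) {
    new_chrom <- j == 1L || chrom[j] != chrom[j - 1L]
    rho <- rho_site[j]
    z <- if (new_chrom) stats::rnorm(nh)
         else rho * z + sqrt(1 - rho^2) * stats::rnorm(nh)
    carrier <- z <= thr[j]
    dos[, j] <- as.integer(carrier[seq_len(n)]) + as.integer(carrier[(n + 1L):nh])
  }
  pos <- integer(m)
  for (cc in unique(chrom)) {
    idx <- which(chrom == cc)
    gaps <- 1L + stats::rgeom(length(idx), 1 / config$bp_spacing)
    pos[idx] <- cumsum(gaps)
  }
  if (config$miss_rate > 0) {
    .substream(config$seed, "missing")
    dos[stats::runif(length(dos)) < config$miss_rate] <- NA_integer_
  }
  snp_meta <- data.frame(chrom = chrom, id = sprintf("snp%06d", seq_len(m)),
                         pos_bp = pos, allele1 = "A", allele2 = "B",
                         stringsAsFactors = FALSE)
  sample_meta <- data.frame(fid = sprintf("F%05d", seq_len(n)),
                            iid = sprintf("I%05d", seq_len(n)),
                            sex = 0L, phenotype = -9, stringsAsFactors = FALSE)
  genotype_matrix(dos, snp_meta, sample_meta)
}

#' Permute carrier status per SNP
#'
#' Independently permutes each SNP's dosage vector across samples. Allele
#' frequencies are exactly preserved while all cross-SNP correlation (LD) is
#' destroyed, as if genotypes were drawn independently from the observed
#' allele-frequency spectrum.
#'
#' @param geno a \code{\link{genotype_matrix}}.
#' @param seed integer seed.
#' @return a \code{\link{genotype_matrix}} with permuted columns.
#' @export
permute_carriers <- function(geno, seed = 1L) {
  .substream(seed, "permute")
  d <- geno$dosage
  n <- nrow(d)
  for (j in seq_len(ncol(d))) d[, j] <- d[sample.int(n), j]
  geno$dosage <- d
  rownames(geno$dosage) <- geno$sample_meta$iid
  update_snp_stats(geno)
}
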