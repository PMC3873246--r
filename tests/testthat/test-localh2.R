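# Locus definition, shrunk linear-model estimates, local variance components,
# expectations, empirical null, and the liability-invariance of the test.

make_panel <- function(seed = 501, n = 250, m = 4000, spacing = 5000) {
  simulate_genotypes(geno_sim_config(n, m, maf_spectrum = strat_spectrum,
                                     ld_rho = 0.6, bp_spacing = spacing, seed = seed))
}

test_that("define_loci merges windows, honours the MHC exclusion and is idempotent", {
  g <- make_panel()
  meta <- g$snp_meta
  # two index SNPs ~200 kb apart -> one merged interval of window + 200 kb
  i1 <- which.min(abs(meta$pos_bp - 5e6))
  i2 <- which.min(abs(meta$pos_bp - (meta$pos_bp[i1] + 2e5)))
  catalog <- data.frame(snp_id = meta$id[c(i1, i2)])
  ls <- define_loci(catalog, g, window_bp = 1e6, exclude = NULL)
  expect_equal(nrow(ls$intervals), 1L)
  expect_equal(ls$intervals$end_bp - ls$intervals$start_bp,
               1e6 + meta$pos_bp[i2] - meta$pos_bp[i1])
  expect_length(attr(ls, "index_snps"), 1L)            # leading SNP only
  # catalog order invariance
  ls_r <- define_loci(catalog[2:1, , drop = FALSE], g, window_bp = 1e6, exclude = NULL)
  expect_equal(ls$intervals, ls_r$intervals)
  # an index SNP inside an exclusion region loses its locus entirely
  mid <- meta$id[which.min(abs(meta$pos_bp - 8e6))]
  excl <- data.frame(chrom = 1L, start_bp = 7.4e6, end_bp = 8.6e6)
  expect_error(define_loci(data.frame(snp_id = mid), g, window_bp = 1e6,
                           exclude = excl), "exclusion")
  # the canonical MHC region is chr6:26-34 Mb
  expect_equal(mhc_region(),
               data.frame(chrom = 6L, start_bp = 26e6, end_bp = 34e6))
  # unresolvable catalog entries are dropped with a message
  expect_message(define_loci(data.frame(snp_id = c(meta$id[i1], "rs_none")), g,
                             window_bp = 1e6, exclude = NULL), "dropped")
})

test_that("rho_physical increases monotonically with window size", {
  g <- make_panel()
  meta <- g$snp_meta
  catalog <- data.frame(snp_id = meta$id[c(300, 1500, 3000)])
  rhos <- sapply(c(1e5, 5e5, 1e6, 2e6), function(w)
    define_loci(catalog, g, window_bp = w, exclude = NULL)$rho_physical)
  expect_true(all(diff(rhos) > 0))
  expect_true(all(rhos > 0 & rhos < 1))
})

test_that("h2_gwas applies the 1/N-per-SNP shrinkage exactly and floors at zero", {
  g <- make_panel(seed = 502)
  n <- nrow(g$dosage)
  idx <- g$snp_meta$id[c(10, 500, 900, 1800, 2500)]
  set.seed(61)
  Z <- normalize_genotypes(subset_geno(g, snps = idx))
  y <- drop(Z %*% c(0.3, 0.25, 0.2, 0.25, 0.3)) + rnorm(n)
  hg <- h2_gwas(g, y, index_snps = idx)
  f0 <- lm(y ~ 1); f1 <- lm(y ~ Z)
  r2 <- summary(f1)$r.squared
  expect_equal(hg$estimate, max(0, r2 - 5 / n), tolerance = 1e-10)
  expect_equal(hg$n_snps_used, 5L)
  # orthogonal index SNPs: the floor engages
  ynull <- rnorm(n)
  expect_equal(h2_gwas(g, ynull, index_snps = idx[1:2])$estimate >= 0, TRUE)
  set.seed(62)
  many_null <- replicate(20, h2_gwas(g, rnorm(n), index_snps = idx)$estimate)
  expect_lt(mean(many_null), 0.01)
})

test_that("h2_joint adds only conditionally significant SNPs", {
  g <- make_panel(seed = 503, n = 400)
  meta <- g$snp_meta
  n <- 400
  # two independent typed causals far apart; index = one of them
  c1 <- meta$id[200]; c2 <- meta$id[2600]
  Z <- normalize_genotypes(subset_geno(g, snps = c(c1, c2)))
  set.seed(63)
  y <- drop(Z %*% c(0.7, 0.7)) + rnorm(n)
  cat1 <- data.frame(snp_id = c1)
  ls <- define_loci(rbind(cat1, data.frame(snp_id = c2)), g,
                    window_bp = 4e5, exclude = NULL)
  hj <- h2_joint(g, y, index_snps = c1, locus_set = ls)
  expect_true(c2 %in% hj$model_snps)
  hgw <- h2_gwas(g, y, index_snps = c1)
  expect_gt(hj$estimate, hgw$estimate)
  # saturated index: no additions, h2_joint == h2_gwas
  hj2 <- h2_joint(g, y, index_snps = c(c1, c2), locus_set = ls)
  expect_equal(hj2$n_added, 0L)
  expect_equal(hj2$estimate, h2_gwas(g, y, index_snps = c(c1, c2))$estimate,
               tolerance = 1e-12)
  # pure-noise phenotype: the Bonferroni screen blocks every candidate
  set.seed(65)
  ynoise <- rnorm(n)
  hj3 <- h2_joint(g, ynoise, index_snps = c1, locus_set = ls)
  expect_equal(hj3$n_added, 0L)
  expect_equal(hj3$estimate, h2_gwas(g, ynoise, index_snps = c1)$estimate,
               tolerance = 1e-12)
})

test_that("h2_local over a whole-genome locus set equals the global fit", {
  g <- make_panel(seed = 504, n = 200, m = 1500)
  tr <- simulate_trait_genomewide(g, trait_sim_config(n_causal = 300, frac_lowfreq = 0.5,
                                                      target_h2 = 0.4, seed = 70))
  span <- range(g$snp_meta$pos_bp)
  whole <- locus_set(data.frame(chrom = 1L, start_bp = span[1], end_bp = span[2] + 1), g)
  f_local <- h2_local(g, tr$y, locus_set = whole, adjustment = "standard")
  f_global <- greml(tr$y, standard_grm(g))
  expect_equal(f_local$h2[["total"]], f_global$h2[["total"]], tolerance = 1e-6)
})

test_that("local_expectation reduces correctly at its extremes and under no enrichment", {
  expect_equal(local_expectation(0.6, 0.1, 1), 0.6)    # rho = 1 -> global
  expect_equal(local_expectation(0.6, 0, 0.011), 0.011 * 0.6)
  expect_equal(local_expectation(0.6, 0.1, 0.2), 0.1 + 0.5 * 0.2)
  expect_equal(local_expectation(0.6, 0.1, 0.2, composition = "rho_only"), 0.12)
  # genic split at the no-enrichment fixed point changes nothing
  genic <- list(rho_genic = 0.2 * 0.5, rho_nongenic = 0.2 * 0.5,
                h2_genic = 0.36, h2_nongenic = 0.24, genic_frac = 0.5)
  expect_equal(local_expectation(0.6, 0.1, 0.2, genic = genic),
               local_expectation(0.6, 0.1, 0.2), tolerance = 1e-12)
  # genic-enriched loci raise the expectation when genic h2 density is higher
  genic2 <- list(rho_genic = 0.2 * 0.8, rho_nongenic = 0.2 * 0.2,
                 h2_genic = 0.45, h2_nongenic = 0.15, genic_frac = 0.5)
  expect_gt(local_expectation(0.6, 0.1, 0.2, genic = genic2),
            local_expectation(0.6, 0.1, 0.2))
  expect_error(local_expectation(0.6, 0.1, locus_set(
    data.frame(chrom = 1L, start_bp = 1, end_bp = 10),
    toy_geno(matrix(c(0L, 1L, 2L), 3, 1))), metric = "ldvar"), "not available")
})

test_that("genic_snps flags markers within the flank of exons", {
  g <- toy_geno(matrix(rbinom(30, 2, 0.4), 3, 10), pos = (1:10) * 50000L)
  exons <- data.frame(chrom = 1L, start_bp = 120000, end_bp = 130000)
  flags <- genic_snps(g, exons, flank_bp = 10000)
  expect_equal(which(flags), which((1:10) * 50000 >= 110000 & (1:10) * 50000 < 140000))
  # BED input is 0-based half-open
  bed <- tempfile()
  writeLines("chr1\t119999\t130000", bed)
  expect_equal(genic_snps(g, bed, flank_bp = 10000), flags)
})

test_that("gain, z and p are invariant under the liability transformation", {
  h2 <- 0.08; se <- 0.02; expd <- 0.05
  zt_obs <- ztest_increase(h2, se, expd)
  lt <- liability_transform(h2, se, K = 0.02, P = 0.4)
  fac <- lt$factor
  zt_liab <- ztest_increase(lt$h2_liab, lt$se_liab, expd * fac)
  expect_equal(zt_liab$gain, zt_obs$gain, tolerance = 1e-12)
  expect_equal(zt_liab$z, zt_obs$z, tolerance = 1e-12)
  expect_equal(zt_liab$p, zt_obs$p, tolerance = 1e-12)
})

test_that("empirical_null is near 0.5 on a null trait and respects exclusions", {
  g <- make_panel(seed = 505, n = 150, m = 1500, spacing = 10000)
  # a genuinely polygenic trait whose loci hold nothing special: draw
  # excesses then scatter around zero and the empirical p sits mid-range
  tr <- simulate_trait_genomewide(g, trait_sim_config(n_causal = 750,
                                                      frac_lowfreq = 0.5,
                                                      target_h2 = 0.4, seed = 71))
  y <- tr$y
  h2g <- greml(y, standard_grm(g))$h2[["total"]]
  en <- suppressWarnings(
    empirical_null(g, y, n_loci = 3, locus_span_bp = 1e6, n_draws = 60,
                   observed_excess = 0, h2_global = h2g,
                   adjustment = "standard", seed = 72))
  expect_gt(en$p_empirical, 0.15)
  expect_lt(en$p_empirical, 0.85)
  # an excess beyond every draw hits the resolution floor
  en2 <- suppressWarnings(
    empirical_null(g, y, n_loci = 3, locus_span_bp = 1e6, n_draws = 60,
                   observed_excess = 1, h2_global = h2g,
                   adjustment = "standard", seed = 73))
  expect_equal(en2$p_empirical, 1 / 61)
  # exclusion regions are never overlapped by the draws
  excl <- data.frame(chrom = 1L, start_bp = 0, end_bp = 6e6)
  en3 <- suppressWarnings(
    empirical_null(g, y, n_loci = 2, locus_span_bp = 5e5, n_draws = 20,
                   observed_excess = 0, h2_global = h2g, exclusions = excl,
                   adjustment = "standard", seed = 74))
  expect_true(is.finite(en3$p_empirical))
  expect_warning(empirical_null(g, y, n_loci = 2, locus_span_bp = 5e5, n_draws = 10,
                                observed_excess = 0, h2_global = h2g,
                                adjustment = "standard", seed = 75),
                 "resolution")
})

test_that("the end-to-end local analysis detects planted locus heritability", {
  g <- make_panel(seed = 506, n = 400, m = 4000, spacing = 10000)
  tr <- simulate_trait_local(g, trait_sim_config(n_causal = 3, maf_class = "common",
                                                 target_h2 = 0.25, n_loci = 6, seed = 76))
  # index SNP per locus: the best typed tag
  ig <- ideal_gwas(g, tr)
  catalog <- data.frame(snp_id = ig$per_locus$snp_id)
  res <- analyze_local(g, tr$y, covars = NULL, catalog = catalog,
                       h2_global = greml(tr$y, standard_grm(g)),
                       window_bp = 1e6, exclude = NULL, adjustment = "standard")
  expect_s3_class(res, "local_result")
  expect_gt(res$h2_local$h2[["total"]], res$expected)
  expect_lt(res$p_analytic, 0.1)
  expect_output(print(res), "h2_local")
})
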