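# Simulators: genotype panel, carrier permutation, trait architectures,
# idealized GWAS SNP, liability-threshold ascertainment.

test_that("genotype simulation is seed-deterministic and spans both MAF classes", {
  cfg <- geno_sim_config(60, 500, maf_spectrum = strat_spectrum, ld_rho = 0.5, seed = 77)
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g1$dosage, g2$dosage)
  expect_identical(g1$snp_meta, g2$snp_meta)
  expect_gt(sum(g1$snp_meta$maf < 0.05), 50)
  expect_gt(sum(g1$snp_meta$maf > 0.10), 50)
  expect_true(all(diff(g1$snp_meta$pos_bp) > 0))
})

test_that("ld_rho controls adjacent LD and its decay with distance", {
  set.seed(121)
  g0 <- simulate_genotypes(geno_sim_config(400, 600, ld_rho = 0, seed = 80))
  Z0 <- normalize_genotypes(g0)
  r2_adj0 <- mean(sapply(2:600, function(j) cor(Z0[, j], Z0[, j - 1])^2))
  expect_equal(r2_adj0, 1 / 400, tolerance = 0.5)      # ~1/n under independence
  g9 <- simulate_genotypes(geno_sim_config(400, 600, ld_rho = 0.9, seed = 81))
  Z9 <- normalize_genotypes(g9)
  r2_adj9 <- mean(sapply(2:600, function(j) cor(Z9[, j], Z9[, j - 1])^2))
  r2_lag10 <- mean(sapply(11:600, function(j) cor(Z9[, j], Z9[, j - 10])^2))
  expect_gt(r2_adj9, 3 * r2_lag10)                     # decay
  expect_gt(r2_adj9, 0.2)
})

test_that("carrier permutation preserves per-SNP counts and destroys LD", {
  g <- simulate_genotypes(geno_sim_config(300, 400, ld_rho = 0.9, seed = 82))
  gp <- permute_carriers(g, seed = 9)
  cnt <- function(d) apply(d, 2, function(x) tabulate(x + 1L, 3L))
  expect_identical(cnt(gp$dosage), cnt(g$dosage))
  expect_identical(gp$snp_meta$maf, g$snp_meta$maf)
  Zp <- normalize_genotypes(gp)
  r2 <- sapply(2:400, function(j) cor(Zp[, j], Zp[, j - 1])^2)
  expect_lt(mean(r2), 3 / 300)                         # O(1/n)
  # a second permutation still conserves the frequency spectrum
  gpp <- permute_carriers(gp, seed = 10)
  expect_identical(cnt(gpp$dosage), cnt(g$dosage))
})

test_that("genome-wide trait honours the low-frequency fraction and hits h2 exactly", {
  g <- simulate_genotypes(geno_sim_config(250, 2000, maf_spectrum = strat_spectrum,
                                          seed = 83))
  maf <- setNames(g$snp_meta$maf, g$snp_meta$id)
  tr0 <- simulate_trait_genomewide(g, trait_sim_config(n_causal = 400, frac_lowfreq = 0,
                                                       target_h2 = 0.8, seed = 84))
  expect_true(all(maf[tr0$causal_ids] >= 0.05))
  tr1 <- simulate_trait_genomewide(g, trait_sim_config(n_causal = 400, frac_lowfreq = 1,
                                                       target_h2 = 0.8, seed = 85))
  expect_true(all(maf[tr1$causal_ids] < 0.05))
  trh <- simulate_trait_genomewide(g, trait_sim_config(n_causal = 400, frac_lowfreq = 0.5,
                                                       target_h2 = 0.8, seed = 86))
  expect_equal(sum(maf[trh$causal_ids] < 0.05), 200)
  expect_equal(trh$realized_h2, 0.8, tolerance = 1e-12)
  expect_equal(var(trh$g) / var(trh$y), 0.8, tolerance = 1e-12)
})

test_that("equal-variance effects contribute equal per-causal variance", {
  g <- simulate_genotypes(geno_sim_config(300, 500, maf_spectrum = strat_spectrum,
                                          seed = 87))
  tr <- simulate_trait_genomewide(g, trait_sim_config(n_causal = 100, frac_lowfreq = 0.5,
                                                      effect_model = "equal_variance",
                                                      target_h2 = 0.5, seed = 88))
  d <- g$dosage[, tr$causal_ids]
  contrib <- sapply(seq_along(tr$causal_ids), function(j)
    tr$beta_allelic[j]^2 * var(as.numeric(d[, j])))
  expect_lt(max(abs(contrib - 1)), 1e-10)              # beta^2 * Var(x) = 1 exactly
  # allelic_normal draws instead scale with 2p(1-p)
  tra <- simulate_trait_genomewide(g, trait_sim_config(n_causal = 100, frac_lowfreq = 0.5,
                                                       effect_model = "allelic_normal",
                                                       target_h2 = 0.5, seed = 89))
  expect_gt(sd(abs(tra$beta_allelic)), 0)
})

test_that("local trait places disjoint loci with the requested causal count and class", {
  g <- simulate_genotypes(geno_sim_config(200, 6000, maf_spectrum = strat_spectrum,
                                          bp_spacing = 5000, seed = 90))
  cfg <- trait_sim_config(n_causal = 3, maf_class = "common", target_h2 = 0.1,
                          n_loci = 12, seed = 91)
  tr <- simulate_trait_local(g, cfg)
  ints <- tr$loci$intervals
  expect_equal(nrow(ints), 12L)
  o <- order(ints$start_bp)
  expect_true(all(ints$start_bp[o][-1] >= ints$end_bp[o][-12]))   # disjoint
  expect_equal(tr$realized_h2, 0.1, tolerance = 1e-12)
  maf <- setNames(g$snp_meta$maf, g$snp_meta$id)
  expect_true(all(maf[tr$causal_ids] > 0.10))
  lt <- tr$locus_table
  expect_true(all(lt$n_causal == 3))
  pos <- setNames(g$snp_meta$pos_bp, g$snp_meta$id)
  for (l in seq_len(nrow(lt)))
    expect_true(all(pos[lt$causal_ids[[l]]] >= lt$start_bp[l] &
                      pos[lt$causal_ids[[l]]] < lt$end_bp[l]))
  # single causal per locus: exactly one causal inside each span
  tr1 <- simulate_trait_local(g, trait_sim_config(n_causal = 1, maf_class = "common",
                                                  target_h2 = 0.1, n_loci = 12, seed = 92))
  expect_true(all(tr1$locus_table$n_causal == 1))
  # infeasible placement on a tiny panel errors with the achievable maximum
  gsmall <- subset_geno(g, snps = 1:200)
  expect_error(simulate_trait_local(gsmall,
                                    trait_sim_config(n_causal = 1, maf_class = "common",
                                                     target_h2 = 0.1, n_loci = 50, seed = 93)),
               "could only place")
})

test_that("the idealized GWAS SNP is the causal itself when typed and handles proxies", {
  set.seed(131)
  # two-SNP analytic case: hidden causal, proxy correlated haplotype-wise
  z1 <- rnorm(500); z2 <- rnorm(500)
  w1 <- 0.8 * z1 + 0.6 * rnorm(500); w2 <- 0.8 * z2 + 0.6 * rnorm(500)
  xc <- as.integer(z1 > 0) + as.integer(z2 > 0)
  xt <- as.integer(w1 > 0) + as.integer(w2 > 0)
  g <- toy_geno(cbind(xc, xt, rbinom(500, 2, 0.5)))
  beta <- c(s1 = 1.3)
  best_typed <- ideal_gwas_snp(g, beta, c("s1", "s2", "s3"))
  expect_equal(best_typed$snp_id, "s1")
  expect_equal(best_typed$marginal_effect, 1.3, tolerance = 1e-9)
  best_hidden <- ideal_gwas_snp(g, beta, c("s2", "s3"))
  expect_equal(best_hidden$snp_id, "s2")
  Z <- normalize_genotypes(g)
  r <- cor(Z[, 1], Z[, 2])
  expect_equal(best_hidden$captured_variance, (1.3 * r)^2, tolerance = 1e-6)
  # antagonistic tagging: opposite effects on two causals cancel in the tag
  g2 <- toy_geno(cbind(xc, xc, xt))
  beta2 <- c(s1 = 1, s2 = -1)
  m <- ideal_gwas_snp(g2, beta2, "s3")
  expect_lt(abs(m$marginal_effect), 1e-9)
  expect_error(ideal_gwas_snp(g, beta, character(0)), "empty")
})

test_that("per-locus capture is exactly 100% with one typed causal per locus", {
  g <- simulate_genotypes(geno_sim_config(150, 4000, maf_spectrum = strat_spectrum,
                                          ld_rho = 0.8, bp_spacing = 5000, seed = 94))
  tr <- simulate_trait_local(g, trait_sim_config(n_causal = 1, maf_class = "low",
                                                 target_h2 = 0.1, n_loci = 8, seed = 95))
  ig <- ideal_gwas(g, tr)
  expect_equal(ig$capture_fraction, 1, tolerance = 1e-10)
  expect_equal(ig$per_locus$snp_id, unlist(tr$locus_table$causal_ids))
  # hiding the causals strictly reduces the captured variance
  igh <- ideal_gwas(g, tr, hide_causals = TRUE)
  expect_lt(igh$capture_fraction, 1)
})

test_that("liability-threshold ascertainment respects K and P", {
  set.seed(133)
  n <- 20000
  gvals <- rnorm(n, 0, sqrt(0.3))
  asc <- ascertain_case_control(gvals, noise_var = 0.7, K = 0.1, P = 0.5,
                                n_target = 2000, seed = 7)
  expect_equal(mean(asc$status), 0.1, tolerance = 1e-3)
  st <- asc$status[asc$sampled_ids]
  expect_equal(mean(st), 0.5, tolerance = 1e-6)
  expect_equal(length(asc$sampled_ids), 2000L)
  # K = P = 0.5: threshold at the liability median
  asc2 <- ascertain_case_control(gvals, 0.7, 0.5, 0.5, 1000, seed = 8)
  expect_equal(asc2$threshold, 0, tolerance = 0.05)
  # cases are genetically enriched under a heritable liability
  expect_gt(mean(gvals[asc$status == 1]), mean(gvals[asc$status == 0]))
})
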