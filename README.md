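# h2local

Variance-component estimation of SNP-heritability, focused on one
question: **how much heritability is concentrated at known GWAS loci
beyond what their lead SNPs explain?** The audience is statistical
geneticists analysing genotyped case-control or quantitative-trait
cohorts (PLINK-format genotypes, GCTA-format relatedness matrices).

A genome-wide association study reports a handful of index SNPs per
trait; the variance they explain jointly (`h2_gwas`, shrunk by 1/N per
fitted SNP) is typically far below the trait's SNP-heritability. This
package estimates the *local* heritability of the loci themselves —
a variance-component fit on a relatedness matrix built only from the
SNPs inside 1 Mbp windows around the index SNPs — and tests whether it
exceeds both `h2_gwas` and the share a random stretch of genome of the
same size would contribute.

## The model

For phenotype `y`, fixed effects `X` and a genetic relatedness matrix
(GRM) `A` built from `m` normalized SNPs:

    y = Xb + g + e,   g ~ N(0, σ²_g A),   e ~ N(0, σ²_e I)
    h²_g = σ²_g / (σ²_g + σ²_e)

fitted by average-information REML (`greml()`), with analytical standard
errors from the inverse AI matrix. Because LD makes some SNPs
over-represented in `A = ZZᵀ/m`, the package implements three
LD adjustments — pruning, the LD-residual regression transform, and
neighbour-count shrinkage — of which the LD-residual is the workhorse:
each marker is replaced by the residual of its regression on the
preceding 100 kbp of markers, and the GRM is renormalized by the summed
residual variances. Local heritability uses the same machinery with the
adjustment applied per locus (`local_grm`), and the observed excess over
the no-enrichment expectation

    E[h²_loc] = h²_gwas + (h²_g − h²_gwas)·ρ

(ρ = the loci's genome fraction: physical, SNP-count, or LD-residual
variance share) is tested by one-sided z-test and, optionally, against
an empirical null of randomly drawn locus sets. A full synthetic-data
module (LD-structured genotype panels, genome-wide and 180-locus trait
architectures, idealized best-tag GWAS SNPs, liability-threshold
ascertainment) reproduces the designs the estimators are calibrated on.

## Worked example

Simulate an LD-structured panel, plant a 6-locus architecture explaining
25% of trait variance, and ask how much of it the lead SNPs versus the
local variance component recover:

```r
library(h2local)
set.seed(1)
spec <- function(m) {                       # half low-frequency, half common
  k <- m / 2
  sample(c(runif(k, 0.011, 0.049), runif(m - k, 0.101, 0.5)))
}
geno <- simulate_genotypes(geno_sim_config(
  n_samples = 800, n_snps = 6000, maf_spectrum = spec,
  ld_rho = 0.9, bp_spacing = 5000, seed = 1))

truth <- simulate_trait_local(geno, trait_sim_config(
  n_causal = 3, maf_class = "common", target_h2 = 0.25,
  n_loci = 6, seed = 2))

fit_global <- greml(truth$y, build_grm(geno, "ld_residual"))

tags <- ideal_gwas(geno, truth)$per_locus$snp_id   # best typed tag per locus
res <- analyze_local(geno, truth$y, catalog = data.frame(snp_id = tags),
                     h2_global = fit_global, exclude = NULL,
                     adjustment = "ld_residual")
res
#> Local heritability at GWAS loci
#>   h2_gwas  = 0.1186
#>   h2_joint = 0.1365
#>   h2_local = 0.2563 (SE 0.0669)
#>   expected = 0.1903; gain = 1.35; z = 0.99; p = 0.162
```

Reading the output: the six lead tags jointly explain 11.9% of variance
(after the 1/N-per-SNP shrinkage); stepwise conditional selection adds a
little (13.7%); the local variance component recovers 25.6% ± 6.7% —
essentially the full planted 25% — illustrating the core result that
multi-causal loci hold substantially more heritability than their lead
SNPs capture. Here the one-sided test against the chance expectation
(19.0%, inflated by the noisy global estimate at this small n) is not
yet significant; power grows quickly with cohort size.

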