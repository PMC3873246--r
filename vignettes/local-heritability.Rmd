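---
title: "Estimating local SNP-heritability with LD-adjusted relatedness matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating local SNP-heritability with LD-adjusted relatedness matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(h2local)
```

## The model

`h2local` estimates the fraction of phenotypic variance tagged by genotyped
SNPs — globally, and within specified genomic loci. The generative model is
the standard additive polygenic model

$$ y = X b + g + e, \qquad g \sim N(0,\, \sigma^2_g A), \qquad
   e \sim N(0,\, \sigma^2_e I), $$

where $A$ is a genetic relatedness matrix (GRM) computed from normalized
genotypes and $X$ holds fixed effects (an affine term and, typically, top
principal components). The SNP-heritability is
$h^2_g = \sigma^2_g / (\sigma^2_g + \sigma^2_e)$. *Local* heritability is
the same quantity with $A$ built only from SNPs inside a locus set — for
example 1 Mbp windows around published GWAS hits. The scientific question
the package is organized around: does the heritability inside known loci
exceed (a) what their lead SNPs explain and (b) what a random stretch of
genome of the same size would explain?

## GRM constructions and non-uniform LD

The standard GRM is $A = Z Z^{\top} / m$ over $m$ mean-imputed, centered,
unit-variance SNP columns. Under linkage disequilibrium (LD) this
construction over-represents SNPs with many close proxies: when causal
variants are drawn preferentially from a frequency class whose LD differs
from the panel average, $\hat h^2_g$ is biased — downward when causals are
low-frequency (weakly tagged), upward when they are common. Three
adjustments are provided:

* **LD pruning** (`ld_prune`): greedy removal, within a sliding window
  (50 SNPs, step 5), of the marker with the most pairs above
  $r^2 = 0.3$ until none remains. Simple, but discards non-redundant
  signal.
* **LD residual** (`ld_residual`): each normalized marker is replaced by
  the least-squares residual of its regression on the retained markers in
  the preceding 100 kbp (500 kbp is appropriate for imputed-density data).
  One of any predictor pair with $r^2 \ge 0.95$ is dropped (leftmost kept)
  so the normal equations are well posed; the cap value is a package choice
  — it only needs to be close enough to 1 to keep the window system
  invertible, and it is exposed as a parameter. Residuals no longer have
  unit variance, so the GRM is normalized by the summed empirical residual
  variances rather than by $m$; those per-SNP variances also define the
  "effective SNP" share of a locus (`effective_snp_fraction`). Processing
  is left-to-right; a `reverse` flag reruns it right-to-left to verify
  order robustness.
* **LD shrink** (`ld_shrink_weights`): each marker is down-weighted by its
  count of high-LD neighbours among the 150 nearest markers,
  $w_j = 1/(1 + \#\{r^2_{jk} > 0.2\})$, and the GRM is normalized by
  $\sum_j w_j$. The functional form is a reconstruction from its stated
  behaviour — a perfect proxy pair shares unit weight — with the published
  neighbourhood size and threshold.

For local analysis (`local_grm`) every locus is adjusted independently —
regression windows never cross locus boundaries — and the adjusted blocks
are combined into a single GRM normalized by the total post-adjustment
variance.

## AI-REML

`greml()` maximizes the restricted likelihood of
$V = \sum_c \sigma^2_c A_c + \sigma^2_e I$ by average-information (AI)
quasi-Newton steps. Design choices:

* **Starting values** split $\mathrm{Var}(y)$ equally across components.
* **Step control**: the first iteration is a single EM-REML step; from then
  on AI steps are used, with an EM fallback whenever an AI proposal leaves
  the feasible region. If AI proposals for a component stay infeasible for
  three consecutive iterations the component is pinned to the lower bound
  $10^{-6}\,\mathrm{Var}(y)$ and a reduced AI step is taken on the free
  components — without this, boundary optima (true $\sigma^2_g \approx 0$)
  converge only at the EM rate.
* **Convergence** requires both $|\Delta \log L| < 10^{-4}$ and a maximum
  relative parameter change below $10^{-6}$, and is only declared off an AI
  step (EM progress can be slow enough to fake convergence far from the
  optimum) unless a bound is active; at most 100 iterations.
* **Standard errors** come from the inverse of the final AI matrix; the
  delta method (using the full component covariance) converts them to
  standard errors on each $h^2_c$ and on the total.
* **Single-GRM fits** use a spectral path: the GRM is projected onto the
  orthocomplement of the fixed effects and eigendecomposed once, making
  every subsequent iteration $O(n)$. The dense path handles any number of
  components; both evaluate the identical restricted likelihood (including
  the $\log|X^\top X|$ term) and are cross-checked against each other and
  against a brute-force likelihood grid in the test suite.
* Candidate SNPs are never entered as fixed effects: conditioning the
  random effect on highly correlated fixed-effect SNPs under-estimates the
  local component, which is why the locus GRM route is used instead.

For ascertained case-control traits, `liability_transform` maps an
observed-scale estimate to the liability scale,
$h^2_{liab} = h^2_{obs}\, K^2 (1-K)^2 / (z^2 P(1-P))$ with
$z = \phi(\Phi^{-1}(1-K))$, $K$ the population prevalence and $P$ the
sample case fraction. The map is linear, so all gains, z-scores and
p-values are unchanged by it — a property the tests assert.

## The local test

For a locus set with genome share $\rho$ (three metrics: physical bp,
SNP count, or LD-residual variance share), the expected local heritability
under no enrichment is composed additively:

$$ E[h^2_{loc}] = h^2_{gwas} + (h^2_g - h^2_{gwas})\,\rho . $$

The composition is a package choice: the two stated boundary behaviours —
a pure $h^2_g\rho$ chance expectation when no index SNPs are claimed
($h^2_{gwas}=0$, the cross-trait case), and $E[h^2_{loc}] = h^2_g$ at
$\rho = 1$ — pin it down only up to how the known-association part enters,
and the additive form is the simplest that honours both. A `rho_only`
composition is available for the cross-trait analysis. `h2_gwas` is the
joint linear-model $R^2$ of the index SNPs beyond covariates, shrunk by
$1/N$ per fitted SNP and floored at zero; `h2_joint` extends it by stepwise
conditional selection (univariate Bonferroni screen at $0.05/m$ over the
$m$ locus SNPs, conditional entry at the same threshold, index SNPs always
kept).

Significance of an observed excess uses a one-sided z-test on the
analytical standard error; noise on the expectation is deliberately not
modelled, because the local and global estimates are computed from the
same samples and partially nested SNP sets. `empirical_null` relaxes the
normality and genome-uniformity assumptions by drawing random locus sets
of matched geometry (1,000 draws in the full design; conservatively
scoring each draw's $h^2_{gwas}$ as 0) and reports
$p = (r + 1)/(R + 1)$ — the add-one convention avoids an exact zero that a
raw exceedance count would produce. The genic variant of the expectation
splits $\rho$ into genic (within 10 kbp of an exon) and non-genic parts
and weights each by the per-class density of a two-component genome-wide
fit; its algebra is a reconstruction from the stated ingredients, with the
no-enrichment fixed point (loci with genome-typical genic content leave
the expectation unchanged) asserted in the tests.

## Quality control

`filter_snps` applies, in order: minor-allele frequency $\ge 0.01$,
missingness $\le 0.002$, Hardy–Weinberg exact-test $p \ge 0.01$, and (for
case-control panels) differential-missingness $p \ge 0.05$. Choices the
protocol leaves open: HWE is tested in controls only when status is
available (cases can deviate through real association); the exact test is
used rather than chi-square for small-count robustness; differential
missingness uses Fisher's exact test when any expected cell is below 5 and
chi-square otherwise. Sample-level QC: `prune_related` removes the
max-degree member of every pair with GRM covariance above 0.05 (the cutoff
is a package default, exposed as a parameter); `pca_outlier_loop` runs up
to five rounds of removing samples more than 6 SD from the mean on any of
the top 20 eigenvectors, recomputing eigenvectors each round; `pc_match`
performs greedy case-control pair matching in a phenotype-weighted
eigenvector metric, visiting controls in input order with ties broken by
case input order.

## The simulators, and what they do (not) emulate

Controlled-access cohort genotypes cannot be redistributed, so
`simulate_genotypes` provides the substrate: haplotypes are latent Gaussian
AR(1) chains along each chromosome, thresholded per site so the minor
allele appears at its drawn frequency; two haplotypes sum to a dosage.
This gives closed-form control of LD decay (`ld_rho`), a tunable MAF
spectrum, and reproducibility from a single seed with named substreams
(genotypes / causals / effects / noise), so any stage can be re-rolled
independently. `ld_rho` may be a function of MAF: giving low-frequency
sites weaker chain coupling emulates the shorter LD of younger alleles,
which is the mechanism behind the deflation of standard-GRM estimates when
causals are rare.

Known limitations, which bound what passing tests say about real data:

* Thresholded-Gaussian rare variants have intrinsically capped *linear*
  predictability from their neighbours (the correlation between a rare
  indicator and its latent field is at most
  $\phi(t)/\sqrt{p(1-p)}$), whereas genotyping arrays select rare SNPs
  that are often near-perfectly tagged. Consequently the LD-residual
  estimate's closeness to truth under all-rare-causal architectures
  depends on the panel's class composition; the bias-direction tests use a
  half-rare panel where the transform is calibrated, and the deflation of
  the *standard* GRM is robust across all panels explored.
* No coalescent history, mutation/recombination process, genotyping error,
  or population structure is modelled (structure enters only through the
  QC and matching functions, which are exercised on constructed outliers).

Trait simulators follow the two architectures the analysis is designed
around: a genome-wide polygenic trait (5,000 causals, a fraction $F$ from
the low-frequency class MAF $< 0.05$, induced $h^2 = 0.8$) and a local
architecture (180 disjoint 1 Mbp loci centered on 1–10 causal variants
drawn from the low-frequency or common (MAF $> 0.10$) class, total
$h^2 = 0.1$ — the locus count and heritability scale reported for adult
height). SNPs with MAF in $[0.05, 0.10]$ are never drawn as causal in
class-restricted designs, keeping the classes unambiguous. The
`equal_variance` effect model uses a fixed-magnitude effect on the
normalized scale with random sign (allelic variance $1/2p(1-p)$), so
per-causal variance contributions are exactly equal; noise is
orthogonalized against the genetic values and rescaled so the realized
$\mathrm{Var}(g)/\mathrm{Var}(y)$ equals the target exactly — recovery
targets are then sharp rather than drifting with the effect draw. Loci are
placed by rejection sampling with the causal cluster at the window
midpoint plus a uniform jitter of 10% of the span.

`ideal_gwas_snp` computes the noise-free marginal effect
$\sum_c \beta_c\, r(t, c)$ of every candidate tag over a locus's causal
set and returns the tag maximizing its square — the best a single-SNP GWAS
could do with no sampling noise. With one typed causal per locus the best
tag is the causal itself and the captured fraction is exactly 100%, which
anchors the simulation calibration. `permute_carriers` destroys LD while
exactly preserving each SNP's genotype counts, isolating allele-frequency
effects from LD effects.

## Problem sizes

The test suite and the acceptance script use desk-scale versions of the
study designs: REML unbiasedness is checked at $n = 2000$, $m = 10{,}000$,
5,000 causals over 10 replicates per MAF mix; the local calibration and
idealized-tag targets use the full 180-locus geometry on sparse 300–400
sample panels; property checks (bias direction, gain monotonicity, SE
calibration, p-value concordance) use panels of 150–1,200 samples and
2,000–15,000 SNPs with 5–30 replicates. These sizes were chosen so each
check is stable under its stated tolerance; the underlying routines are
$O(n^3 + n^2 m)$ per fit and scale to cohort sizes via the spectral path.

## Degenerate inputs and tie-breaks

Monomorphic SNPs are excluded from every GRM with a warning; zero-variance
columns normalize to zero. Perfectly collinear residuals get variance
exactly 0 and drop out of the normalization. Greedy procedures break ties
by input order (pruning: leftmost position; relatedness: first sample;
matching: first case). Identical GRM components, or a GRM equal to the
identity, abort the fit as non-identifiable rather than returning an
arbitrary split. Empty loci are dropped with a warning and recorded;
an empty locus *set* is an error.
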