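# Shared fixture builders. Panels are generated in code at test time; no
# files are stored.

# stratified MAF spectrum: half low-frequency (MAF < 0.05), half common
# (MAF > 0.10), so class-restricted causal designs are feasible at any F
strat_spectrum <- function(m) {
  k <- ceiling(m / 2)
  sample(c(stats::runif(k, 0.011, 0.049), stats::runif(m - k, 0.101, 0.5)))
}

# frequency-dependent LD: low-frequency (young) alleles carry less LD
freq_ld <- function(rho_rare, rho_common) {
  function(maf) ifelse(maf < 0.05, rho_rare, rho_common)
}

# small hand-built genotype matrix from an explicit dosage matrix
toy_geno <- function(dosage, chrom = NULL, pos = NULL) {
  dosage <- as.matrix(dosage)
  m <- ncol(dosage)
  if (is.null(chrom)) chrom <- rep(1L, m)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  genotype_matrix(dosage,
                  data.frame(chrom = chrom, id = paste0("s", seq_len(m)),
                             pos_bp = pos, allele1 = "A", allele2 = "B",
                             stringsAsFactors = FALSE))
}

# independent REML log-likelihood oracle, straight from the definition:
# -0.5 [ (n-p) log 2pi + log|V| + log|X'V^-1 X| - log|X'X| + y'Py ]
reml_loglik_oracle <- function(y, X, A, sg, se) {
  n <- length(y)
  V <- sg * A + diag(se, n)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtViX) %*% t(X) %*% Vi
  -0.5 * ((n - ncol(X)) * log(2 * pi) +
            as.numeric(determinant(V, logarithm = TRUE)$modulus) +
            as.numeric(determinant(XtViX, logarithm = TRUE)$modulus) -
            as.numeric(determinant(t(X) %*% X, logarithm = TRUE)$modulus) +
            drop(t(y) %*% P %*% y))
}

# exact HWE probability of a genotype table by direct factorial enumeration
hwe_enum_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  na <- 2 * n_aa + n_Aa                      # count of the 'a' allele
  nA <- 2 * n - na
  prob <- function(het) {
    hom_a <- (na - het) / 2
    hom_A <- n - het - hom_a
    exp(lfactorial(n) - lfactorial(het) - lfactorial(hom_a) - lfactorial(hom_A) +
          het * log(2) + lfactorial(na) + lfactorial(nA) - lfactorial(2 * n))
  }
  hets <- seq(min(na, nA) %% 2, min(na, nA), by = 2)
  pr <- vapply(hets, prob, numeric(1))
  obs <- prob(n_Aa)
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]) / sum(pr))
}
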