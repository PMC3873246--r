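Package: h2local
Title: SNP-Heritability at Known GWAS Loci with LD-Adjusted Relatedness Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Variance-component estimation of SNP-heritability with a focus on
    quantifying the heritability concentrated at known GWAS loci. Implements
    genetic relatedness matrices (GRMs) adjusted for non-uniform linkage
    disequilibrium (LD-pruning, the LD-residual regression transform, and
    neighbour-count LD shrinkage), multi-component average-information REML
    with analytical standard errors, liability-scale transformation for
    ascertained case-control traits, locus definition and local-vs-expected
    heritability tests with analytic and empirical significance, stepwise
    joint/conditional GWAS models, a quality-control pipeline for genotype
    panels, and a reproducible simulator of LD-structured genotypes and
    polygenic trait architectures. Reads and writes PLINK BED/BIM/FAM,
    PLINK text phenotype/covariate tables, and GCTA binary GRM files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, tools, jsonlite, optparse, yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
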