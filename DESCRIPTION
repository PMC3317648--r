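Package: vcqtl
Title: Variance-Components Linkage and Measured-Genotype Accounting for
    Quantitative Trait Loci in Pedigrees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Variance-components linkage analysis and measured-genotype
    association for quantitative traits in family data, with the combined
    linkage-association machinery needed to decide whether a set of SNPs
    fully accounts for a linkage peak.  Provides recursive kinship
    computation from pedigrees, maximum-likelihood fitting of the
    multivariate-normal model with locus-specific (IBD), polygenic and
    environmental variance components, single-SNP measured-genotype scans,
    LD pruning of SNP panels, conditional LOD-drop accounting per SNP and
    per gene, and a permutation-based empirical p-value for abolished
    linkage (adjusted LOD below 0.5).  A synthetic-cohort module generates
    pedigrees, LD-structured genotypes across a multi-gene region, true
    locus IBD matrices and a multi-variant small-effect trait so the whole
    pipeline runs end to end without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
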