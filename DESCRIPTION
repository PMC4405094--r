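Package: wildarch
Title: Genome Partitioning of Quantitative Trait Variation in Pedigreed
    Wild Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for dissecting the genetic architecture of quantitative
    traits in SNP-typed pedigreed populations. Implements average-information
    REML for linear mixed ("animal") models with genomic-relatedness and
    group-structured random effects; partitioning of additive genetic
    variance between chromosomes and sliding SNP windows (regional
    heritability mapping) with likelihood-ratio tests; a two-stage
    residual-based association scan (GRAMMAR) with genomic-inflation
    diagnostics and mixed-model effect refitting; genotype-level selection
    coefficients with gene-drop drift nulls for allele-frequency trends;
    and haplotype-sharing statistics that trace trait alleles to an
    admixture source. A forward pedigree simulator generates populations
    with the linkage-disequilibrium and relatedness structure the analyses
    assume. Readers and writers for PLINK bed/bim/fam, phased VCF and GCTA
    binary GRM formats are included.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), lme4, jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
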