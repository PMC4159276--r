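Package: imprecover
Title: Evaluating Recovery of Exome-Array Content by Genotype Imputation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A self-contained pipeline for asking whether the content of an
    exome-style genotyping array can be recovered by statistical imputation
    from ordinary GWAS arrays. Provides a seeded haplotype-population
    simulator with ascertainment-biased chip design, SNP/sample quality
    control (exact Hardy-Weinberg test, identity-by-state screening, PCA
    outlier detection), hierarchical linkage-disequilibrium surrogate search
    for rebuilding legacy array content, a Li-Stephens haplotype-copying
    imputation engine with reference-panel merging and genomic chunking, and
    the standard imputation quality metrics (info score, thresholded call
    rate, overall and minor-allele concordance, MAF-binned coverage
    accounting).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
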