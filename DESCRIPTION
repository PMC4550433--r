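Package: pathgsea
Title: Pathway-Based Association Analysis of GWAS Data by Permutation
    Gene Set Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pathway-based analysis of genome-wide association data for
    quantitative and threshold-dichotomized traits, motivated by plasma
    triglyceride genetics. Implements single-marker association testing
    (allelic chi-square and regression F) with minor-allele-frequency and
    Hardy-Weinberg quality control, SNP-to-gene statistic aggregation with
    flanking windows, a weighted Kolmogorov-Smirnov-like gene-set
    enrichment score with phenotype-label and SNP-label permutation null
    distributions, normalized enrichment scores, empirical P-values and a
    pooled-null false discovery rate, LD r-squared candidate-SNP
    selection, and a synthetic-study generator emulating array-scale
    genotypes and log-normal triglyceride phenotypes for method
    evaluation. Standard file formats (PLINK ped/map, BED, GMT, TSV) are
    read and written with explicit coordinate conventions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
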