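Package: partherit
Title: Genomic Heritability, GBLUP Prediction and SNP-Set Contributions in
    Family-Structured Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative-genetic analysis of family-structured
    populations genotyped at genome-wide SNPs: SNP quality control (minor
    allele frequency, minimum homozygote frequency, Hardy-Weinberg
    equilibrium), additive and dominance genomic relationship matrices,
    variance-component estimation by average-information restricted maximum
    likelihood (GREML), genomic best linear unbiased prediction (GBLUP) with
    per-individual reliabilities and back-solved per-SNP effects, single-SNP
    association scans (generalized least squares with family random effects,
    and least squares with multidimensional-scaling stratification
    correction), tenfold cross-validation with observed and expected
    prediction accuracies, and three methods for quantifying the contribution
    of a SNP set to genomic heritability and prediction accuracy, including
    partial heritability via fixed-SNP adjustment. A gene-dropping simulator
    of half-sib family data with local linkage disequilibrium provides
    datasets with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    SummarizedExperiment,
    S4Vectors,
    jsonlite,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
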