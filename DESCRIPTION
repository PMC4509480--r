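Package: finestruct
Title: Fine-Scale Population Structure and Stratification Analysis for SNP Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for fine-scale population-structure analysis of diploid
    biallelic SNP genotypes: PED/MAP input and output, quality control (sample
    and SNP missingness, minor allele frequency, an exact Hardy-Weinberg test,
    linkage-disequilibrium pruning), principal component analysis with
    Patterson-style standardization, Weir-Cockerham F_ST variance components
    with SNP-bootstrap confidence intervals and outlier scans, EM estimation of
    admixture proportions, genetic-geographic correlation (principal components
    versus latitude, F_ST versus distance), and case-control association
    simulations quantifying the impact of population stratification on false
    positive rate, power and genomic inflation. Includes Balding-Nichols
    genotype simulators (with latitudinal clines and stratified case-control
    sampling) so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    geosphere,
    vegan
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
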