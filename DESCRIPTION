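Package: omga
Title: Omnibus Multi-Trait Gene-Based Association Testing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gene-based association testing of multiple correlated quantitative
    traits. For each trait the joint (linear or nonlinear) effect of the SNPs in
    a gene is tested with a kernel U-statistic whose null distribution is
    approximated by a Satterthwaite scaled chi-square; p-values across candidate
    kernels (linear, IBS, Gaussian) are combined by a Cauchy omnibus test, and
    per-trait p-values are combined across traits by a Fisher statistic with a
    gamma approximation that accounts for the dependence between traits.
    Includes a genome-wide scan driver (MAF filtering, windowed SNP-to-gene
    mapping, multiple-testing adjustment), a PLINK and delimited-matrix reader,
    and an LD-structured genotype and correlated-trait simulator for type-I
    error and power studies, with a per-SNP MANOVA minimum-p comparator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
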