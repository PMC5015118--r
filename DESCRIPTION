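Package: fastbat
Title: Fast Set-Based Association Tests from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gene-based (set-based) association testing from genome-wide
    association study summary statistics and linkage-disequilibrium (LD)
    correlations estimated in a reference genotype panel. The set statistic is
    the sum of per-SNP chi-squared statistics; its null distribution, a
    weighted sum of 1-df chi-squares with weights equal to the eigenvalues of
    the LD correlation matrix, is evaluated analytically by Satterthwaite
    moment matching or Kuonen's saddlepoint approximation, removing the
    resolution floor of permutation- or simulation-based tests. Includes
    greedy LD pruning of SNP sets, a PLINK-1 bed/bim/fam reader with QC
    filters, a synthetic-cohort simulator (unlinked and block-LD genotypes,
    phenotypes with controlled per-variant heritability), resampling oracles
    (phenotype permutation and multivariate-normal simulation), and a
    command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
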