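Package: hlapheno
Title: HLA Imputation and Phenome-Wide Association Analysis of the MHC Region
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for population-scale analysis of classical HLA variation from
    SNP array data: attribute-bagging HLA allele imputation with posterior call
    thresholds, amino-acid translation of imputed alleles, a phenome-wide
    association scan with a multiallelic omnibus likelihood-ratio test,
    forward-type conditional fine-mapping with LD-linked HLA covariates,
    Haseman-Elston heritability and genetic-correlation networks, EM estimation
    of multilocus HLA haplotype frequencies, and carrier summaries for adverse
    drug reaction associated alleles. Includes a synthetic-cohort generator that
    emulates MHC-like LD between SNP haplotypes and HLA alleles so the whole
    chain is testable without restricted biobank data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    igraph,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
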