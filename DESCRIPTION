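Package: evlink
Title: Single Extracellular Vesicle Surface Proteomics and Genetic
    Association Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing single extracellular-vesicle (EV) surface
    proteomics generated by proximity barcoding assays (PBA): simulation of
    PBA read tables and genotype/phenotype cohorts with known truth, parsing
    of read tables into sparse EV-by-protein count matrices, chi-square
    background denoising with quantile thresholding, enumeration and
    quantification of marker-specific EV phenotypes (single markers and
    marker pairs), linear-model association testing against adiposity traits
    with sex-by-EV interaction and Benjamini-Hochberg false discovery rate
    control, preparation of EV phenotypes for genome-wide association scans,
    minor-allele-frequency filtering, per-SNP linear association scans,
    SNP-set annotation with flanking windows, and SNP-set heritability
    enrichment scoring against simulated genetic architectures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    IRanges,
    jsonlite,
    Matrix,
    methods,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
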