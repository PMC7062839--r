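Package: pleiocfdr
Title: Cross-Trait Pleiotropy Analysis of GWAS Summary Statistics with
    Conditional FDR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing shared genetic architecture between two
    phenotypes from genome-wide association study (GWAS) summary statistics.
    Harmonizes two sets of per-SNP association results onto a common allele
    orientation, prunes correlated variants with a reference linkage
    disequilibrium (LD) panel, draws stratified fold-enrichment and
    conditional quantile-quantile curves, computes per-SNP conditional false
    discovery rates (cFDR) in both directions and their conjunction (ccFDR),
    fits two-sample MR-Egger regression with a directional-pleiotropy
    intercept test, and annotates significant loci with nearest genes.
    Includes a synthetic-data generator with block-LD reference panels and a
    tunable pleiotropic architecture so the whole pipeline is testable
    without external downloads.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
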