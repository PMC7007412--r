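Package: polledcheck
Title: Verification Analyses for Genome-Edited Polled Cattle
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable implementations of the verification analyses applied to a
    genome-edited polled bull and his offspring: reconstruction of the wild-type,
    Celtic POLLED and plasmid-integrated alleles of the bovine POLLED locus;
    in-silico PCR genotyping of the polled/horned screen; k-mer baiting and
    junction classification of sequencing reads to assess insertion stability;
    donor-plasmid backbone screening and long-read allele assignment; trio
    Mendelian-error statistics with a windowed error-hotspot scan and group
    ANOVA; and VIF-pruned identity-by-state distances with dendrogram export.
    A synthetic-data generator with full ground truth drives end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
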