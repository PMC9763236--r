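Package: carrierrank
Title: Ranking Carrier Frequencies of Recessive Disease Genes from
    Population Callsets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates and ranks per-population carrier frequencies of
    autosomal recessive and X-linked disease genes from sites-only
    population variant callsets. Variants are classified into four
    deleterious categories (known pathogenic, presumed loss-of-function
    with a nonsense-mediated-decay escape rule, ensemble-predicted
    deleterious missense, and harmful in-frame insertions/deletions in
    pathogenic-harbouring protein domains), variant and gene carrier
    rates and predicted genetic prevalence are computed per population,
    genes are ranked, and cohorts are compared by rank correlation. A
    fully synthetic cohort generator with known ground truth supports
    end-to-end validation.
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
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
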