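Package: fiberdev
Title: Candidate Gene Discovery and Allele-Specific Markers for Cotton Fiber Quality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested reimplementation of a comparative transcriptome workflow
    for discovering fiber-quality candidate genes in allotetraploid cotton.
    Simulates an unreplicated two-species (Gossypium barbadense and
    G. hirsutum) fiber development count time course, quantifies expression as
    RPKM, performs two-library differential expression with
    Benjamini-Hochberg adjustment, classifies expression trends into
    elongation and secondary-cell-wall groups, filters cross-species
    upregulated candidates, runs hypergeometric GO enrichment, designs
    tri-primer allele-specific PCR markers that discriminate both species and
    homeologous subgenomes, genotypes a simulated BC3F5 introgression
    population in silico, and tests marker-trait associations with two-tailed
    t-tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
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
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
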