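Package: rohdiv
Title: Runs of Homozygosity and Genomic Diversity Analysis for Multi-Breed SNP Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for characterising genomic diversity in small livestock and
    poultry populations from SNP-array genotypes: PLINK PED/MAP input with
    call-rate and autosome quality control, per-population marker diversity
    statistics, consecutive-run detection of runs of homozygosity (ROH) with
    length-class summaries, exact-boundary ROH island calling and per-SNP
    incidence tracks, gene-interval annotation of islands, genomic inbreeding
    coefficients (F_HOM and F_ROH), Weir-Cockerham pairwise F_ST,
    identity-by-state distances with neighbour-joining trees, principal
    component scores, and linkage-disequilibrium-based historical effective
    population size. A forward-time multi-breed simulator with tracked
    identity-by-descent segments and exact pedigree inbreeding provides ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
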