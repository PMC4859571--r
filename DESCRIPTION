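Package: lobulescreen
Title: Voxel-Level Expression Screening for Cerebellar Purkinje Cell Vulnerability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mining volumetric in situ hybridization expression
    atlases for genes underlying the anterior-to-posterior gradient of
    cerebellar Purkinje cell vulnerability. Builds a gene-by-voxel expression
    matrix from per-gene expression-energy volumes, contrasts anatomically
    defined regions of interest (vulnerable lobules II/III versus resistant
    lobule X) with a pooled-variance t-test under Bonferroni correction and
    with Significance Analysis of Microarrays (permutation FDR with fudge
    factor selection), takes the top-N union of both rankings, and applies
    formalized curation filters (single-region detectability, concordance
    with a reference Purkinje cell survival pattern) to classify candidate
    neuroprotective and susceptibility genes. Includes hierarchical
    clustering of candidates, hypergeometric annotation over-representation,
    and a seeded synthetic-atlas generator with planted ground truth so the
    whole screen is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
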