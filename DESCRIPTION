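Package: invashift
Title: Gut Microbiome Shift and Homogenization During Biological Invasion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for comparing host-associated microbiomes between
    native and invaded ranges of invasive species. Implements core-microbiome
    identification from a Poisson abundance-occupancy null model with bootstrap
    consensus across hosts, taxonomic and phylogenetic alpha and beta diversity
    in the Hill-number framework (orders q = 0 and q = 1) at several taxonomic
    ranks, permutational multivariate tests (PERMANOVA with sequential sums of
    squares and interactions, pairwise PERMANOVA, PERMDISP) computed directly
    from dissimilarity matrices, compositional (centered log-ratio) and
    rank-based differential abundance with false-discovery-rate control,
    beta-diversity analysis of short-chain fatty acid functional groups from
    KEGG Orthology tables, and quantification of within- and between-species
    microbiome homogenization. A Dirichlet-multinomial community simulator with
    planted core taxa, regional abundance shifts and group-specific dispersion
    provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    vegan,
    withr,
    yaml
Suggests:
    biomformat,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
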