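Package: clonescape
Title: Clonality, Connectivity and Reproductive Investment in Seagrass
    Seascapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline linking clonal structure in seagrass
    meadows to sexual reproductive investment and hydrodynamic
    connectivity.  Detects clones from diploid microsatellite data
    (multilocus genotype matching, genotypic richness R, P_gen and P_sex),
    estimates genetic diversity (Na, observed heterozygosity, Nei's
    unbiased expected heterozygosity) and Weir-Cockerham F_ST with
    permutation significance, runs Mantel tests against distance or
    dispersal matrices, simulates seed-carrying fragment dispersal over
    gridded current fields (staged buoyancy, escalating mortality,
    delayed settlement, beaching) to produce dispersal probability and
    flow matrices, builds F_ST-threshold connectivity networks
    (node degree, betweenness centrality), and fits logit-link beta
    regressions of genotypic diversity on seed density and propagule
    inflow with AICc all-subsets model selection.  A synthetic-data
    module generates clonal microsatellite datasets, enclosed-bay
    current fields and reproductive covariates with known truth so the
    whole pipeline is testable without field data.
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
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
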