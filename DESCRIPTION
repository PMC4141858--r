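Package: clonepart
Title: Clonal Lineage Delimitation and Clone-Aware Population Genetics
    for Microsatellite Data
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing clonal population structure from codominant
    microsatellite genotypes, built around the multilocus-genotype (MLG) /
    multilocus-lineage (MLL) framework used for parthenogenetic organisms
    such as aphids. Collapses individuals to MLGs, computes allelic-difference
    distance matrices, delimits MLLs from the first minimum of the pairwise
    distance distribution, validates lineages with the p_sex probability of
    repeated sexual origin, and summarises clonal richness. Includes
    minimum-spanning networks with reticulation (tie) edges, clone-aware
    population genetics (Weir-Cockerham F_IS and F_ST, Monte-Carlo
    Hardy-Weinberg and genic G tests), COI barcode haplotype collapse and
    p-distance divergence, and a stepwise-mutation simulator of clonal
    datasets with ground truth for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    igraph,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
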