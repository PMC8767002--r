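Package: miceco
Title: Community Assembly, Abundance Categories, and Co-Occurrence
    Networks for Microbiome OTU Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for community ecology of amplicon (16S rRNA) OTU tables
    from grouped study designs: alpha diversity (observed richness,
    bias-corrected Chao1, Shannon, Faith's phylogenetic diversity),
    Bray-Curtis and Jaccard distances with NMDS ordination and
    permutation tests (PERMANOVA, ANOSIM, Mantel); classification of taxa
    into six abundance categories (rare, abundant, moderate, and their
    conditional variants); null-model inference of community assembly
    processes via beta mean nearest-taxon distance, the beta nearest-taxon
    index, and the modified Raup-Crick index on Bray-Curtis; random-matrix
    theory thresholded co-occurrence networks with fast-greedy modules,
    topology indices, degree-preserving random baselines, and Zi-Pi node
    roles; fish growth indices (Fulton's K, daily growth coefficient);
    and a synthetic-community generator with known assembly processes for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    vegan,
    igraph,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    picante
Config/testthat/edition: 3
RoxygenNote: 7.3.3
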