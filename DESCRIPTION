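Package: moltloss
Title: Repeated Gene Loss, Ancestral Orthogroup Content, and Molting-Regulator
    Screening on Nematode Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Inference machinery for studying the repeated loss of the
    ecdysone receptor (ecr) and its heterodimer partner (usp) across a
    species phylogeny, and for screening conserved molting regulators.
    Provides Dollo-parsimony mapping of minimal gene-loss events onto a
    taxon tree with a reliability rule for distinguishing loss from
    missing data; reconstruction of ancestral nuclear-receptor orthogroup
    content from OrthoFinder-style tables using an all-taxa coverage rule;
    reciprocal one-to-one top-hit homolog screening with iterative query
    expansion and gene-tree clade validation; fuzzy c-means clustering of
    molting-cycle expression time courses with algorithmic selection of
    pre-molt clusters; cross-species orthogroup intersection and
    transcription-factor domain filtering; and Kabsch/TM-score structural
    classification of ligand-binding domains against a reference receptor
    panel. A synthetic-data module generates inputs with known ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    bio3d,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
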