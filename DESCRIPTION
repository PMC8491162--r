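Package: topojak
Title: Topological QSAR Discriminant Screening for JAK Inhibitors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ligand-based discovery toolkit for Janus kinase (JAK) inhibitors
    built on molecular topology. Parses SMILES into annotated chemical graphs,
    computes the topological descriptor families used by published linear
    discriminant models (self-returning walk counts, information-content
    indices, Geary and Moran autocorrelations, Galvez charge indices, edge
    adjacency eigenvalues, P_VSA-like sums, multiple path counts), fits and
    validates two-group discriminant functions with Wilks-lambda stepwise
    selection, derives activity windows from pharmacological distribution
    diagrams, screens and subtype-profiles compound libraries, and clusters
    hits by Carhart atom-pair fingerprint similarity with the Kelley
    cluster-count criterion. Includes a seeded synthetic library generator so
    the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    ape,
    ChemmineR,
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
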