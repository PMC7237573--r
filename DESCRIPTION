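Package: ienar
Title: Individual-Specific Edge-Network Analysis of Microbiome Abundance Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-sample network scoring of taxon abundance tables against a
    healthy reference cohort. Implements the individual-specific edge-network
    analysis (iENA) workflow for fecal metagenomic profiles: single-sample
    Pearson correlation perturbation (sPCC), edge-network construction from
    top-ranked taxon pairs, fourth-order correlation scores for edge-pairs,
    edge-biomarker ("Marker") selection, the sCI composite index used to
    quantify how far an individual microbiota community has departed from the
    reference state, and per-group co-occurrence networks with differential
    network and hub analysis. Also provides the conventional companion
    statistics (Wilcoxon and Kruskal-Wallis differential abundance with BH
    correction, hypergeometric category enrichment, alpha diversity, PCA) and
    a seeded compositional cohort simulator with planted correlation rewiring
    for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    MASS,
    igraph,
    jsonlite,
    vegan,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
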