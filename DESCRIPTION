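Package: neurometnet
Title: Neuron-Astrocyte Metabolic Network Analysis and Differential Hub Genes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Integrative analysis of two-cell (neuron-astrocyte) constraint-based
    metabolic models. Solves flux balance analysis with a coupled
    neurotransmission objective, extracts reduced-cost sensitivities and
    phenotypic phase planes, scores reactions by Absolute Optimality and by
    node-removal induced centrality aggregated into the Absolute Centrality
    Contribution, and intersects the resulting hub genes with differential
    expression tables to derive differential hub genes, with hypergeometric
    over-representation analysis against gene-set collections. Includes a
    seeded synthetic-data generator producing feasible two-cell models
    (lactate-shuttle, glutamate-glutamine cycle and sodium-pump arms) with
    planted hubs and planted differentially expressed genes for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
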