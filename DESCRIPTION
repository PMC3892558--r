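Package: traitvenn
Title: Comparative Census of Molecular Traits Across the Three Superkingdoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative genomic analysis of trait repertoires
    (protein fold superfamilies, terminal Gene Ontology terms) across
    Archaea, Bacteria and Eukarya. Partitions traits into the seven
    mutually exclusive Venn taxonomic groups, quantifies per-superkingdom
    spread with f-values, calls directional horizontal gene transfer
    candidates from f-value differences, summarises genomic abundance as
    a relative-age proxy, maps terminal ontology terms to level-1 parent
    categories over an is_a DAG, and places traits on node-distance (nd)
    evolutionary timelines.  A superkingdom-diversification simulator
    generates ground-truthed occurrence/abundance matrices, metadata,
    ontologies and trait trees so every stage of the pipeline can be
    validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
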