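Package: pathoverlay
Title: Icon-Overlay Pathway Diagrams and Gene-Set Enrichment for
    Gene-Centric Annotations
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Headless toolkit for interpreting gene-centric annotation
    tables in the context of biological pathways. Ingests tab-delimited
    annotation files keyed by gene symbol, normalizes symbols against an
    HGNC reference with two-phase approved/synonym matching and
    ambiguous-synonym removal, joins annotations onto pathway gene sets
    (GMT) and Cytoscape XGMML topologies, computes per-pathway overlap
    counts and one-sided Fisher's exact enrichment, and renders static
    SVG/HTML pathway diagrams with per-gene annotation icons, hover
    tooltips, a legend, and GeneCards hyperlinks. Includes deterministic
    fixture generators and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
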