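Package: wormpaths
Title: Multi-Level Metabolic Pathway Annotation, Enrichment Analysis, and
    Standardized Pathway-Map Rendering for C. elegans-Style Metabolic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for working with genome-scale metabolic model annotations
    in the style of the iCEL1314 C. elegans network: parsing of tabular model
    files with boolean OR/AND gene-reaction rules, a four-level gene-to-pathway
    annotation hierarchy with GMT gene-set export, hypergeometric pathway
    enrichment/depletion analysis (PEA) over the metabolic gene universe,
    metabolite pathway-connectivity and transportability classification,
    terminal-metabolite rules for pathway map design, a standardized SVG
    pathway-map renderer with a map linter, and a deterministic synthetic
    fixture generator with planted ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    yaml,
    xml2,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
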