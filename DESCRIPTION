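Package: variotools
Title: Variation Ontology (VariO) Annotation of Sequence Variants
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for annotating the effects, consequences and mechanisms
    of sequence variants with the Variation Ontology (VariO). Parses HGVS
    variant descriptions at the DNA, RNA and protein levels, classifies
    variants into VariO concepts (substitution classes such as transitions
    and transversions, chain variations, coding consequences), expands
    every assigned concept to its full root-to-leaf ontology path, attaches
    attribute modifiers (quantity change, pathogenicity association,
    conservation, interaction) and Evidence Codes Ontology (ECO) terms
    under the ontology's usage rules, and validates and renders complete
    annotation sets as text, JSON or TSV. Ships a self-contained
    mini-ontology fixture and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    jsonlite,
    yaml,
    Biostrings,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'ontology.R'
    'hgvs.R'
    'classify.R'
    'annotate.R'
    'render.R'
    'fixtures.R'
    'cli.R'
    'variotools-package.R'
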