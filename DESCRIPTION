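Package: ervatlas
Title: Endogenous Retrovirus Discovery, Annotation, and Insertion Dating
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome mining of endogenous retroviruses (ERVs) from assembled
    genomes: translated homology screening with retroviral POL probes,
    paired-LTR provirus structure calling with target-site duplication,
    primer-binding-site and polypurine-tract annotation, lineage clustering
    and consensus construction under standard ERV nomenclature, solo-LTR
    classification, Kimura two-parameter paired-LTR insertion dating, and
    cross-genome orthologous-insertion detection.  Includes a provirus
    genome simulator with a machine-readable truth table so every stage of
    the pipeline can be validated against planted elements of known age.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape,
    jsonlite,
    optparse
Config/testthat/edition: 3
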