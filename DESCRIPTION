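Package: pelscan
Title: Discovery of Phenotypically Enriched Loci from Patient CNV Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds genotype-based patient networks from copy-number-variant
    (CNV) overlaps, mines maximal cliques of genetically related patients,
    scores each clique for Human Phenotype Ontology (HPO) term enrichment
    with an exact hypergeometric test, and characterizes Phenotypically
    Enriched Loci (PELs) by case-control Fisher association against a
    healthy-population structural-variant catalogue, with a Cooper-style
    penetrance estimate per locus-phenotype pair. Includes five permutation
    null models for assessing discovery significance and a seeded synthetic
    cohort generator with implanted ground-truth loci for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    IRanges,
    S4Vectors,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
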