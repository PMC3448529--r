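Package: phenoeq
Title: Entity-Quality Formalization and Structural Reasoning for Yeast
    Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Compiles entity-quality (EQ) phenotype definitions from OBO
    flat files into class expressions using per-category phene patterns,
    formalizes SGD-style genotype-phenotype annotations (observable +
    qualifier, optionally a ChEBI chemical), reasons structurally over
    the results (EL-style subsumption with transitive-reflexive part-of
    and the has-part/part-of property chain, classification, hierarchy
    inference, qualifier consistency checking), and runs a phenotype to
    Gene Ontology gene-function recovery analysis with support for novel
    candidate annotations. Ships deterministic mini-ontology fixtures
    and a seeded synthetic benchmark with planted recovery rates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
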