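# Shared fixture objects, built once per test run.

fx <- build_mini_ontologies()
fx_all <- fx$merged
fx_defs <- compile_ontology_definitions(fx_all, unions = fx$unions)
fx_ax <- build_axioms(fx_all, fx_defs$equivalences, fx_defs$sufficient)
# axiom set without class definitions: pure ontology-graph + property
# semantics, the fragment the brute-force oracle covers
fx_ax_plain <- build_axioms(fx_all)

fx_anns <- example_phenotype_annotations()
fx_goa <- example_gene_go_annotations()

# the published class expressions (the bare token "normal" is written
# as its home class PATO:0000461)
published_expressions <- c(
  "APO:0000053" =
    "phenotype-of some (has-part some (GO:0005618 and has-quality some PATO:0000051))",
  "APO:0000142" =
    "phenotype-of some (has-part some (GO:0005623 and has-quality some PATO:0000117 and during some GO:0031576))",
  "APO:0000066" =
    "phenotype-of some (has-part some (part-of some GO:0009987 and has-quality some PATO:0000001))",
  "APO:0000090" =
    "phenotype-of some (has-part some (GO:0010038 and has-quality some PATO:0001457))",
  "APO:0000087" =
    "phenotype-of some (GO:0042221 and has-quality some (PATO:0001457 and towards some CHEBI:37577))",
  "heat-sensitivity:increased" =
    "phenotype-of some (has-part some GO:0009408 and has-quality some (PATO:0001457 and increased-in-magnitude-relative-to some PATO:0000461))",
  "cell-cycle:arrested" =
    "phenotype-of some (has-part some GO:0022402 and has-quality some PATO:0000297)",
  "S000000649" =
    "phenotype-of some (has-part some GO:0042221 and has-quality some (PATO:0001457 and towards some CHEBI:26710))"
)
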