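# phenoeq

Entity–quality (EQ) formalization and structural reasoning for yeast
phenotypes.

## The problem

Budding-yeast phenotypes are curated as *pre-composed* class pairs: an
**observable** (the affected trait, e.g. *heat sensitivity*, *cell wall
morphology*) and a **qualifier** (the comparative value, e.g.
*increased*, *arrested*), drawn from the Ascomycete Phenotype Ontology
(APO), optionally joined by a ChEBI chemical for triples such as *ionic
stress resistance: decreased, sodium chloride*. These pre-composed
classes are opaque to reasoners and do not interoperate with phenotype
annotations of other species.

The EQ method decomposes each observable into an affected **entity**
(a GO process, function or cellular component, or a chemical) and a
PATO **quality** that inheres in it. `phenoeq` compiles such
decompositions — stored as ordinary OBO `intersection_of` blocks — into
composed class expressions, applies qualifiers, reasons structurally
over the results, and uses the GO classes embedded in the expressions
to recover and propose gene-function annotations. It is intended for
ontology engineers and curators working on phenotype integration, and
as a compact, fully testable implementation of the EQ compilation and
reasoning machinery.

## The method

Each EQ-defined observable compiles through a *phene pattern* selected
by its category:

| category          | pattern |
|-------------------|---------|
| object morphology | `phenotype-of some (has-part some (E and has-quality some Q))` |
| temporal object   | as above, with `… and during some S` inside the bearer conjunction |
| process           | `phenotype-of some (has-part some (part-of some E and has-quality some Q))` |
| disposition       | `phenotype-of some (has-part some (E and has-quality some Q))` |
| relational        | disposition with `Q and towards some C` as the quality |

`E` is the bearer entity, `Q` the PATO quality, `S` a temporal stage,
`C` a chemical. Qualifiers compose in one of two ways: a PATO
*substitution* (e.g. *arrested* → `PATO:0000297` replaces the quality)
or a *magnitude modifier*
(`Q and increased-in-magnitude-relative-to some PATO:0000461`).
A genotype's phenotype expressions combine by class intersection.

Reasoning is structural EL-style subsumption (description-tree
homomorphism) with `part-of` transitive and reflexive, the property
chain `has-part ∘ part-of → has-part`, and free `is_a` traversal inside
`part-of` chains. Because the process pattern routes through `part-of`
over GO, the reasoner infers a restructured observable hierarchy (e.g.
development phenotypes fall under cellular-process phenotypes), checks
qualifier/bearer category consistency, and classifies yeast expressions
under any other loaded ontology's EQ-defined classes.

Expression syntax (the render grammar; `normal` is accepted as an alias
for `PATO:0000461`):

```
expr    ::= primary ( "and" primary )*
primary ::= CURIE | RELATION "some" primary | "(" expr ")"
```

## Worked example

```r
library(phenoeq)

fx   <- build_mini_ontologies()      # mini GO / PATO / ChEBI / APO
onts <- fx$merged
anns <- example_phenotype_annotations()

# formalize "heat sensitivity (APO:0000147): increased (APO:0000004)"
heat <- formalize_annotation(anns[1, ], onts)
print(heat)
#> phenotype-of some (has-part some (GO:0009408 and has-quality some
#>   (PATO:0001457 and increased-in-magnitude-relative-to some PATO:0000461)))
```

The expression reads: a phenotype of something that has a part which is
a response-to-heat process bearing an increased process sensitivity.
The reasoner places it back under its observable:

```r
defs <- compile_ontology_definitions(onts, unions = fx$unions)
ax   <- build_axioms(onts, defs$equivalences, defs$sufficient)
classify_expression(heat, ax)$most_specific
#> [1] "APO:0000147"

infer_hierarchy(ax)
#>         child      parent
#> 1 APO:0000023 APO:0000066
#> 2 APO:0000024 APO:0000066
#> 3 APO:0000087 APO:0000089
#> 4 APO:0000090 APO:0000089
#> 5 APO:0000094 APO:0000066
#> 6 APO:0000253 APO:0000066
#> 7 APO:0000303 APO:0000094
```

The first and fifth rows are the signature restructuring: development
(APO:0000023) and metabolism-and-growth (APO:0000094) phenotypes are
inferred to be cellular-process phenotypes (APO:0000066) purely from
GO's process hierarchy and the process pattern.

Function recovery compares phenotype-derived GO classes against a
gene–GO table (ancestor-or-descendant matching by default) and
proposes unmatched predictions as novel candidates:

```r
rep <- recover_functions(anns, example_gene_go_annotations(), onts)
rep$counts
#>  aspect recovered total percentage
#>       P         1     1        100
#>       F         0     4          0
#>       C         0     1          0
subset(rep$candidates, gene_id == "CLN3")
#>   gene_id      go_id  genotypes
#> 4    CLN3 GO:0000080 S000031234
```

The CLN3 row proposes involvement in the mitotic G1 phase from the
gene's curated phenotype alone — the novel-candidate mechanism.

## Command line

A thin wrapper is installed at `inst/cli/phenoeq.R`:

```sh
Rscript inst/cli/phenoeq.R fixtures --out-dir fx --seed 42
Rscript inst/cli/phenoeq.R compile --obo fx/mini-apo.obo --obo fx/mini-go.obo \
    --obo fx/mini-pato.obo --obo fx/mini-chebi.obo --unions fx/unions.tsv --verbatim
Rscript inst/cli/phenoeq.R annotate  --annotations fx/example-phenotypes.tsv --obo ...
Rscript inst/cli/phenoeq.R classify  --expression "GO:0009987" --obo ...
Rscript inst/cli/phenoeq.R infer-hierarchy --obo ... --unions fx/unions.tsv
Rscript inst/cli/phenoeq.R recover --phenotypes p.tsv --goa g.tsv --match ancestor --obo ...
```

Exit codes: 0 success, 1 input error, 2 internal error.

### File dialects

Phenotype annotations are UTF-8 TSV with header
`genotype_id gene_id observable_id qualifier_id chemical_id condition`
(empty `chemical_id` = pair annotation; `!` lines are comments).
Gene–GO tables have header `gene_id go_id aspect` with aspect in
`P`/`F`/`C`. The qualifier map and category overrides are editable TSV
configs shipped under `inst/extdata/`. A converter from native SGD
download formats is future work.

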