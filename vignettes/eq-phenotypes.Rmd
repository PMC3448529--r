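---
title: "Compiling and reasoning over entity–quality yeast phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compiling and reasoning over entity–quality yeast phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoeq)
```

## The model

Yeast phenotype curation records an *observable* (the affected trait)
and a *qualifier* (its comparative value), both from the Ascomycete
Phenotype Ontology, sometimes with a ChEBI chemical as a third member.
`phenoeq` treats each observable as an entity–quality (EQ) pair: a
PATO quality inhering in an entity from GO (a process, function or
cellular component) or ChEBI, recorded as an ordinary OBO
`intersection_of` block whose genus is the quality and whose
differentia are `inheres_in` (the bearer), and optionally `during`
(a temporal stage) and `towards` (the second argument of a relational
quality).

Compilation turns each definition into a class expression over a fixed
relation vocabulary (`phenotype-of`, `has-part`, `part-of`,
`has-quality`, `during`, `towards`, and the two magnitude-modifier
relations). The pattern used depends on the definition's category:

* **object morphology** — the quality inheres in a material part:
  `phenotype-of some (has-part some (E and has-quality some Q))`.
* **temporal object** — the same with `during some S` added inside the
  bearer conjunction.
* **process** — the quality inheres in something that is part of the
  named process: the bearer becomes `part-of some E`. Routing through
  `part-of` is what lets GO's process graph reorganize the observable
  hierarchy.
* **disposition** — process-directed qualities (sensitivity of a
  process, arrested, and other descendants of PATO's process-quality
  branch) already inhere in the affected process, so the bearer is
  used directly, without the `part-of` wrapper.
* **relational** — a disposition whose quality takes a second
  argument: `Q and towards some C`.

`inheres_in` itself never appears in compiled output; it exists only in
the OBO EQ layer. `has-disposition`/`has-function` relations are
deliberately not used: distinguishing processes from dispositions
formally would make large parts of existing phenotype ontologies
unsatisfiable, so the uniform `has-part` form is kept.

### Category assignment

The source material assigns patterns by prose section, not by
algorithm, so the package fixes a rule, applied in order: `towards`
present → relational; `during` present → temporal object; quality in
PATO's process-quality branch (`PATO:0001236` or below) → disposition;
bearer namespace `biological_process`/`molecular_function` → process;
otherwise → object morphology. The process-quality clause generalizes
"quality is a process sensitivity": it is what makes *cell cycle
progression: arrested* compile without a `part-of` wrapper, matching
the published form, while *cellular process* (generic quality,
process bearer) keeps it. Terms where the rule is wrong can be pinned
via a two-column override table (`inst/extdata/category_overrides.tsv`,
empty by default — the rules cover every shipped fixture).

### Qualifiers

Qualifier composition is table-driven
(`inst/extdata/qualifier_map.tsv`). Two strategies exist, exactly one
per qualifier:

* **substitution** — the qualifier's PATO equivalent replaces the
  observable's quality (*arrested* → `PATO:0000297`, *absent* →
  `PATO:0000462`, *abnormal* → `PATO:0000460`). When the substituted
  quality specializes the observable's own quality (arrested ⊑ process
  quality), the formalized annotation is provably subsumed by the bare
  observable's class; the shipped *abnormal* mapping is a covering
  value rather than a specialization, so that guarantee does not
  extend to it. The *absent* mapping is a package choice — the
  published material names the qualifier but never prints its
  expression.
* **magnitude modifier** — *increased*/*decreased* refine the quality:
  `Q and increased-in-magnitude-relative-to some PATO:0000461`. The
  bare token `normal` used in published listings is given a resolvable
  home as `PATO:0000461` (a class, not an individual); the parser
  accepts `normal` as an alias but renderings always use the CURIE.

Triples attach the observed chemical as `towards` on the quality,
replacing any more general `towards` class in the observable's own
definition. For *decreased resistance* triples, the intended semantics
is ambiguous (decreased sensitivity vs. a bare relational quality);
default mode applies the decreased modifier for consistency with the
heat-sensitivity pattern, while verbatim mode reproduces the published
layout, which leaves the quality bare.

### Normalized vs. verbatim output

Published expression listings are not laid out uniformly: the
resistance-to-chemicals equivalence omits `has-part`, and annotation
expressions place `has-quality` as a sibling of `has-part` rather than
inside its filler. Default output normalizes everything to the nested
`has-part` form, so subsumption behaves uniformly; `verbatim = TRUE`
reproduces the published layouts token for token (the acceptance tests
pin all eight printed expressions). Compiled output preserves pattern
order (bearer, quality, stage); `canonicalize_expression()` separately
provides the flattened, byte-lexicographically sorted form used
wherever bit-stable renderings matter. Conjunct order is semantically
inert either way.

## Reasoning

Subsumption is structural: `general` subsumes `specific` iff the
description tree of `general` maps homomorphically into that of
`specific`, with atoms matched through the `is_a` closure, `part-of`
matched along transitive (and reflexive, i.e. zero-length) chains of
`part-of` and `is_a` edges drawn from both the expressions and the
ontology's `relationship` clauses, and `has-part` absorbing a trailing
`part-of` chain (the property chain). Equivalence-defined atoms are
unfolded before matching, with cycle detection; definitional cycles
are treated as authoring errors. This conjunctive-existential fragment
covers every construct the compiler can emit, which is what makes the
exhaustive homomorphism oracle in the test suite a meaningful
cross-check; no general TBox saturation, negation, cardinality or
universal restriction is attempted, and completeness against a full
OWL reasoner is not claimed.

The expression language has no union node. The one union-defined
observable (metabolism and growth ≙ cellular metabolic process *or*
cellular growth) is carried as a list of per-disjunct sufficient
conditions: an expression classifies under the class if any disjunct
subsumes it, and for class-level subsumption the disjuncts are read as
jointly exhaustive, so the class sits below a parent exactly when every
disjunct does. That reading is what licenses placing
metabolism-and-growth under cellular-process phenotypes.

`infer_hierarchy()` computes pairwise class subsumption among defined
classes, discards asserted edges, and returns the transitive reduction
(asserted edges may serve as intermediates). Most-specific subsumer
sets return all minimal elements, sorted by CURIE. Qualifier
consistency checking reads the quality's category off PATO's
process-quality/object-quality branches and the bearer's category off
its namespace; qualities under neither branch produce a warning and a
skipped check rather than a verdict.

## Function recovery

GO classes are extracted from every atom position of a gene's
formalized expressions (bearers, `during` stages alike). The source
material says only that extracted terms were "compared" with existing
annotations; exact matching would put recovery near zero because EQ
bearers are deliberately high-level, so the default rule counts an
existing annotation as recovered when a predicted term equals it or is
its ancestor or descendant in the combined `is_a`/`part_of` closure.
Both rules are exposed (`match = "ancestor"` / `"exact"`). Duplicate
annotation lines are deduplicated before counting; per-aspect
percentages are `recovered/total × 100`, with `0/0` rendered `NA` to
distinguish absence of data from failure. Predicted terms that recover
nothing for their gene become novel candidate annotations, carrying
their supporting genotype ids. Published recovery percentages from
2011-era database snapshots are treated as reference points only: the
underlying gene sets, ontology releases and matching rule are not
recoverable, so the package's quantitative claims are made against its
own synthetic benchmark instead.

## Fixtures and the synthetic benchmark

The fixture catalog hand-curates mini versions of GO, PATO, ChEBI and
APO (~75 classes) whose edges mirror the public ontologies for every
class the worked examples touch; mini-APO keeps the four top-level
hierarchies (observable, qualifier, experiment type, mutant type),
with the latter two present only structurally — their terms are never
formalized. Ids that the public ontologies publish are used verbatim;
fixture-only terms carry synthetic ids and are marked as such in the
source. Everything is generated in code; nothing is fetched.

The benchmark emulates the shape of a genotype–phenotype plus gene–GO
comparison: each of `n_genes` simulated genes gets one phenotype
annotation per GO aspect (observables drawn from fixed per-aspect
pools) and two GO annotation lines per aspect. Independently per line,
with probability `planted_rate` the GO term is drawn from the bearer's
hand-curated ancestor/descendant set (recoverable by construction),
otherwise from a same-namespace decoy set that is neither ancestor nor
descendant of any of the gene's phenotype-derived terms. The plant
decisions are recorded, so the pipeline's recovery can be required to
equal the generator's ground truth *exactly* — the plant and the
comparator are computed by independent routes (curated constants vs.
graph closure), and a dedicated test verifies the constants against
the closure. Defaults are 200 genes, rate 0.5, seed 42: 400 annotation
lines per aspect put the 99% binomial envelope at roughly ±6.4
percentage points around the planted rate, tight enough to detect a
broken comparator and cheap enough to run in seconds; a 2000-gene run
in the test suite checks that the estimate tightens as the gene count
grows. What the benchmark does *not* emulate: real annotation depth
distributions, evidence codes, correlated phenotypes within a gene,
conditional phenotypes, or the breadth of real GO — passing it shows
the extraction/comparison machinery is correct, not that any
particular recovery percentage will hold on live databases.

Determinism: one integer seed, R's Mersenne–Twister, generator state
restored afterwards; regeneration with the same seed is
byte-identical. The generator algorithm (per-gene loop, flags first,
then term draws without replacement within each group) is stated so
that reimplementations can match the recorded output files, though not
necessarily the raw random stream.

## Numerical and degenerate-input choices

* Canonical conjunction order is byte-lexicographic (`radix`) on the
  rendering — locale-independent, so renderings are bit-stable across
  platforms. Exact duplicate conjuncts are dropped.
* OBO output orders terms by CURIE and clauses by a fixed schedule;
  unknown clause types pass through opaquely, so `write_obo ∘
  parse_obo` is a fixpoint and loses nothing.
* Dangling cross-ontology references are recorded and logged, never
  fatal; duplicate CURIEs (within a file or across merged files) are
  hard errors.
* Empty inputs: an empty document parses to an empty ontology; an
  empty genotype expression list is an error (there is no empty
  intersection); 0/0 recovery aspects render `NA`.
* Condition text on annotations is carried verbatim and never
  interpreted; whether it encodes semantics (temperatures for
  conditional mutants) is an open question upstream.

## Limitations

* The reasoner is intentionally small: no disjointness, no
  unsatisfiability detection beyond the qualifier-category check.
* Experiment-type and mutant-type branches are not formalized.
* The SGD download format itself is not parsed; the package defines
  its own stable TSV dialect and leaves a converter as future work.
* Cross-species classification is demonstrated against a synthetic
  mini-ontology; classifying under the real mammalian or worm
  phenotype ontologies requires loading those ontologies (the
  machinery supports it in principle, given EQ bridging definitions).
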