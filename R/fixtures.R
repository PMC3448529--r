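## Deterministic desk-scale fixtures: mini versions of GO, PATO, ChEBI
## and APO whose edges mirror the public ontologies' is_a/part_of
## structure for the ~50 classes the EQ machinery exercises, curated
## example annotation sets, and a seeded synthetic benchmark with a
## planted recovery rate. Edge lists are hand-curated constants,
## versioned here; nothing is ever fetched from the network. Ids the
## source ontologies publish are used verbatim; ids invented for
## unpublished fixture terms (hierarchy roots, benchmark observables)
## are marked "synthetic id" in the term name comment.

tm <- function(id, name, ns, isa = character(0), rel = NULL, eq = NULL) {
  relationships <- if (is.null(rel)) {
    list()
  } else {
    lapply(rel, function(r) list(relation = r[1], target = r[2]))
  }
  intersection_of <- if (is.null(eq)) {
    NULL
  } else {
    list(
      genus = eq$genus,
      differentia = lapply(eq$diff, function(d) {
        list(relation = d[1], target = d[2])
      })
    )
  }
  new_ontology_term(id, name = name, namespace = ns, is_a = isa,
                    relationships = relationships,
                    intersection_of = intersection_of)
}

ontology_from_terms <- function(terms) {
  o <- new_ontology(stats::setNames(terms,
                                    vapply(terms, `[[`, character(1),
                                           "id")))
  o$dangling <- find_dangling(o)
  o
}

mini_go_terms <- function() {
  bp <- "biological_process"
  cc <- "cellular_component"
  mf <- "molecular_function"
  list(
    tm("GO:0008150", "biological_process", bp),
    tm("GO:0009987", "cellular process", bp, "GO:0008150"),
    tm("GO:0048869", "cellular developmental process", bp, "GO:0009987"),
    tm("GO:0030154", "cell differentiation", bp, "GO:0048869"),
    tm("GO:0008152", "metabolic process", bp, "GO:0008150"),
    tm("GO:0044237", "cellular metabolic process", bp,
       c("GO:0008152", "GO:0009987")),
    tm("GO:0016049", "cell growth", bp, "GO:0009987"),
    tm("GO:0007049", "cell cycle", bp, "GO:0009987"),
    tm("GO:0022402", "cell cycle process", bp, "GO:0009987",
       rel = list(c("part_of", "GO:0007049"))),
    tm("GO:0000080", "mitotic G1 phase", bp, "GO:0022402"),
    tm("GO:0031576", "G2/M transition of mitotic cell cycle", bp,
       "GO:0022402"),
    tm("GO:0007114", "cell budding", bp, "GO:0009987"),
    tm("GO:0006914", "autophagy", bp, "GO:0044237"),
    tm("GO:0050896", "response to stimulus", bp, "GO:0008150"),
    tm("GO:0042221", "response to chemical", bp, "GO:0050896"),
    tm("GO:0010038", "response to metal ion", bp, "GO:0042221"),
    tm("GO:0009408", "response to heat", bp, "GO:0050896"),
    tm("GO:0005575", "cellular_component", cc),
    tm("GO:0110165", "cellular anatomical entity", cc, "GO:0005575"),
    tm("GO:0005623", "cell", cc, "GO:0005575"),
    tm("GO:0005618", "cell wall", cc, "GO:0110165",
       rel = list(c("part_of", "GO:0005623"))),
    tm("GO:0009277", "fungal-type cell wall", cc, "GO:0005618"),
    tm("GO:0005634", "nucleus", cc, "GO:0110165"),
    tm("GO:0005739", "mitochondrion", cc, "GO:0110165"),
    tm("GO:0005886", "plasma membrane", cc, "GO:0110165"),
    tm("GO:0003674", "molecular_function", mf),
    tm("GO:0003824", "catalytic activity", mf, "GO:0003674"),
    tm("GO:0016740", "transferase activity", mf, "GO:0003824"),
    tm("GO:0016301", "kinase activity", mf, "GO:0016740"),
    tm("GO:0004674", "protein serine/threonine kinase activity", mf,
       "GO:0016301"),
    tm("GO:0016787", "hydrolase activity", mf, "GO:0003824"),
    tm("GO:0005215", "transporter activity", mf, "GO:0003674")
  )
}

mini_pato_terms <- function() {
  q <- "quality"
  list(
    tm("PATO:0000001", "quality", q),
    tm("PATO:0001236", "process quality", q, "PATO:0000001"),
    tm("PATO:0001241", "physical object quality", q, "PATO:0000001"),
    tm("PATO:0000051", "morphology", q, "PATO:0001241"),
    tm("PATO:0000052", "shape", q, "PATO:0000051"),
    tm("PATO:0000117", "size", q, "PATO:0000051"),
    tm("PATO:0001457", "sensitivity of a process", q, "PATO:0001236"),
    tm("PATO:0001551", "increased sensitivity of a process", q,
       "PATO:0001457"),
    tm("PATO:0000297", "arrested", q, "PATO:0001236"),
    tm("PATO:0000502", "delayed", q, "PATO:0001236"),
    tm("PATO:0000461", "normal", q, "PATO:0000001"),
    tm("PATO:0000460", "abnormal", q, "PATO:0000001"),
    tm("PATO:0000462", "absent", q, "PATO:0000001")
  )
}

mini_chebi_terms <- function() {
  ch <- "chebi_ontology"
  list(
    tm("CHEBI:24431", "chemical entity", ch),
    tm("CHEBI:37577", "chemical compound", ch, "CHEBI:24431"),
    tm("CHEBI:26710", "sodium chloride", ch, "CHEBI:37577")
  )
}

mini_apo_terms <- function() {
  ob <- "observable"
  ql <- "qualifier"
  list(
    # the four top-level hierarchies (root ids other than observable
    # are synthetic ids)
    tm("APO:0000017", "observable", ob),
    tm("APO:0000015", "qualifier", ql),                  # synthetic id
    tm("APO:0000019", "experiment type", "experiment_type"),  # synthetic id
    tm("APO:0000018", "mutant type", "mutant_type"),          # synthetic id
    tm("APO:0000020", "classical genetics", "experiment_type",
       "APO:0000019"),                                   # synthetic id
    tm("APO:0000021", "conditional", "mutant_type",
       "APO:0000018"),                                   # synthetic id
    # observables
    tm("APO:0000032", "morphology", ob, "APO:0000017"),  # synthetic id
    tm("APO:0000051", "cell shape", ob, "APO:0000032",
       eq = list(genus = "PATO:0000052",
                 diff = list(c("inheres_in", "GO:0005623")))),
    tm("APO:0000053", "cell wall morphology", ob, "APO:0000032",
       eq = list(genus = "PATO:0000051",
                 diff = list(c("inheres_in", "GO:0005618")))),
    tm("APO:0000301", "nuclear morphology", ob, "APO:0000032",
       eq = list(genus = "PATO:0000051",
                 diff = list(c("inheres_in", "GO:0005634")))),  # synthetic id
    tm("APO:0000142",
       "critical cell size at G2/M (cryptic G2/M cell size checkpoint)",
       ob, "APO:0000032",
       eq = list(genus = "PATO:0000117",
                 diff = list(c("inheres_in", "GO:0005623"),
                             c("during", "GO:0031576")))),
    tm("APO:0000066", "cellular process", ob, "APO:0000017",
       eq = list(genus = "PATO:0000001",
                 diff = list(c("inheres_in", "GO:0009987")))),
    tm("APO:0000023", "development", ob, "APO:0000017",
       eq = list(genus = "PATO:0000001",
                 diff = list(c("inheres_in", "GO:0048869")))),
    # APO:0000094 is union-defined (see fixture_union_table()); the
    # OBO subset cannot express unions, so it carries no
    # intersection_of here
    tm("APO:0000094", "metabolism and growth", ob, "APO:0000017"),
    tm("APO:0000024", "budding", ob, "APO:0000017",
       eq = list(genus = "PATO:0000001",
                 diff = list(c("inheres_in", "GO:0007114")))),
    tm("APO:0000253", "cell cycle progression", ob, "APO:0000017",
       eq = list(genus = "PATO:0001236",
                 diff = list(c("inheres_in", "GO:0022402")))),
    tm("APO:0000300", "G1 phase progression", ob, "APO:0000253",
       eq = list(genus = "PATO:0001236",
                 diff = list(c("inheres_in", "GO:0000080")))),  # synthetic id
    tm("APO:0000303", "autophagy", ob, "APO:0000017",
       eq = list(genus = "PATO:0000001",
                 diff = list(c("inheres_in", "GO:0006914")))),  # synthetic id
    tm("APO:0000147", "heat sensitivity", ob, "APO:0000017",
       eq = list(genus = "PATO:0001457",
                 diff = list(c("inheres_in", "GO:0009408")))),
    tm("APO:0000087", "resistance to chemicals", ob, "APO:0000017",
       eq = list(genus = "PATO:0001457",
                 diff = list(c("inheres_in", "GO:0042221"),
                             c("towards", "CHEBI:37577")))),
    tm("APO:0000090", "metal resistant", ob, "APO:0000017",
       eq = list(genus = "PATO:0001457",
                 diff = list(c("inheres_in", "GO:0010038")))),
    tm("APO:0000089", "ionic stress resistance", ob, "APO:0000017",
       eq = list(genus = "PATO:0001457",
                 diff = list(c("inheres_in", "GO:0042221")))),  # synthetic id
    tm("APO:0000310", "protein kinase activity phenotype", ob,
       "APO:0000017",
       eq = list(genus = "PATO:0000001",
                 diff = list(c("inheres_in", "GO:0016301")))),  # synthetic id
    tm("APO:0000311", "hydrolase activity phenotype", ob, "APO:0000017",
       eq = list(genus = "PATO:0000001",
                 diff = list(c("inheres_in", "GO:0016787")))),  # synthetic id
    # qualifiers
    tm("APO:0000002", "abnormal", ql, "APO:0000015"),
    tm("APO:0000003", "decreased", ql, "APO:0000015"),  # synthetic id
    tm("APO:0000004", "increased", ql, "APO:0000015"),
    tm("APO:0000005", "absent", ql, "APO:0000015"),
    tm("APO:0000250", "arrested", ql, "APO:0000015")
  )
}

#' Build the mini-ontology fixture catalog
#'
#' Deterministic in-memory mini versions of GO, PATO, ChEBI and APO
#' covering every class the worked examples use, with is_a/part_of
#' edges mirroring the public ontologies. Mini-APO exposes the four
#' top-level hierarchies (observable, qualifier, experiment type,
#' mutant type). The union table carries the one union-defined
#' observable (metabolism and growth covers cellular metabolic process
#' or cellular growth).
#'
#' @return A `fixture_catalog`: list with `mini_go`, `mini_pato`,
#'   `mini_chebi`, `mini_apo` (ontologies), `unions` (data frame
#'   `term_id`, `quality`, `bearers`), and `merged` (all four merged).
#' @export
build_mini_ontologies <- function() {
  mini_go <- ontology_from_terms(mini_go_terms())
  mini_pato <- ontology_from_terms(mini_pato_terms())
  mini_chebi <- ontology_from_terms(mini_chebi_terms())
  mini_apo <- ontology_from_terms(mini_apo_terms())
  unions <- data.frame(
    term_id = "APO:0000094",
    quality = "PATO:0000001",
    bearers = "GO:0044237|GO:0016049",
    stringsAsFactors = FALSE
  )
  merged <- merge_ontologies(mini_apo, mini_go, mini_pato, mini_chebi)
  structure(
    list(mini_go = mini_go, mini_pato = mini_pato,
         mini_chebi = mini_chebi, mini_apo = mini_apo,
         unions = unions, merged = merged),
    class = "fixture_catalog"
  )
}

#' Roots of an ontology
#'
#' Terms with no is_a parent; mini-APO has exactly the four top-level
#' hierarchies.
#' @param ontology An `ontology`.
#' @return Sorted character vector of root CURIEs.
#' @export
ontology_roots <- function(ontology) {
  ids <- names(ontology$terms)
  sort(ids[vapply(ontology$terms, function(t) length(t$is_a) == 0L,
                  logical(1))], method = "radix")
}

#' Curated example annotation sets
#'
#' The worked-example records: the three phenotype annotations of
#' genotype S000029075 (a conditional cdc28 mutant: heat sensitivity
#' increased, budding absent, cell cycle progression arrested), the
#' S000000649 triple (ionic stress resistance decreased towards sodium
#' chloride), an arrested G1-phase-progression record for CLN3 whose
#' phenotype-derived G1-phase class is missing from CLN3's GO
#' annotations (the novel-candidate scenario), and an autophagy-absent
#' record (the cross-species classification demo). Genotype and gene
#' ids other than the published S000029075/S000000649/S000029048 are
#' synthetic.
#'
#' @return For `example_phenotype_annotations()` a data frame shaped
#'   like [read_phenotype_annotations()] output; for
#'   `example_gene_go_annotations()` a gene-GO data frame.
#' @export
example_phenotype_annotations <- function() {
  data.frame(
    genotype_id = c("S000029075", "S000029075", "S000029075",
                    "S000000649", "S000031234", "S000029048"),
    gene_id = c("CDC28", "CDC28", "CDC28", "ENA1", "CLN3", "ATG1"),
    observable = c("APO:0000147", "APO:0000024", "APO:0000253",
                   "APO:0000089", "APO:0000300", "APO:0000303"),
    qualifier = c("APO:0000004", "APO:0000005", "APO:0000250",
                  "APO:0000003", "APO:0000250", "APO:0000005"),
    chemical = c(NA, NA, NA, "CHEBI:26710", NA, NA),
    condition = c("conditional mutant", "conditional mutant",
                  "conditional mutant", "", "", ""),
    stringsAsFactors = FALSE
  )
}

#' @rdname example_phenotype_annotations
#' @export
example_gene_go_annotations <- function() {
  data.frame(
    gene_id = c("CDC28", "CDC28", "CLN3", "CLN3", "ENA1", "ATG1"),
    go_id = c("GO:0007049", "GO:0016301", "GO:0016301", "GO:0005634",
              "GO:0005215", "GO:0016301"),
    aspect = c("P", "F", "F", "C", "F", "F"),
    stringsAsFactors = FALSE
  )
}

#' A synthetic cross-species phenotype mini-ontology
#'
#' Stands in for a phenotype ontology of another species whose classes
#' carry the same style of EQ definitions: once both ontologies are
#' loaded, a yeast phenotype expression classifies under the foreign
#' ontology's defined classes. Entirely synthetic (XPO prefix).
#'
#' @return An `ontology` with two EQ-defined classes: abnormal
#'   autophagy and abnormal cellular process.
#' @export
build_cross_species_demo <- function() {
  ontology_from_terms(list(
    tm("XPO:0000001", "abnormal autophagy (synthetic)", "observable",
       eq = list(genus = "PATO:0000001",
                 diff = list(c("inheres_in", "GO:0006914")))),
    tm("XPO:0000002", "abnormal cellular process (synthetic)",
       "observable",
       eq = list(genus = "PATO:0000001",
                 diff = list(c("inheres_in", "GO:0009987"))))
  ))
}

## ---- synthetic recovery benchmark ------------------------------------

# per-bearer term pools for the benchmark generator; "related" holds
# the bearer itself plus every ancestor/descendant in the mini-GO
# is_a+part_of closure, "decoy" same-namespace classes that are neither
benchmark_pools <- function() {
  list(
    observables = list(
      P = c("APO:0000023", "APO:0000253", "APO:0000024"),
      C = c("APO:0000053", "APO:0000301"),
      F = c("APO:0000310", "APO:0000311")
    ),
    qualifiers = c(P = "APO:0000250", C = "APO:0000004",
                   F = "APO:0000004"),
    bearers = c(
      "APO:0000023" = "GO:0048869", "APO:0000253" = "GO:0022402",
      "APO:0000024" = "GO:0007114", "APO:0000053" = "GO:0005618",
      "APO:0000301" = "GO:0005634", "APO:0000310" = "GO:0016301",
      "APO:0000311" = "GO:0016787"
    ),
    related = list(
      "GO:0048869" = c("GO:0048869", "GO:0030154", "GO:0009987",
                       "GO:0008150"),
      "GO:0022402" = c("GO:0022402", "GO:0000080", "GO:0031576",
                       "GO:0007049", "GO:0009987", "GO:0008150"),
      "GO:0007114" = c("GO:0007114", "GO:0009987", "GO:0008150"),
      "GO:0005618" = c("GO:0005618", "GO:0009277", "GO:0110165",
                       "GO:0005575", "GO:0005623"),
      "GO:0005634" = c("GO:0005634", "GO:0110165", "GO:0005575"),
      "GO:0016301" = c("GO:0016301", "GO:0004674", "GO:0016740",
                       "GO:0003824", "GO:0003674"),
      "GO:0016787" = c("GO:0016787", "GO:0003824", "GO:0003674")
    ),
    decoys = list(
      "GO:0048869" = c("GO:0009408", "GO:0042221", "GO:0010038",
                       "GO:0050896", "GO:0008152"),
      "GO:0022402" = c("GO:0009408", "GO:0042221", "GO:0010038",
                       "GO:0050896", "GO:0008152"),
      "GO:0007114" = c("GO:0009408", "GO:0042221", "GO:0010038",
                       "GO:0050896", "GO:0008152"),
      "GO:0005618" = c("GO:0005634", "GO:0005739", "GO:0005886"),
      "GO:0005634" = c("GO:0005618", "GO:0009277", "GO:0005739",
                       "GO:0005886"),
      "GO:0016301" = c("GO:0016787", "GO:0005215"),
      "GO:0016787" = c("GO:0016301", "GO:0004674", "GO:0005215")
    )
  )
}

with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(),
                      inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(code)
}

#' Simulate a recovery benchmark with a planted recovery rate
#'
#' Each simulated gene receives one phenotype annotation per GO aspect
#' (a process, a component and a function observable drawn from fixed
#' pools) and two GO annotations per aspect. Independently for every GO
#' annotation line, with probability `planted_rate` its term is drawn
#' from the bearer's hand-curated ancestor/descendant set (recoverable
#' under the ancestor matching rule), otherwise from a same-namespace
#' decoy set that is neither an ancestor nor a descendant of any of the
#' gene's phenotype-derived terms. The realized plant decisions are
#' recorded as ground truth, so pipeline recovery can be checked for
#' exact agreement; regeneration with the same seed is byte-identical.
#'
#' @param n_genes Number of genes (>= 1).
#' @param planted_rate Probability in `[0, 1]` that a GO annotation
#'   line is recoverable.
#' @param seed Integer seed.
#' @return A `synthetic_benchmark`: list with `phenotypes` (annotation
#'   data frame), `goa` (gene-GO data frame), `expected` (data frame
#'   `aspect`, `recovered`, `total`, `percentage`), and the call
#'   parameters.
#' @export
simulate_benchmark <- function(n_genes, planted_rate, seed) {
  if (!is.numeric(planted_rate) || planted_rate < 0 ||
      planted_rate > 1) {
    stop("planted_rate must be in [0, 1]", call. = FALSE)
  }
  if (n_genes < 1L) stop("n_genes must be >= 1", call. = FALSE)
  pools <- benchmark_pools()
  aspects <- c("P", "F", "C")
  lines_per_aspect <- 2L

  with_local_seed(seed, {
    ph <- list()
    goa <- list()
    planted <- stats::setNames(integer(3), aspects)
    total <- stats::setNames(integer(3), aspects)
    for (i in seq_len(n_genes)) {
      gene <- sprintf("G%04d", i)
      genotype <- sprintf("S%09d", 900000000L + i)
      for (a in aspects) {
        obs <- sample(pools$observables[[a]], 1L)
        bearer <- pools$bearers[[obs]]
        ph[[length(ph) + 1L]] <- data.frame(
          genotype_id = genotype, gene_id = gene, observable = obs,
          qualifier = unname(pools$qualifiers[[a]]),
          chemical = NA_character_, condition = "",
          stringsAsFactors = FALSE
        )
        flags <- stats::rbinom(lines_per_aspect, 1L, planted_rate) == 1L
        n_rec <- sum(flags)
        n_dec <- lines_per_aspect - n_rec
        terms <- character(lines_per_aspect)
        if (n_rec > 0L) {
          terms[flags] <- sample(pools$related[[bearer]], n_rec)
        }
        if (n_dec > 0L) {
          terms[!flags] <- sample(pools$decoys[[bearer]], n_dec)
        }
        goa[[length(goa) + 1L]] <- data.frame(
          gene_id = gene, go_id = terms, aspect = a,
          stringsAsFactors = FALSE
        )
        planted[a] <- planted[a] + n_rec
        total[a] <- total[a] + lines_per_aspect
      }
    }
    expected <- data.frame(
      aspect = aspects,
      recovered = as.integer(planted),
      total = as.integer(total),
      percentage = ifelse(total > 0, 100 * planted / total, NA_real_),
      stringsAsFactors = FALSE
    )
    structure(
      list(phenotypes = do.call(rbind, ph), goa = do.call(rbind, goa),
           expected = expected, n_genes = n_genes,
           planted_rate = planted_rate, seed = seed),
      class = "synthetic_benchmark"
    )
  })
}

## ---- writing fixtures to disk ----------------------------------------

#' Write annotation tables in the package's TSV dialects
#'
#' @param annotations Data frame shaped like
#'   [read_phenotype_annotations()] output.
#' @param goa Data frame shaped like [read_gene_go_annotations()]
#'   output.
#' @param path Optional output file.
#' @return The TSV text (invisibly when `path` is given).
#' @export
write_phenotype_annotations <- function(annotations, path = NULL) {
  df <- data.frame(
    genotype_id = annotations$genotype_id,
    gene_id = annotations$gene_id,
    observable_id = annotations$observable,
    qualifier_id = annotations$qualifier,
    chemical_id = ifelse(is.na(annotations$chemical), "",
                         annotations$chemical),
    condition = annotations$condition,
    stringsAsFactors = FALSE
  )
  write_tsv_lines(df, path)
}

#' @rdname write_phenotype_annotations
#' @export
write_gene_go_annotations <- function(goa, path = NULL) {
  write_tsv_lines(goa[, c("gene_id", "go_id", "aspect")], path)
}

#' Write the full fixture set to a directory
#'
#' Emits the four mini-ontology OBO files, the union table, the curated
#' example annotation TSVs, and a seeded benchmark (phenotypes, GOA and
#' expected per-aspect recovery).
#'
#' @param dir Output directory (created if needed).
#' @param seed Benchmark seed.
#' @param n_genes,planted_rate Benchmark parameters.
#' @return Invisibly, the vector of files written.
#' @export
write_fixtures <- function(dir, seed = 42L, n_genes = 200L,
                           planted_rate = 0.5) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cat_fix <- build_mini_ontologies()
  files <- character(0)
  for (nm in c("mini_go", "mini_pato", "mini_chebi", "mini_apo")) {
    p <- file.path(dir, paste0(gsub("_", "-", nm), ".obo"))
    write_obo(cat_fix[[nm]], p)
    files <- c(files, p)
  }
  p <- file.path(dir, "unions.tsv")
  write_tsv_lines(cat_fix$unions, p)
  files <- c(files, p)
  p <- file.path(dir, "example-phenotypes.tsv")
  write_phenotype_annotations(example_phenotype_annotations(), p)
  files <- c(files, p)
  p <- file.path(dir, "example-goa.tsv")
  write_gene_go_annotations(example_gene_go_annotations(), p)
  files <- c(files, p)
  bench <- simulate_benchmark(n_genes, planted_rate, seed)
  p <- file.path(dir, "benchmark-phenotypes.tsv")
  write_phenotype_annotations(bench$phenotypes, p)
  files <- c(files, p)
  p <- file.path(dir, "benchmark-goa.tsv")
  write_gene_go_annotations(bench$goa, p)
  files <- c(files, p)
  p <- file.path(dir, "benchmark-expected.tsv")
  write_tsv_lines(bench$expected, p)
  files <- c(files, p)
  invisible(files)
}
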