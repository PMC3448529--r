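## Phene-pattern compiler: EQ definitions and phenotype annotations
## become class expressions. One pattern per observable category:
##
##   object-morphology  phenotype-of some (has-part some
##                        (bearer and has-quality some Q))
##   temporal-object    as above, with "during some stage" appended
##                        inside the bearer conjunction
##   process            phenotype-of some (has-part some
##                        (part-of some bearer and has-quality some Q))
##   disposition        like object-morphology (the quality already
##                        inheres directly in the affected process)
##   relational         disposition with "towards some chemical" inside
##                        the quality conjunction
##
## The part-of wrapper in the process pattern is what lets GO's process
## hierarchy drive inferred restructuring of the observable hierarchy.

PATO_QUALITY_ROOT <- "PATO:0000001"
PATO_PROCESS_QUALITY <- "PATO:0001236"
PATO_OBJECT_QUALITY <- "PATO:0001241"

#' Assign a phene-pattern category to an EQ definition
#'
#' Category rules, applied in order: a `towards` differentium makes the
#' definition *relational*; a `during` differentium *temporal-object*;
#' a quality inside PATO's process-quality branch (\eqn{\sqsubseteq}
#' `PATO:0001236`, e.g. sensitivity of a process, arrested)
#' *disposition* -- the quality inheres directly in the affected
#' process, so no `part-of` wrapper is added; otherwise a bearer in the
#' `biological_process` / `molecular_function` namespace gives the
#' *process* pattern and anything else (cellular components, cells) the
#' *object-morphology* pattern. Per-term overrides win over the rules.
#'
#' @param def An [eq_definition()].
#' @param ontologies A merged `ontology` (used for the PATO hierarchy
#'   and bearer namespaces).
#' @param overrides Optional named character vector mapping term CURIEs
#'   to categories; see [read_category_overrides()].
#' @param term_id CURIE of the term being categorized (for overrides
#'   and error messages).
#' @return One of `"object-morphology"`, `"temporal-object"`,
#'   `"process"`, `"disposition"`, `"relational"`.
#' @export
assign_pattern_category <- function(def, ontologies, overrides = NULL,
                                    term_id = NULL) {
  if (!is.null(term_id) && !is.null(overrides) &&
      term_id %in% names(overrides)) {
    cat_ok <- c("object-morphology", "temporal-object", "process",
                "disposition", "relational")
    ov <- overrides[[term_id]]
    if (!ov %in% cat_ok) {
      stop("invalid category override '", ov, "' for ", term_id,
           call. = FALSE)
    }
    return(ov)
  }
  if (!is.na(def$towards)) return("relational")
  if (!is.na(def$during)) return("temporal-object")
  anc <- isa_ancestors_self(def$quality, ontologies)
  if (PATO_PROCESS_QUALITY %in% anc) return("disposition")
  ns <- term_namespace(def$bearer, ontologies)
  if (!is.na(ns) && ns %in% c("biological_process", "molecular_function")) {
    return("process")
  }
  "object-morphology"
}

term_namespace <- function(curie, ontologies) {
  t <- ontologies$terms[[curie]]
  if (is.null(t)) NA_character_ else t$namespace
}

# is_a ancestors including the start class; plain BFS over the asserted
# is_a edges (small ontologies; no memoization needed at this scale)
isa_ancestors_self <- function(curie, ontologies) {
  seen <- character(0)
  queue <- curie
  while (length(queue)) {
    x <- queue[[1]]
    queue <- queue[-1]
    if (x %in% seen) next
    seen <- c(seen, x)
    t <- ontologies$terms[[x]]
    if (!is.null(t)) queue <- c(queue, t$is_a)
  }
  seen
}

build_quality_expr <- function(quality, towards = NA_character_,
                               modifier = NA_character_) {
  parts <- list(ce_atom(quality))
  if (!is.na(modifier)) {
    parts <- c(parts, list(ce_some(modifier, ce_atom(PATO_NORMAL))))
  }
  if (!is.na(towards)) {
    parts <- c(parts, list(ce_some("towards", ce_atom(towards))))
  }
  if (length(parts) == 1L) parts[[1]] else ce_and(parts)
}

build_pattern_expr <- function(category, bearer, quality_expr,
                               during = NA_character_,
                               flat = FALSE, omit_has_part = FALSE) {
  bearer_expr <- if (category == "process") {
    ce_some("part-of", ce_atom(bearer))
  } else {
    ce_atom(bearer)
  }
  hq <- ce_some("has-quality", quality_expr)
  if (omit_has_part) {
    # the printed Resistance-to-chemicals equivalence attaches the
    # quality directly under phenotype-of, without a has-part wrapper
    inner <- ce_and(bearer_expr, hq)
    return(ce_some("phenotype-of", inner))
  }
  if (flat) {
    # paper layout for formalized annotations: has-quality is a sibling
    # of has-part rather than nested inside its filler
    parts <- list(ce_some("has-part", bearer_expr), hq)
    if (!is.na(during)) {
      parts <- c(parts, list(ce_some("during", ce_atom(during))))
    }
    return(ce_some("phenotype-of", ce_and(parts)))
  }
  parts <- list(bearer_expr, hq)
  if (!is.na(during)) {
    parts <- c(parts, list(ce_some("during", ce_atom(during))))
  }
  ce_some("phenotype-of", ce_some("has-part", ce_and(parts)))
}

# Equivalences the paper prints in a non-uniform layout, reproduced
# when verbatim = TRUE. Currently one flagged exception.
VERBATIM_OMIT_HAS_PART <- "APO:0000087"

#' Compile an EQ definition into a class expression
#'
#' Applies the phene pattern for the term's category (see
#' [assign_pattern_category()]). With `verbatim = TRUE` the flagged
#' exceptions keep their published layout (`APO:0000087` omits the
#' `has-part` wrapper); the default normalizes every term to the
#' uniform `has-part` form so subsumption behaves uniformly.
#'
#' @param term An `ontology_term` carrying an `intersection_of` EQ
#'   definition.
#' @param ontologies Merged `ontology` covering the quality, bearer and
#'   differentia classes.
#' @param verbatim Reproduce published layouts for flagged exceptions.
#' @param overrides Optional per-term category overrides.
#' @return A `class_expression`, with attribute `category`.
#' @examples
#' \dontrun{
#' apo <- build_mini_ontologies()
#' all <- merge_ontologies(apo$mini_apo, apo$mini_go, apo$mini_pato,
#'                         apo$mini_chebi)
#' render_expression(compile_definition(all$terms[["APO:0000053"]], all))
#' }
#' @export
compile_definition <- function(term, ontologies, verbatim = FALSE,
                               overrides = NULL) {
  def <- eq_definition(term)
  if (is.null(def)) {
    stop("term ", term$id, " has no EQ definition (no intersection_of)",
         call. = FALSE)
  }
  if (is.na(def$quality) || is.na(def$bearer)) {
    stop("term ", term$id, ": EQ definition missing quality or bearer",
         call. = FALSE)
  }
  category <- assign_pattern_category(def, ontologies, overrides, term$id)
  q <- build_quality_expr(def$quality, towards = def$towards)
  expr <- build_pattern_expr(
    category, def$bearer, q, during = def$during,
    omit_has_part = verbatim && term$id %in% VERBATIM_OMIT_HAS_PART
  )
  attr(expr, "category") <- category
  expr
}

#' Compile a union (either/or) observable definition
#'
#' Some observables cover a disjunction of processes (metabolism *and
#' growth* covers cellular metabolic process or cellular growth). The
#' conjunctive expression language has no union node, so each disjunct
#' compiles through the process pattern and is registered as a
#' *sufficient condition* (`expression` \eqn{\sqsubseteq} term) rather
#' than an equivalence. With a single bearer this degenerates to the
#' ordinary equivalence case.
#'
#' @param term_id CURIE of the defined observable.
#' @param bearers Character vector of bearer CURIEs (the disjuncts).
#' @param quality PATO quality CURIE shared by all disjuncts.
#' @param ontologies Merged `ontology`.
#' @param overrides Optional category overrides.
#' @return A list of class expressions, one per bearer.
#' @export
compile_union_definition <- function(term_id, bearers, quality,
                                     ontologies, overrides = NULL) {
  stopifnot(length(bearers) >= 1L)
  lapply(bearers, function(b) {
    def <- structure(list(quality = quality, bearer = b,
                          during = NA_character_,
                          towards = NA_character_),
                     class = "eq_definition")
    category <- assign_pattern_category(def, ontologies, overrides,
                                        term_id)
    expr <- build_pattern_expr(category, b, build_quality_expr(quality))
    attr(expr, "category") <- category
    expr
  })
}

## ---- qualifier mapping ------------------------------------------------

#' Qualifier mapping table
#'
#' Maps APO qualifier classes to a formalization strategy: either a
#' PATO substitution (the qualifier's PATO equivalent replaces the
#' observable's quality, e.g. arrested to `PATO:0000297`) or a
#' magnitude modifier (the quality is refined with
#' `increased-/decreased-in-magnitude-relative-to some PATO:0000461`).
#' The default table ships at
#' `system.file("extdata", "qualifier_map.tsv", package = "phenoeq")`
#' and is an editable three-column TSV
#' (`qualifier_id`, `strategy` in `pato`/`modifier`, `value`).
#'
#' @param path Path to a qualifier TSV.
#' @return A data frame with columns `qualifier_id`, `strategy`,
#'   `value`.
#' @export
read_qualifier_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          comment.char = "!", stringsAsFactors = FALSE)
  need <- c("qualifier_id", "strategy", "value")
  if (!identical(names(df), need)) {
    stop("qualifier table must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  bad <- !df$strategy %in% c("pato", "modifier")
  if (any(bad)) {
    stop("unknown qualifier strategy: ",
         paste(unique(df$strategy[bad]), collapse = ", "), call. = FALSE)
  }
  df
}

#' @rdname read_qualifier_table
#' @export
default_qualifier_table <- function() {
  read_qualifier_table(system.file("extdata", "qualifier_map.tsv",
                                   package = "phenoeq", mustWork = TRUE))
}

#' Look up a qualifier's formalization strategy
#'
#' @param qualifier APO qualifier CURIE.
#' @param table A qualifier table, see [read_qualifier_table()].
#' @return A list with `strategy` (`"pato"` or `"modifier"`) and
#'   `value` (a PATO CURIE, or a magnitude-modifier relation name).
#' @export
map_qualifier <- function(qualifier, table = default_qualifier_table()) {
  i <- match(qualifier, table$qualifier_id)
  if (is.na(i)) {
    stop("unmapped qualifier ", qualifier, "; known qualifiers: ",
         paste(table$qualifier_id, collapse = ", "), call. = FALSE)
  }
  list(strategy = table$strategy[i], value = table$value[i])
}

#' Per-term category overrides
#'
#' Two-column TSV (`term_id`, `category`) overriding
#' [assign_pattern_category()]'s rules. The shipped default table is
#' empty: the rules cover every fixture term.
#'
#' @param path Path to the TSV.
#' @return Named character vector (possibly empty).
#' @export
read_category_overrides <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          comment.char = "!", stringsAsFactors = FALSE)
  if (!identical(names(df), c("term_id", "category"))) {
    stop("category override table must have columns term_id, category",
         call. = FALSE)
  }
  stats::setNames(df$category, df$term_id)
}

## ---- annotation formalization ----------------------------------------

#' Formalize a genotype-phenotype annotation
#'
#' Starts from the observable's EQ definition and applies the
#' qualifier: a PATO substitution replaces the quality atom; a
#' magnitude modifier wraps it as
#' `(quality and modifier some PATO:0000461)`. A triple's chemical
#' attaches as `towards` on the quality (replacing any `towards` class
#' in the observable's own definition with the more specific chemical
#' observed). The result is compiled through the observable's pattern
#' category. With `verbatim = TRUE` the published layout for annotation
#' expressions is used: `has-quality` as a sibling of `has-part`, and
#' triples keep the quality bare (no magnitude modifier), as in the
#' published S000000649 listing.
#'
#' @param ann One row of [read_phenotype_annotations()] output (or a
#'   list with fields `observable`, `qualifier`, optional `chemical`).
#' @param ontologies Merged `ontology` containing the observable's EQ
#'   definition.
#' @param table Qualifier table.
#' @param verbatim Reproduce the published annotation layout.
#' @param overrides Optional category overrides.
#' @return A `class_expression` with attribute `category`.
#' @export
formalize_annotation <- function(ann, ontologies,
                                 table = default_qualifier_table(),
                                 verbatim = FALSE, overrides = NULL) {
  term <- ontologies$terms[[ann$observable]]
  if (is.null(term) || is.null(term$intersection_of)) {
    stop("observable ", ann$observable,
         " has no EQ definition; annotation is unformalizable",
         call. = FALSE)
  }
  def <- eq_definition(term)
  q <- map_qualifier(ann$qualifier, table)
  quality <- def$quality
  modifier <- NA_character_
  if (q$strategy == "pato") {
    quality <- q$value
  } else {
    modifier <- q$value
  }
  chemical <- if (!is.null(ann$chemical) && !is.na(ann$chemical)) {
    ann$chemical
  } else {
    def$towards
  }
  if (verbatim && !is.na(chemical)) {
    modifier <- NA_character_  # published triples leave the quality bare
  }
  category <- assign_pattern_category(def, ontologies, overrides,
                                      term$id)
  qe <- build_quality_expr(quality, towards = chemical,
                           modifier = modifier)
  expr <- build_pattern_expr(category, def$bearer, qe,
                             during = def$during, flat = verbatim)
  attr(expr, "category") <- category
  expr
}

#' Combine a genotype's phenotype expressions
#'
#' A genotype with several phenotype annotations is described by the
#' class intersection of the individual phenotype expressions. The
#' result is canonicalized; a single expression is returned unchanged.
#'
#' @param exprs Non-empty list of class expressions.
#' @return A `class_expression`.
#' @export
combine_genotype <- function(exprs) {
  if (length(exprs) == 0L) {
    stop("combine_genotype() needs at least one expression",
         call. = FALSE)
  }
  if (length(exprs) == 1L) {
    return(exprs[[1]])
  }
  canonicalize_expression(ce_and(exprs))
}

#' Compile every EQ-defined term of an ontology set
#'
#' @param ontologies Merged `ontology`.
#' @param unions Optional union table: a data frame with columns
#'   `term_id`, `quality`, `bearers` (bearer CURIEs joined by `|`);
#'   listed terms get sufficient conditions instead of an equivalence.
#' @param verbatim,overrides Passed to [compile_definition()].
#' @return A list with `equivalences` (named list CURIE to expression)
#'   and `sufficient` (named list CURIE to list of expressions).
#' @export
compile_ontology_definitions <- function(ontologies, unions = NULL,
                                         verbatim = FALSE,
                                         overrides = NULL) {
  equivalences <- list()
  sufficient <- list()
  union_ids <- if (is.null(unions)) character(0) else unions$term_id
  for (id in sort(names(ontologies$terms), method = "radix")) {
    t <- ontologies$terms[[id]]
    if (id %in% union_ids) next
    if (is.null(t$intersection_of) || isTRUE(t$is_obsolete)) next
    equivalences[[id]] <- compile_definition(t, ontologies,
                                             verbatim = verbatim,
                                             overrides = overrides)
  }
  if (!is.null(unions)) {
    for (k in seq_len(nrow(unions))) {
      id <- unions$term_id[k]
      bearers <- strsplit(unions$bearers[k], "|", fixed = TRUE)[[1]]
      exprs <- compile_union_definition(id, bearers, unions$quality[k],
                                        ontologies, overrides)
      if (length(exprs) == 1L) {
        equivalences[[id]] <- exprs[[1]]
      } else {
        sufficient[[id]] <- exprs
      }
    }
  }
  list(equivalences = equivalences, sufficient = sufficient)
}

#' Read a union-definition table
#'
#' @param path TSV with columns `term_id`, `quality`, `bearers`
#'   (pipe-separated CURIEs).
#' @return The table as a data frame.
#' @export
read_union_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          comment.char = "!", stringsAsFactors = FALSE)
  if (!identical(names(df), c("term_id", "quality", "bearers"))) {
    stop("union table must have columns term_id, quality, bearers",
         call. = FALSE)
  }
  df
}
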