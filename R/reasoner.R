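## Structural subsumption over the conjunctive-existential expression
## language. subsumes(G, S) holds iff there is a homomorphism from G's
## description tree into S's, where
##   * an atom A matches any node carrying an atom B with B is_a* A;
##   * Some(r, F) matches along a single same-relation edge for plain
##     relations;
##   * Some(part-of, F) matches along chains of part-of / is_a edges
##     (transitive), including the empty chain (reflexive);
##   * has-part absorbs a following part-of chain (the property chain
##     has-part o part-of -> has-part);
##   * And requires all operands matched at the same node.
## Edges come both from the expression itself and from the ontology
## (a term's relationship clauses, inherited up its is_a ancestors).
## Atoms carrying an equivalence axiom are unfolded before matching,
## with cycle detection (definitional cycles are authoring errors).

#' Build an axiom set for the reasoner
#'
#' Bundles the ontology graph (is_a closure, part_of and other
#' relationship edges), compiled equivalence axioms, and sufficient
#' conditions into the structure the reasoning operations consume.
#' A CURIE may not carry both an equivalence and sufficient conditions.
#'
#' @param ontologies Merged `ontology`.
#' @param equivalences Named list CURIE to `class_expression`.
#' @param sufficient Named list CURIE to list of `class_expression`
#'   (each a sufficient condition for the named class; for union-defined
#'   classes the disjuncts are treated as jointly exhaustive when the
#'   class appears on the specific side of a class-level subsumption).
#' @return An object of class `axiom_set`.
#' @seealso [compile_ontology_definitions()] which produces the
#'   `equivalences` / `sufficient` lists.
#' @export
build_axioms <- function(ontologies, equivalences = list(),
                         sufficient = list()) {
  both <- intersect(names(equivalences), names(sufficient))
  if (length(both)) {
    stop("CURIE(s) with both an equivalence and sufficient conditions: ",
         paste(both, collapse = ", "), call. = FALSE)
  }
  isa <- list()
  rels <- list()
  for (t in ontologies$terms) {
    isa[[t$id]] <- t$is_a
    if (length(t$relationships)) {
      rels[[t$id]] <- lapply(t$relationships, function(r) {
        list(relation = norm_relation_name(r$relation),
             target = r$target)
      })
    }
  }
  structure(
    list(ontologies = ontologies, isa = isa, rels = rels,
         equivalences = equivalences, sufficient = sufficient,
         cache = new.env(parent = emptyenv())),
    class = "axiom_set"
  )
}

ax_ancestors_self <- function(curie, axioms) {
  key <- paste0("anc:", curie)
  hit <- axioms$cache[[key]]
  if (!is.null(hit)) return(hit)
  seen <- character(0)
  queue <- curie
  while (length(queue)) {
    x <- queue[[1]]
    queue <- queue[-1]
    if (x %in% seen) next
    seen <- c(seen, x)
    queue <- c(queue, axioms$isa[[x]])
  }
  axioms$cache[[key]] <- seen
  seen
}

# atoms present directly at a node (the node itself if an atom, or the
# atom operands of a conjunction)
node_atoms <- function(node) {
  if (inherits(node, "ce_atom")) return(node$curie)
  if (inherits(node, "ce_and")) {
    ats <- Filter(function(o) inherits(o, "ce_atom"), node$operands)
    return(vapply(ats, `[[`, character(1), "curie"))
  }
  character(0)
}

# expression-level edges with a given relation at a node
node_expr_edges <- function(node, relation) {
  pick <- function(o) {
    inherits(o, "ce_some") && o$relation == relation
  }
  if (inherits(node, "ce_some")) {
    if (node$relation == relation) return(list(node$filler))
    return(list())
  }
  if (inherits(node, "ce_and")) {
    lapply(Filter(pick, node$operands), `[[`, "filler")
  } else {
    list()
  }
}

# ontology-level edges: relationship clauses of a node's atoms and of
# their is_a ancestors (a term inherits restrictions from superclasses)
node_onto_edges <- function(node, relation, axioms) {
  out <- character(0)
  for (a in node_atoms(node)) {
    for (b in ax_ancestors_self(a, axioms)) {
      for (r in axioms$rels[[b]]) {
        if (r$relation == relation) out <- c(out, r$target)
      }
    }
  }
  unique(out)
}

# unfold one level of equivalence on an atom node; returns NULL when
# the atom carries no equivalence
atom_unfolding <- function(node, axioms) {
  if (!inherits(node, "ce_atom")) return(NULL)
  axioms$equivalences[[node$curie]]
}

#' Structural subsumption between class expressions
#'
#' `TRUE` iff `general` subsumes `specific` (every instance of
#' `specific` is an instance of `general`) under the structural
#' EL-style semantics described above. Total: never errors on
#' well-formed expressions; reflexive and transitive.
#'
#' @param general,specific Class expressions.
#' @param axioms An [build_axioms()] result.
#' @return `TRUE` or `FALSE`.
#' @export
subsumes <- function(general, specific, axioms) {
  ce_satisfies(specific, general, axioms,
               unfold_guard = character(0))
}

ce_satisfies <- function(node, general, axioms, unfold_guard) {
  if (inherits(general, "ce_and")) {
    for (g in general$operands) {
      if (!ce_satisfies(node, g, axioms, unfold_guard)) return(FALSE)
    }
    return(TRUE)
  }
  if (inherits(general, "ce_atom")) {
    target <- general$curie
    for (a in node_atoms(node)) {
      if (target %in% ax_ancestors_self(a, axioms)) return(TRUE)
    }
    # a defined class on the general side: satisfying its definition
    # (or any sufficient condition) implies membership
    if (!target %in% unfold_guard) {
      guard <- c(unfold_guard, target)
      eq <- axioms$equivalences[[target]]
      if (!is.null(eq) &&
          ce_satisfies(node, eq, axioms, guard)) {
        return(TRUE)
      }
      for (s in axioms$sufficient[[target]]) {
        if (ce_satisfies(node, s, axioms, guard)) return(TRUE)
      }
    }
    return(other_side_unfold(node, general, axioms, unfold_guard))
  }
  # general is ce_some
  r <- general$relation
  filler <- general$filler
  if (r == "part-of") {
    return(partof_satisfies(node, filler, axioms, unfold_guard,
                            visited = character(0)))
  }
  if (r == "has-part") {
    for (w in c(node_expr_edges(node, "has-part"),
                lapply(node_onto_edges(node, "has-part", axioms),
                       ce_atom))) {
      if (partof_satisfies(w, filler, axioms, unfold_guard,
                           visited = character(0))) {
        return(TRUE)
      }
    }
    return(other_side_unfold(node, general, axioms, unfold_guard))
  }
  for (w in c(node_expr_edges(node, r),
              lapply(node_onto_edges(node, r, axioms), ce_atom))) {
    if (ce_satisfies(w, filler, axioms, unfold_guard)) return(TRUE)
  }
  other_side_unfold(node, general, axioms, unfold_guard)
}

# unfold an equivalence-defined atom on the specific side and retry
other_side_unfold <- function(node, general, axioms, unfold_guard) {
  if (inherits(node, "ce_atom")) {
    key <- paste0("spec:", node$curie)
    if (!key %in% unfold_guard) {
      for (a in ax_ancestors_self(node$curie, axioms)) {
        eq <- axioms$equivalences[[a]]
        if (!is.null(eq) &&
            ce_satisfies(eq, general, axioms, c(unfold_guard, key))) {
          return(TRUE)
        }
      }
    }
  } else if (inherits(node, "ce_and")) {
    for (op in node$operands) {
      if (inherits(op, "ce_atom") &&
          other_side_unfold(op, general, axioms, unfold_guard)) {
        return(TRUE)
      }
    }
  }
  FALSE
}

# Some(part-of, F): reflexive-transitive chain search over expression
# part-of edges and ontology part_of edges (is_a traversed freely)
partof_satisfies <- function(node, filler, axioms, unfold_guard,
                             visited) {
  if (ce_satisfies(node, filler, axioms, unfold_guard)) return(TRUE)
  for (w in node_expr_edges(node, "part-of")) {
    if (partof_satisfies(w, filler, axioms, unfold_guard, visited)) {
      return(TRUE)
    }
  }
  for (tcur in node_onto_edges(node, "part-of", axioms)) {
    if (tcur %in% visited) next
    if (partof_satisfies(ce_atom(tcur), filler, axioms, unfold_guard,
                         c(visited, tcur))) {
      return(TRUE)
    }
  }
  FALSE
}

## ---- class-level subsumption and classification ----------------------

class_disjuncts <- function(curie, axioms) {
  eq <- axioms$equivalences[[curie]]
  if (!is.null(eq)) return(list(eq))
  s <- axioms$sufficient[[curie]]
  if (!is.null(s)) return(s)
  NULL
}

# parent subsumes child at the class level: asserted is_a, or every
# disjunct of the child's definition is subsumed by some disjunct of
# the parent's (union definitions read as exhaustive covers)
class_subsumes <- function(parent, child, axioms) {
  if (parent == child) return(TRUE)
  if (parent %in% ax_ancestors_self(child, axioms)) return(TRUE)
  dc <- class_disjuncts(child, axioms)
  dp <- class_disjuncts(parent, axioms)
  if (is.null(dc) || is.null(dp)) return(FALSE)
  for (c_expr in dc) {
    ok <- FALSE
    for (p_expr in dp) {
      if (subsumes(p_expr, c_expr, axioms)) {
        ok <- TRUE
        break
      }
    }
    if (!ok) return(FALSE)
  }
  TRUE
}

#' Classify an expression under defined classes
#'
#' Finds the named classes whose definitions subsume an expression. A
#' class with sufficient conditions counts when any disjunct subsumes
#' the expression. The most-specific set contains the subsumers with no
#' other subsumer strictly below them; ties are returned sorted by
#' CURIE.
#'
#' @param expr A class expression.
#' @param axioms An [build_axioms()] result.
#' @param classes CURIEs to test; defaults to every class with an
#'   equivalence or sufficient conditions in `axioms`.
#' @return A list with `all` and `most_specific` (sorted character
#'   vectors).
#' @export
classify_expression <- function(expr, axioms,
                                classes = union(names(axioms$equivalences),
                                                names(axioms$sufficient))) {
  subsumers <- character(0)
  for (c in classes) {
    for (d in class_disjuncts(c, axioms)) {
      if (subsumes(d, expr, axioms)) {
        subsumers <- c(subsumers, c)
        break
      }
    }
  }
  subsumers <- sort(unique(subsumers), method = "radix")
  msc <- subsumers[vapply(subsumers, function(c) {
    !any(vapply(subsumers, function(d) {
      d != c && class_subsumes(c, d, axioms) &&
        !class_subsumes(d, c, axioms)
    }, logical(1)))
  }, logical(1))]
  list(all = subsumers, most_specific = msc)
}

#' Infer new hierarchy edges among defined classes
#'
#' Computes pairwise class-level subsumption among the defined classes,
#' keeps the pairs absent from the asserted is_a closure, and returns
#' their transitive reduction (with asserted edges available as
#' intermediate steps). These are the edges a reasoner adds to the
#' asserted observable hierarchy -- e.g. development and
#' metabolism-and-growth phenotypes fall under cellular-process
#' phenotypes once the process patterns over GO's hierarchy are in
#' place.
#'
#' @param axioms An [build_axioms()] result.
#' @param defined CURIEs to consider; defaults to every defined class.
#' @return Data frame with columns `child`, `parent`, sorted by child
#'   then parent.
#' @export
infer_hierarchy <- function(axioms,
                            defined = union(names(axioms$equivalences),
                                            names(axioms$sufficient))) {
  defined <- sort(unique(as.character(defined)), method = "radix")
  n <- length(defined)
  if (n == 0L) {
    return(data.frame(child = character(0), parent = character(0),
                      stringsAsFactors = FALSE))
  }
  inferred <- matrix(FALSE, n, n, dimnames = list(defined, defined))
  asserted <- matrix(FALSE, n, n, dimnames = list(defined, defined))
  for (c in defined) {
    anc <- ax_ancestors_self(c, axioms)
    for (p in defined) {
      if (p == c) next
      if (p %in% anc) {
        asserted[c, p] <- TRUE
      } else if (class_subsumes(p, c, axioms)) {
        inferred[c, p] <- TRUE
      }
    }
  }
  reach <- inferred | asserted
  keep <- inferred
  for (c in defined) {
    for (p in defined) {
      if (!inferred[c, p]) next
      for (m in defined) {
        if (m == c || m == p) next
        if (reach[c, m] && reach[m, p]) {
          keep[c, p] <- FALSE
          break
        }
      }
    }
  }
  idx <- which(keep, arr.ind = TRUE)
  out <- data.frame(child = defined[idx[, 1]],
                    parent = defined[idx[, 2]],
                    stringsAsFactors = FALSE)
  out[order(out$child, out$parent, method = "radix"), , drop = FALSE] ->
    out
  rownames(out) <- NULL
  out
}

## ---- qualifier / bearer consistency ----------------------------------

#' Check a quality/bearer combination for category consistency
#'
#' PATO distinguishes qualities of processes from qualities of material
#' objects; pairing a process quality with a cellular component (or an
#' object quality with a process or function) is a curation error this
#' check reports. The quality's category is read off the PATO hierarchy
#' (descendant of `PATO:0001236` = process quality, of `PATO:0001241` =
#' object quality); a quality under neither branch yields a warning and
#' the check is skipped.
#'
#' @param quality PATO CURIE.
#' @param bearer Entity CURIE (its namespace decides the bearer
#'   category).
#' @param ontologies Merged `ontology`.
#' @return A list with `status` (`"ok"`, `"violation"` or `"skipped"`),
#'   `quality_category`, `bearer_category`, and `message`.
#' @export
check_qualifier_consistency <- function(quality, bearer, ontologies) {
  anc <- isa_ancestors_self(quality, ontologies)
  qcat <- if (PATO_PROCESS_QUALITY %in% anc) {
    "process-quality"
  } else if (PATO_OBJECT_QUALITY %in% anc) {
    "object-quality"
  } else {
    NA_character_
  }
  if (is.na(qcat)) {
    warning("quality ", quality,
            " has no declared bearer category; check skipped",
            call. = FALSE)
    return(list(status = "skipped", quality_category = NA_character_,
                bearer_category = NA_character_,
                message = paste0("no category for ", quality)))
  }
  ns <- term_namespace(bearer, ontologies)
  bcat <- if (!is.na(ns) &&
              ns %in% c("biological_process", "molecular_function")) {
    "process"
  } else if (!is.na(ns) && ns %in% c("cellular_component", "cell")) {
    "object"
  } else {
    NA_character_
  }
  if (is.na(bcat)) {
    warning("bearer ", bearer, " has no usable namespace; check skipped",
            call. = FALSE)
    return(list(status = "skipped", quality_category = qcat,
                bearer_category = NA_character_,
                message = paste0("no namespace for ", bearer)))
  }
  bad <- (qcat == "process-quality" && bcat == "object") ||
    (qcat == "object-quality" && bcat == "process")
  if (bad) {
    list(status = "violation", quality_category = qcat,
         bearer_category = bcat,
         message = paste0(quality, " (", qcat, ") cannot inhere in ",
                          bearer, " (", bcat, " bearer)"))
  } else {
    list(status = "ok", quality_category = qcat, bearer_category = bcat,
         message = "consistent")
  }
}
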