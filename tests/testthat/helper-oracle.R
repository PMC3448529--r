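# Independent brute-force subsumption oracle. Instead of the package's
# recursive path-search matcher, it materializes an explicit
# description graph for the specific expression over the ontology,
# saturates the part-of edges (transitivity and the
# has-part o part-of -> has-part chain) to a fixpoint, and then
# enumerates homomorphisms of the general expression into the explicit
# edge set. Reflexivity of part-of is realized in the checker as a
# zero-length step. Covers expressions over classes without
# equivalence axioms.

oracle_anc_cache <- new.env(parent = emptyenv())

oracle_anc_self <- function(curie, onts) {
  hit <- oracle_anc_cache[[curie]]
  if (!is.null(hit)) return(hit)
  seen <- character(0)
  queue <- curie
  while (length(queue)) {
    x <- queue[[1]]
    queue <- queue[-1]
    if (x %in% seen) next
    seen <- c(seen, x)
    t <- onts$terms[[x]]
    if (!is.null(t)) queue <- c(queue, t$is_a)
  }
  oracle_anc_cache[[curie]] <- seen
  seen
}

oracle_norm_rel <- function(rel) {
  switch(rel, part_of = "part-of", has_part = "has-part", rel)
}

oracle_subsumes <- function(general, specific, onts) {
  nodes <- list()
  class_idx <- new.env(parent = emptyenv())

  add_node <- function(labels) {
    nodes[[length(nodes) + 1L]] <<- list(labels = labels, edges = list())
    length(nodes)
  }
  has_edge <- function(from, rel, to) {
    for (ed in nodes[[from]]$edges) {
      if (ed$rel == rel && ed$to == to) return(TRUE)
    }
    FALSE
  }
  add_edge <- function(from, rel, to) {
    if (!has_edge(from, rel, to)) {
      nodes[[from]]$edges <<- c(nodes[[from]]$edges,
                                list(list(rel = rel, to = to)))
    }
  }
  class_node <- function(curie) {
    hit <- class_idx[[curie]]
    if (!is.null(hit)) return(hit)
    idx <- add_node(oracle_anc_self(curie, onts))
    class_idx[[curie]] <- idx
    attach_onto_edges(idx, curie)
    idx
  }
  attach_onto_edges <- function(idx, curies) {
    for (a in curies) {
      for (b in oracle_anc_self(a, onts)) {
        t <- onts$terms[[b]]
        if (is.null(t)) next
        for (r in t$relationships) {
          add_edge(idx, oracle_norm_rel(r$relation),
                   class_node(r$target))
        }
      }
    }
  }
  expr_node <- function(e) {
    if (inherits(e, "ce_atom")) {
      return(class_node(e$curie))
    }
    if (inherits(e, "ce_some")) {
      idx <- add_node(character(0))
      child <- expr_node(e$filler)
      add_edge(idx, e$relation, child)
      return(idx)
    }
    atoms <- vapply(
      Filter(function(o) inherits(o, "ce_atom"), e$operands),
      function(o) o$curie, character(1)
    )
    labels <- unique(unlist(lapply(atoms, oracle_anc_self, onts)))
    if (is.null(labels)) labels <- character(0)
    idx <- add_node(labels)
    for (op in e$operands) {
      if (inherits(op, "ce_some")) {
        add_edge(idx, op$relation, expr_node(op$filler))
      }
    }
    attach_onto_edges(idx, atoms)
    idx
  }

  root <- expr_node(specific)

  # saturate part-of transitivity and the has-part chain
  repeat {
    changed <- FALSE
    for (i in seq_along(nodes)) {
      for (ed in nodes[[i]]$edges) {
        if (!ed$rel %in% c("part-of", "has-part")) next
        for (ed2 in nodes[[ed$to]]$edges) {
          if (ed2$rel != "part-of") next
          if (!has_edge(i, ed$rel, ed2$to)) {
            add_edge(i, ed$rel, ed2$to)
            changed <- TRUE
          }
        }
      }
    }
    if (!changed) break
  }

  sat <- function(i, g) {
    if (inherits(g, "ce_atom")) {
      return(g$curie %in% nodes[[i]]$labels)
    }
    if (inherits(g, "ce_and")) {
      for (op in g$operands) if (!sat(i, op)) return(FALSE)
      return(TRUE)
    }
    if (g$relation == "part-of" && sat(i, g$filler)) return(TRUE)
    for (ed in nodes[[i]]$edges) {
      if (ed$rel == g$relation && sat(ed$to, g$filler)) return(TRUE)
    }
    FALSE
  }

  sat(root, general)
}
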