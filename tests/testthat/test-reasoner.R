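test_that("qualified phenotypes fall under their observable's class", {
  heat <- formalize_annotation(fx_anns[1, ], fx_all)
  expect_true(subsumes(fx_defs$equivalences[["APO:0000147"]], heat,
                       fx_ax))
  # and not under an unrelated disposition class
  expect_false(subsumes(fx_defs$equivalences[["APO:0000090"]], heat,
                        fx_ax))
})

test_that("part-of chains traverse is_a edges and are reflexive", {
  g <- ce_some("part-of", ce_atom("GO:0009987"))
  # reflexive: a cellular-process subclass is part-of some cellular
  # process via the zero-length chain
  expect_true(subsumes(g, ce_atom("GO:0022402"), fx_ax_plain))
  # ontology part_of edge (cell cycle process part_of cell cycle)
  expect_true(subsumes(ce_some("part-of", ce_atom("GO:0007049")),
                       ce_atom("GO:0022402"), fx_ax_plain))
  # transitive through is_a then part_of: mitotic G1 phase is_a cell
  # cycle process part_of cell cycle
  expect_true(subsumes(ce_some("part-of", ce_atom("GO:0007049")),
                       ce_atom("GO:0000080"), fx_ax_plain))
  expect_false(subsumes(ce_some("part-of", ce_atom("GO:0008152")),
                        ce_atom("GO:0022402"), fx_ax_plain))
})

test_that("the has-part / part-of property chain is applied", {
  general <- ce_some("has-part", ce_atom("GO:0007049"))
  specific <- ce_some("has-part", ce_atom("GO:0022402"))
  expect_true(subsumes(general, specific, fx_ax_plain))
  # no chain in the other direction
  expect_false(subsumes(specific, general, fx_ax_plain))
})

test_that("subsumption is reflexive and transitive on random expressions", {
  set.seed(303)
  exprs <- replicate(40, canonicalize_expression(random_expression()),
                     simplify = FALSE)
  for (e in exprs) {
    expect_true(subsumes(e, e, fx_ax_plain))
  }
  checked <- 0L
  for (i in seq_along(exprs)) {
    for (j in seq_along(exprs)) {
      if (!subsumes(exprs[[i]], exprs[[j]], fx_ax_plain)) next
      for (k in seq_along(exprs)) {
        if (subsumes(exprs[[j]], exprs[[k]], fx_ax_plain)) {
          checked <- checked + 1L
          expect_true(subsumes(exprs[[i]], exprs[[k]], fx_ax_plain))
        }
      }
    }
  }
  expect_gt(checked, 0L)
})

test_that("adding is_a edges never breaks a true subsumption", {
  set.seed(404)
  pairs <- replicate(40, list(
    g = canonicalize_expression(random_expression(depth = 2L)),
    s = canonicalize_expression(random_expression(depth = 2L))
  ), simplify = FALSE)
  before <- vapply(pairs, function(p) {
    subsumes(p$g, p$s, fx_ax_plain)
  }, logical(1))
  # graft an extra is_a edge: response to heat under cellular process
  aug <- fx_all
  aug$terms[["GO:0009408"]]$is_a <-
    c(aug$terms[["GO:0009408"]]$is_a, "GO:0009987")
  ax_aug <- build_axioms(aug)
  after <- vapply(pairs, function(p) {
    subsumes(p$g, p$s, ax_aug)
  }, logical(1))
  expect_true(all(after[before]))
})

test_that("reasoner agrees with the brute-force homomorphism oracle", {
  set.seed(505)
  disagreements <- 0L
  for (i in 1:300) {
    g <- canonicalize_expression(random_expression())
    s <- canonicalize_expression(random_expression())
    mine <- subsumes(g, s, fx_ax_plain)
    oracle <- oracle_subsumes(g, s, fx_all)
    if (mine != oracle) disagreements <- disagreements + 1L
  }
  expect_equal(disagreements, 0L)
})

test_that("classification finds all and most-specific subsumers", {
  heat <- formalize_annotation(fx_anns[1, ], fx_all)
  res <- classify_expression(heat, fx_ax)
  expect_true("APO:0000147" %in% res$most_specific)
  # an atom with no definitions loaded has no subsumers
  empty_ax <- build_axioms(fx_all)
  expect_length(classify_expression(ce_atom("GO:0009987"), empty_ax)$all,
                0L)
})

test_that("a yeast expression classifies under a cross-species ontology", {
  xpo <- build_cross_species_demo()
  merged <- merge_ontologies(fx$mini_apo, fx$mini_go, fx$mini_pato,
                             fx$mini_chebi, xpo)
  defs <- compile_ontology_definitions(merged, unions = fx$unions)
  ax <- build_axioms(merged, defs$equivalences, defs$sufficient)
  absent_autophagy <- formalize_annotation(
    fx_anns[fx_anns$genotype_id == "S000029048", ], merged
  )
  res <- classify_expression(absent_autophagy, ax)
  expect_true(all(c("XPO:0000001", "XPO:0000002") %in% res$all))
  expect_true("XPO:0000001" %in% res$most_specific)
  expect_false("XPO:0000002" %in% res$most_specific)
})

test_that("hierarchy inference recovers the process-pattern restructuring", {
  edges <- infer_hierarchy(fx_ax)
  key <- paste(edges$child, edges$parent)
  expect_true("APO:0000023 APO:0000066" %in% key)
  expect_true("APO:0000094 APO:0000066" %in% key)
  # asserted edges are never re-reported
  expect_false("APO:0000300 APO:0000253" %in% key)
  # no definitions -> no edges
  expect_equal(nrow(infer_hierarchy(build_axioms(fx_all))), 0L)
})

test_that("inferred edges agree with pairwise oracle subsumption", {
  defined <- union(names(fx_ax$equivalences), names(fx_ax$sufficient))
  disjuncts <- function(id) {
    eq <- fx_ax$equivalences[[id]]
    if (!is.null(eq)) list(eq) else fx_ax$sufficient[[id]]
  }
  oracle_class_sub <- function(parent, child) {
    all(vapply(disjuncts(child), function(dc) {
      any(vapply(disjuncts(parent), function(dp) {
        oracle_subsumes(dp, dc, fx_all)
      }, logical(1)))
    }, logical(1)))
  }
  asserted_anc <- function(id) {
    seen <- character(0); queue <- id
    while (length(queue)) {
      x <- queue[[1]]; queue <- queue[-1]
      if (x %in% seen) next
      seen <- c(seen, x)
      t <- fx_all$terms[[x]]
      if (!is.null(t)) queue <- c(queue, t$is_a)
    }
    seen
  }
  full <- list()
  for (c in defined) {
    for (p in defined) {
      if (p == c || p %in% asserted_anc(c)) next
      if (oracle_class_sub(p, c)) {
        full[[length(full) + 1L]] <- c(c, p)
      }
    }
  }
  full_keys <- vapply(full, paste, character(1), collapse = " ")
  edges <- infer_hierarchy(fx_ax)
  edge_keys <- paste(edges$child, edges$parent)
  # every reported edge is oracle-true
  expect_true(all(edge_keys %in% full_keys))
  # every oracle-true pair is reported or implied through the
  # transitive reduction
  reach <- function(c, p) {
    p %in% asserted_anc(c) ||
      any(vapply(full, function(e) e[1] == c && e[2] == p, logical(1)))
  }
  for (e in full) {
    if (paste(e[1], e[2]) %in% edge_keys) next
    implied <- any(vapply(defined, function(m) {
      m != e[1] && m != e[2] && reach(e[1], m) && reach(m, e[2])
    }, logical(1)))
    expect_true(implied, info = paste(e[1], "->", e[2]))
  }
})

test_that("inferred plus asserted edges stay acyclic", {
  edges <- infer_hierarchy(fx_ax)
  adj <- list()
  for (t in fx_all$terms) {
    adj[[t$id]] <- t$is_a
  }
  for (k in seq_len(nrow(edges))) {
    adj[[edges$child[k]]] <- c(adj[[edges$child[k]]], edges$parent[k])
  }
  state <- new.env(parent = emptyenv())
  visit <- function(x, stack) {
    expect_false(x %in% stack, info = paste("cycle through", x))
    if (isTRUE(state[[x]])) return(invisible(NULL))
    state[[x]] <- TRUE
    for (p in adj[[x]]) visit(p, c(stack, x))
  }
  for (id in names(adj)) visit(id, character(0))
})

test_that("qualifier/bearer category consistency is checked", {
  ok <- check_qualifier_consistency("PATO:0000297", "GO:0022402", fx_all)
  expect_equal(ok$status, "ok")
  bad <- check_qualifier_consistency("PATO:0000297", "GO:0005618", fx_all)
  expect_equal(bad$status, "violation")
  expect_match(bad$message, "PATO:0000297.*process-quality")
  expect_equal(
    check_qualifier_consistency("PATO:0000051", "GO:0005618",
                                fx_all)$status,
    "ok"
  )
  # object quality on a process is the mirror violation
  expect_equal(
    check_qualifier_consistency("PATO:0000051", "GO:0022402",
                                fx_all)$status,
    "violation"
  )
  expect_warning(
    res <- check_qualifier_consistency("PATO:0000461", "GO:0022402",
                                       fx_all),
    "no declared bearer category"
  )
  expect_equal(res$status, "skipped")
})
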