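#' The fixed relation vocabulary
#'
#' Relations usable in compiled class expressions, together with their
#' declared properties. `part-of` is transitive and reflexive, and the
#' property chain `has-part o part-of -> has-part` is registered, so a
#' phenotype that has a part located anywhere inside a structure also
#' has that structure's parts-bearing phenotype. `inheres_in` is *not*
#' part of this vocabulary: it only occurs inside OBO `intersection_of`
#' blocks and is translated away by the compiler.
#'
#' @return A list with elements `relations` (character vector of relation
#'   names), `transitive`, `reflexive` (character vectors), and `chains`
#'   (list of three-element character vectors `c(r1, r2, implied)`).
#' @export
relation_vocabulary <- function() {
  list(
    relations = c(
      "phenotype-of", "has-part", "part-of", "has-quality",
      "during", "towards",
      "increased-in-magnitude-relative-to",
      "decreased-in-magnitude-relative-to"
    ),
    transitive = "part-of",
    reflexive = "part-of",
    chains = list(c("has-part", "part-of", "has-part"))
  )
}

#' The distinguished CURIE for the quality "normal"
#'
#' Magnitude-modifier qualifiers compare against a normal reference
#' quality; the bare token `normal` in rendered expressions is an alias
#' for this PATO class.
#' @export
PATO_NORMAL <- "PATO:0000461"

curie_regex <- "^[A-Za-z][A-Za-z0-9_]*:[0-9]+$"

is_curie <- function(x) grepl(curie_regex, x)

## ---- constructors -----------------------------------------------------

#' Class-expression constructors
#'
#' A class expression is one of an atom (a named class referenced by its
#' CURIE), a conjunction (`and`) of two or more expressions, or an
#' existential restriction `relation some filler`. Conjunctions are
#' flattened on construction (no `ce_and` directly inside a `ce_and`);
#' operand order is preserved as given (see [canonicalize_expression()]
#' for the sorted canonical form).
#'
#' @param curie A CURIE string such as `"GO:0005618"`.
#' @param relation A relation name from [relation_vocabulary()].
#' @param filler A class expression.
#' @param ... For `ce_and()`, two or more class expressions (or a single
#'   list of them).
#' @return A `class_expression` object.
#' @examples
#' ce_some("has-quality", ce_atom("PATO:0000051"))
#' @export
ce_atom <- function(curie) {
  stopifnot(is.character(curie), length(curie) == 1L)
  if (!is_curie(curie)) {
    stop("not a CURIE: '", curie, "'", call. = FALSE)
  }
  structure(list(curie = curie), class = c("ce_atom", "class_expression"))
}

#' @rdname ce_atom
#' @export
ce_some <- function(relation, filler) {
  vocab <- relation_vocabulary()$relations
  if (!relation %in% vocab) {
    stop("unknown relation '", relation, "'; known: ",
         paste(vocab, collapse = ", "), call. = FALSE)
  }
  stopifnot(inherits(filler, "class_expression"))
  structure(list(relation = relation, filler = filler),
            class = c("ce_some", "class_expression"))
}

#' @rdname ce_atom
#' @export
ce_and <- function(...) {
  ops <- list(...)
  if (length(ops) == 1L && is.list(ops[[1]]) &&
      !inherits(ops[[1]], "class_expression")) {
    ops <- ops[[1]]
  }
  flat <- list()
  for (op in ops) {
    stopifnot(inherits(op, "class_expression"))
    if (inherits(op, "ce_and")) {
      flat <- c(flat, op$operands)
    } else {
      flat <- c(flat, list(op))
    }
  }
  if (length(flat) < 2L) {
    stop("ce_and() needs at least two operands", call. = FALSE)
  }
  structure(list(operands = flat), class = c("ce_and", "class_expression"))
}

#' @export
print.class_expression <- function(x, ...) {
  cat(render_expression(x), "\n")
  invisible(x)
}

## ---- rendering --------------------------------------------------------

#' Render a class expression as text
#'
#' Grammar: an atom renders as its CURIE; `ce_some(r, f)` renders as
#' `"r some F"` with `F` parenthesized unless it is an atom; a
#' conjunction renders as its operands joined by `" and "`. Single
#' spaces throughout, no trailing whitespace; the output is the
#' canonical on-disk / CLI expression syntax and is parsed back by
#' [parse_expression()].
#'
#' @param expr A class expression.
#' @return A single string.
#' @examples
#' render_expression(ce_some("has-quality", ce_atom("PATO:0000051")))
#' @export
render_expression <- function(expr) {
  stopifnot(inherits(expr, "class_expression"))
  if (inherits(expr, "ce_atom")) {
    return(expr$curie)
  }
  if (inherits(expr, "ce_some")) {
    f <- render_expression(expr$filler)
    if (!inherits(expr$filler, "ce_atom")) {
      f <- paste0("(", f, ")")
    }
    return(paste(expr$relation, "some", f))
  }
  paste(vapply(expr$operands, render_expression, character(1)),
        collapse = " and ")
}

## ---- parsing ----------------------------------------------------------

tokenize_expression <- function(text) {
  # returns data.frame(token, offset) ; offsets are 1-based character
  # positions into the original text (for error messages)
  tokens <- character(0)
  offsets <- integer(0)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (grepl("^\\s$", ch)) {
      i <- i + 1L
      next
    }
    if (ch %in% c("(", ")")) {
      tokens <- c(tokens, ch)
      offsets <- c(offsets, i)
      i <- i + 1L
      next
    }
    j <- i
    while (j <= n && !grepl("^[\\s()]$", chars[j], perl = TRUE)) {
      j <- j + 1L
    }
    tokens <- c(tokens, paste(chars[i:(j - 1L)], collapse = ""))
    offsets <- c(offsets, i)
    i <- j
  }
  data.frame(token = tokens, offset = offsets, stringsAsFactors = FALSE)
}

#' Parse the textual expression syntax
#'
#' Inverse of [render_expression()]. Tolerates redundant whitespace and
#' line breaks (printed expressions re-wrapped across lines parse
#' unchanged). The bare token `normal` is accepted as an alias for
#' `PATO:0000461`.
#'
#' @param text Expression text in the render grammar.
#' @return A class expression.
#' @examples
#' parse_expression("GO:0009987")
#' parse_expression("has-quality some (PATO:0001457 and
#'    increased-in-magnitude-relative-to some normal)")
#' @export
parse_expression <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  toks <- tokenize_expression(text)
  if (nrow(toks) == 0L) {
    stop("empty expression", call. = FALSE)
  }
  vocab <- relation_vocabulary()$relations
  pos <- 1L

  peek <- function() if (pos <= nrow(toks)) toks$token[pos] else NA_character_
  here <- function() {
    if (pos <= nrow(toks)) toks$offset[pos] else nchar(text) + 1L
  }
  advance <- function() pos <<- pos + 1L

  parse_err <- function(msg, at = here()) {
    stop("parse error at character ", at, ": ", msg, call. = FALSE)
  }

  parse_primary <- function() {
    tok <- peek()
    if (is.na(tok)) parse_err("unexpected end of input")
    if (tok == "(") {
      open_at <- here()
      advance()
      e <- parse_conjunction()
      if (is.na(peek()) || peek() != ")") {
        parse_err("unbalanced parentheses (opened here)", open_at)
      }
      advance()
      return(e)
    }
    if (tok == ")") parse_err("unexpected ')'")
    # identifier: relation (followed by 'some'), CURIE, or 'normal'
    if (pos + 1L <= nrow(toks) && toks$token[pos + 1L] == "some") {
      if (!tok %in% vocab) {
        parse_err(paste0("unknown relation '", tok, "'"))
      }
      advance()  # relation
      advance()  # 'some'
      filler <- parse_primary()
      return(ce_some(tok, filler))
    }
    if (tok == "normal") {
      advance()
      return(ce_atom(PATO_NORMAL))
    }
    if (!is_curie(tok)) {
      parse_err(paste0("expected a CURIE, got '", tok, "'"))
    }
    advance()
    ce_atom(tok)
  }

  parse_conjunction <- function() {
    ops <- list(parse_primary())
    while (!is.na(peek()) && peek() == "and") {
      advance()
      ops <- c(ops, list(parse_primary()))
    }
    if (length(ops) == 1L) ops[[1]] else ce_and(ops)
  }

  e <- parse_conjunction()
  if (!is.na(peek())) {
    parse_err(paste0("trailing input '", peek(), "'"))
  }
  e
}

## ---- canonical form ---------------------------------------------------

#' Canonicalize a class expression
#'
#' Flattens nested conjunctions, removes exact-duplicate operands, and
#' sorts operands byte-lexicographically by their rendering so equal
#' expressions have bit-identical renderings. Idempotent; the result is
#' subsumption-equivalent to the input.
#'
#' @param expr A class expression.
#' @return The canonical class expression.
#' @export
canonicalize_expression <- function(expr) {
  stopifnot(inherits(expr, "class_expression"))
  if (inherits(expr, "ce_atom")) {
    return(expr)
  }
  if (inherits(expr, "ce_some")) {
    return(ce_some(expr$relation, canonicalize_expression(expr$filler)))
  }
  ops <- lapply(expr$operands, canonicalize_expression)
  # ce_and() flattening happens in the constructor; re-run it on the
  # canonicalized operands, then sort and deduplicate by rendering
  flat <- ce_and(ops)$operands
  keys <- vapply(flat, render_expression, character(1))
  keep <- !duplicated(keys)
  flat <- flat[keep]
  keys <- keys[keep]
  ord <- order(keys, method = "radix")
  flat <- flat[ord]
  if (length(flat) == 1L) flat[[1]] else ce_and(flat)
}

#' Test two expressions for structural equality
#'
#' Deep equality of the ASTs after canonicalization.
#' @param a,b Class expressions.
#' @return `TRUE` or `FALSE`.
#' @export
expressions_equal <- function(a, b) {
  identical(render_expression(canonicalize_expression(a)),
            render_expression(canonicalize_expression(b)))
}

## ---- EQ definitions ---------------------------------------------------

#' Extract the EQ definition carried by an ontology term
#'
#' Reads the `intersection_of` block of an OBO term as an entity-quality
#' definition: the genus is the PATO quality, the `inheres_in`
#' differentium the bearer entity, and optional `during` / `towards`
#' differentia the temporal stage and the second argument of a
#' relational quality.
#'
#' @param term An `ontology_term` (see [parse_obo()]).
#' @return An object of class `eq_definition` with fields `quality`,
#'   `bearer`, `during`, `towards` (the last two possibly `NA`), or
#'   `NULL` when the term has no `intersection_of` block.
#' @export
eq_definition <- function(term) {
  ix <- term$intersection_of
  if (is.null(ix)) {
    return(NULL)
  }
  quality <- ix$genus
  bearer <- NA_character_
  during <- NA_character_
  towards <- NA_character_
  for (d in ix$differentia) {
    rel <- norm_relation_name(d$relation)
    if (rel == "inheres_in") {
      bearer <- d$target
    } else if (rel == "during") {
      during <- d$target
    } else if (rel == "towards") {
      towards <- d$target
    } else {
      stop("term ", term$id, ": unsupported differentium relation '",
           d$relation, "' in intersection_of", call. = FALSE)
    }
  }
  if (is.na(bearer)) {
    stop("term ", term$id,
         ": intersection_of has no inheres_in differentium", call. = FALSE)
  }
  structure(
    list(quality = quality, bearer = bearer,
         during = during, towards = towards),
    class = "eq_definition"
  )
}

# OBO files write relations with underscores (part_of, has_part); the
# expression vocabulary uses hyphens. inheres_in stays underscored: it
# never leaves the OBO layer.
norm_relation_name <- function(rel) {
  switch(rel,
    part_of = "part-of",
    has_part = "has-part",
    has_quality = "has-quality",
    phenotype_of = "phenotype-of",
    increased_in_magnitude_relative_to = "increased-in-magnitude-relative-to",
    decreased_in_magnitude_relative_to = "decreased-in-magnitude-relative-to",
    rel
  )
}
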