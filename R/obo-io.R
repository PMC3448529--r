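## OBO 1.2 flat-file subset and tabular annotation formats.
##
## The reader supports exactly the clause types the EQ machinery needs
## (id, name, namespace, is_a, relationship, intersection_of,
## is_obsolete); every other tag inside a [Term] stanza is preserved as
## an opaque passthrough line so write_obo() does not lose it. Stanza
## types other than [Term] are skipped with a warning.

new_ontology_term <- function(id, name = NA_character_,
                              namespace = NA_character_,
                              is_a = character(0),
                              relationships = list(),
                              intersection_of = NULL,
                              is_obsolete = FALSE,
                              extra = character(0)) {
  structure(
    list(id = id, name = name, namespace = namespace, is_a = is_a,
         relationships = relationships, intersection_of = intersection_of,
         is_obsolete = is_obsolete, extra = extra),
    class = "ontology_term"
  )
}

new_ontology <- function(terms = list(), dangling = character(0),
                         skipped_stanzas = 0L) {
  vocab <- relation_vocabulary()
  structure(
    list(
      terms = terms,
      relation_declarations = list(
        transitive = vocab$transitive,
        reflexive = vocab$reflexive
      ),
      chains = vocab$chains,
      dangling = dangling,
      skipped_stanzas = skipped_stanzas
    ),
    class = "ontology"
  )
}

#' @export
print.ontology <- function(x, ...) {
  cat("ontology with", length(x$terms), "terms")
  if (length(x$dangling)) {
    cat(",", length(x$dangling), "dangling references")
  }
  cat("\n")
  invisible(x)
}

strip_obo_comment <- function(x) {
  # comments start at an unquoted "!"; the subset here has no quoting
  sub("\\s*!.*$", "", x)
}

#' Parse an OBO 1.2 flat-file document
#'
#' Reads `[Term]` stanzas into an ontology. Recognized clauses: `id`,
#' `name`, `namespace`, `is_a`, `relationship`, `intersection_of`,
#' `is_obsolete`; any other clause is preserved verbatim and re-emitted
#' by [write_obo()]. `!` comments are stripped before parsing. Stanza
#' types other than `[Term]` are skipped with a warning. CURIEs
#' referenced but not defined in the document are recorded in the
#' ontology's `dangling` field (cross-ontology references are routine,
#' so they are not errors).
#'
#' @param document OBO text: a single string or a character vector of
#'   lines.
#' @return An object of class `ontology`: a named list of terms plus
#'   relation declarations, property chains, and bookkeeping fields
#'   (`dangling`, `skipped_stanzas`).
#' @seealso [read_obo()] to read from a file, [write_obo()].
#' @export
parse_obo <- function(document) {
  if (length(document) == 1L && grepl("\n", document, fixed = TRUE)) {
    lines <- strsplit(document, "\n", fixed = TRUE)[[1]]
  } else {
    lines <- document
  }
  lines <- sub("\r$", "", lines)

  terms <- list()
  skipped <- 0L

  i <- 1L
  n <- length(lines)
  in_term <- FALSE
  in_other <- FALSE
  cur <- NULL
  cur_genus <- character(0)
  cur_diff <- list()
  had_intersection <- FALSE

  finish_term <- function() {
    if (is.null(cur)) return(invisible(NULL))
    if (is.na(cur$id)) {
      stop("[Term] stanza without an id clause", call. = FALSE)
    }
    if (had_intersection) {
      if (length(cur_genus) == 0L) {
        stop("term ", cur$id,
             ": intersection_of block has no genus clause", call. = FALSE)
      }
      if (length(cur_genus) > 1L) {
        stop("term ", cur$id, ": intersection_of block has ",
             length(cur_genus), " genus clauses", call. = FALSE)
      }
      if (cur$is_obsolete) {
        stop("term ", cur$id,
             ": obsolete terms may not carry intersection_of",
             call. = FALSE)
      }
      cur$intersection_of <<- list(genus = cur_genus,
                                   differentia = cur_diff)
    }
    if (!is.null(terms[[cur$id]])) {
      stop("duplicate term id: ", cur$id, call. = FALSE)
    }
    terms[[cur$id]] <<- structure(cur, class = "ontology_term")
    invisible(NULL)
  }

  for (i in seq_len(n)) {
    raw <- lines[i]
    line <- trimws(strip_obo_comment(raw))
    if (trimws(raw) == "[Term]") {
      finish_term()
      cur <- unclass(new_ontology_term(NA_character_))
      cur_genus <- character(0)
      cur_diff <- list()
      had_intersection <- FALSE
      in_term <- TRUE
      in_other <- FALSE
      next
    }
    if (grepl("^\\[", trimws(raw))) {
      finish_term()
      cur <- NULL
      in_term <- FALSE
      in_other <- TRUE
      skipped <- skipped + 1L
      warning("skipping stanza ", trimws(raw), call. = FALSE)
      next
    }
    if (!in_term || line == "") next
    m <- regmatches(line, regexec("^([A-Za-z_]+):\\s*(.*)$", line))[[1]]
    if (length(m) == 0L) next
    tag <- m[2]
    value <- trimws(m[3])
    if (tag == "id") {
      cur$id <- value
    } else if (tag == "name") {
      cur$name <- value
    } else if (tag == "namespace") {
      cur$namespace <- value
    } else if (tag == "is_a") {
      cur$is_a <- c(cur$is_a, value)
    } else if (tag == "relationship") {
      parts <- strsplit(value, "\\s+")[[1]]
      if (length(parts) != 2L) {
        stop("term ", cur$id, ": malformed relationship clause '",
             value, "'", call. = FALSE)
      }
      cur$relationships <- c(cur$relationships,
                             list(list(relation = parts[1],
                                       target = parts[2])))
    } else if (tag == "intersection_of") {
      had_intersection <- TRUE
      parts <- strsplit(value, "\\s+")[[1]]
      if (length(parts) == 1L) {
        cur_genus <- c(cur_genus, parts[1])
      } else if (length(parts) == 2L) {
        cur_diff <- c(cur_diff,
                      list(list(relation = parts[1], target = parts[2])))
      } else {
        stop("term ", cur$id, ": malformed intersection_of clause '",
             value, "'", call. = FALSE)
      }
    } else if (tag == "is_obsolete") {
      cur$is_obsolete <- identical(value, "true")
    } else {
      # opaque passthrough; keep the comment-stripped form so the
      # write/parse round trip is a fixpoint
      cur$extra <- c(cur$extra, line)
    }
  }
  finish_term()

  onto <- new_ontology(terms, skipped_stanzas = skipped)
  onto$dangling <- find_dangling(onto)
  if (length(onto$dangling)) {
    message("ontology has ", length(onto$dangling),
            " dangling reference(s): ",
            paste(utils::head(onto$dangling, 5L), collapse = ", "),
            if (length(onto$dangling) > 5L) ", ..." else "")
  }
  onto
}

find_dangling <- function(ontology) {
  refs <- character(0)
  for (t in ontology$terms) {
    refs <- c(refs, t$is_a,
              vapply(t$relationships, `[[`, character(1), "target"))
    if (!is.null(t$intersection_of)) {
      refs <- c(refs, t$intersection_of$genus,
                vapply(t$intersection_of$differentia, `[[`,
                       character(1), "target"))
    }
  }
  sort(setdiff(unique(refs), names(ontology$terms)))
}

#' @rdname parse_obo
#' @param path Path to an OBO file.
#' @export
read_obo <- function(path) {
  parse_obo(readLines(path, warn = FALSE, encoding = "UTF-8"))
}

#' Serialize an ontology to OBO text
#'
#' Terms are emitted sorted by CURIE; clause order within a stanza is
#' id, name, namespace, is_a (sorted), intersection_of (genus first,
#' differentia in stored order), relationship (sorted), passthrough
#' lines, is_obsolete. Output is deterministic and byte-identical for
#' equal inputs; `parse_obo(write_obo(x))` reproduces `x`.
#'
#' @param ontology An `ontology`.
#' @param path Optional file path; when given the text is also written
#'   there (UTF-8, `\n` line endings).
#' @return The OBO document as a single string, invisibly when `path`
#'   is given.
#' @export
write_obo <- function(ontology, path = NULL) {
  stopifnot(inherits(ontology, "ontology"))
  out <- c("format-version: 1.2", "")
  ids <- sort(as.character(names(ontology$terms)), method = "radix")
  for (id in ids) {
    t <- ontology$terms[[id]]
    out <- c(out, "[Term]", paste0("id: ", t$id))
    if (!is.na(t$name)) out <- c(out, paste0("name: ", t$name))
    if (!is.na(t$namespace)) {
      out <- c(out, paste0("namespace: ", t$namespace))
    }
    for (p in sort(t$is_a, method = "radix")) {
      out <- c(out, paste0("is_a: ", p))
    }
    if (!is.null(t$intersection_of)) {
      out <- c(out, paste0("intersection_of: ", t$intersection_of$genus))
      for (d in t$intersection_of$differentia) {
        out <- c(out,
                 paste0("intersection_of: ", d$relation, " ", d$target))
      }
    }
    if (length(t$relationships)) {
      rl <- vapply(t$relationships, function(r) {
        paste0("relationship: ", r$relation, " ", r$target)
      }, character(1))
      out <- c(out, sort(rl, method = "radix"))
    }
    out <- c(out, t$extra)
    if (isTRUE(t$is_obsolete)) out <- c(out, "is_obsolete: true")
    out <- c(out, "")
  }
  text <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(path)) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeChar(text, con, eos = NULL)
    return(invisible(text))
  }
  text
}

#' Merge several ontologies into one store
#'
#' Used when definitions span APO, GO, PATO and ChEBI. Duplicate CURIEs
#' across the inputs are a hard error; dangling references are
#' recomputed on the merged term set.
#'
#' @param ... Ontologies, or a single list of ontologies.
#' @return A merged `ontology`.
#' @export
merge_ontologies <- function(...) {
  onts <- list(...)
  if (length(onts) == 1L && !inherits(onts[[1]], "ontology")) {
    onts <- onts[[1]]
  }
  terms <- list()
  skipped <- 0L
  for (o in onts) {
    stopifnot(inherits(o, "ontology"))
    dup <- intersect(names(o$terms), names(terms))
    if (length(dup)) {
      stop("duplicate CURIE(s) across ontologies: ",
           paste(dup, collapse = ", "), call. = FALSE)
    }
    terms <- c(terms, o$terms)
    skipped <- skipped + o$skipped_stanzas
  }
  onto <- new_ontology(terms, skipped_stanzas = skipped)
  onto$dangling <- find_dangling(onto)
  onto
}

## ---- tabular annotation formats --------------------------------------

read_annotation_table <- function(table, columns) {
  if (length(table) == 1L && (file.exists(table) || grepl("\n", table))) {
    if (file.exists(table)) {
      lines <- readLines(table, warn = FALSE, encoding = "UTF-8")
    } else {
      lines <- strsplit(table, "\n", fixed = TRUE)[[1]]
    }
  } else {
    lines <- table
  }
  lines <- sub("\r$", "", lines)
  keep <- !startsWith(lines, "!")
  lineno <- seq_along(lines)[keep]
  lines <- lines[keep]
  nonblank <- nzchar(trimws(lines))
  lineno <- lineno[nonblank]
  lines <- lines[nonblank]
  if (length(lines) == 0L) {
    stop("annotation table has no header line", call. = FALSE)
  }
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (!identical(header, columns)) {
    stop("unexpected header; expected: ",
         paste(columns, collapse = "\t"), call. = FALSE)
  }
  body <- lines[-1]
  body_lineno <- lineno[-1]
  rows <- vector("list", length(body))
  for (k in seq_along(body)) {
    fields <- strsplit(body[k], "\t", fixed = TRUE)[[1]]
    # trailing empty fields are dropped by strsplit; pad
    if (length(fields) < length(columns) &&
        length(fields) >= 1L) {
      ncommit <- lengths(regmatches(body[k],
                                    gregexpr("\t", body[k], fixed = TRUE)))
      if (ncommit + 1L == length(columns)) {
        fields <- c(fields, rep("", length(columns) - length(fields)))
      }
    }
    if (length(fields) != length(columns)) {
      stop("line ", body_lineno[k], ": expected ", length(columns),
           " tab-separated fields, found ", length(fields), call. = FALSE)
    }
    rows[[k]] <- fields
  }
  list(rows = rows, lineno = body_lineno)
}

#' Read genotype-phenotype annotations
#'
#' The canonical phenotype-annotation dialect of this package: UTF-8,
#' tab-separated, header line
#' `genotype_id gene_id observable_id qualifier_id chemical_id condition`,
#' one record per line, lines starting `!` ignored. An empty
#' `chemical_id` field makes a pair annotation (observable + qualifier);
#' a ChEBI CURIE makes a triple. The `condition` column is carried but
#' not interpreted.
#'
#' @param table A file path, a single string with embedded newlines, or
#'   a character vector of lines.
#' @return A data frame with one row per annotation, columns
#'   `genotype_id`, `gene_id`, `observable`, `qualifier`, `chemical`
#'   (`NA` when absent), `condition`, in file order.
#' @export
read_phenotype_annotations <- function(table) {
  cols <- c("genotype_id", "gene_id", "observable_id", "qualifier_id",
            "chemical_id", "condition")
  parsed <- read_annotation_table(table, cols)
  n <- length(parsed$rows)
  out <- data.frame(
    genotype_id = character(n), gene_id = character(n),
    observable = character(n), qualifier = character(n),
    chemical = character(n), condition = character(n),
    stringsAsFactors = FALSE
  )
  for (k in seq_len(n)) {
    f <- parsed$rows[[k]]
    ln <- parsed$lineno[k]
    for (idx in c(3L, 4L)) {
      if (!is_curie(f[idx])) {
        stop("line ", ln, ": '", f[idx], "' in column ", cols[idx],
             " is not a CURIE", call. = FALSE)
      }
    }
    if (nzchar(f[5]) && !is_curie(f[5])) {
      stop("line ", ln, ": '", f[5], "' in column chemical_id",
           " is not a CURIE", call. = FALSE)
    }
    out$genotype_id[k] <- f[1]
    out$gene_id[k] <- f[2]
    out$observable[k] <- f[3]
    out$qualifier[k] <- f[4]
    out$chemical[k] <- if (nzchar(f[5])) f[5] else NA_character_
    out$condition[k] <- f[6]
  }
  if (n == 0L) out$chemical <- as.character(out$chemical)
  out
}

#' Read gene-to-GO annotations
#'
#' Tab-separated, header `gene_id go_id aspect`; aspect must be one of
#' `P` (biological process), `F` (molecular function), `C` (cellular
#' component). Duplicate lines are preserved (the recovery comparator
#' deduplicates).
#'
#' @inheritParams read_phenotype_annotations
#' @return A data frame with columns `gene_id`, `go_id`, `aspect`, in
#'   file order.
#' @export
read_gene_go_annotations <- function(table) {
  cols <- c("gene_id", "go_id", "aspect")
  parsed <- read_annotation_table(table, cols)
  n <- length(parsed$rows)
  out <- data.frame(gene_id = character(n), go_id = character(n),
                    aspect = character(n), stringsAsFactors = FALSE)
  for (k in seq_len(n)) {
    f <- parsed$rows[[k]]
    ln <- parsed$lineno[k]
    if (!f[3] %in% c("P", "F", "C")) {
      stop("line ", ln, ": unknown aspect code '", f[3],
           "' (expected P, F or C)", call. = FALSE)
    }
    if (!is_curie(f[2])) {
      stop("line ", ln, ": '", f[2], "' in column go_id is not a CURIE",
           call. = FALSE)
    }
    out$gene_id[k] <- f[1]
    out$go_id[k] <- f[2]
    out$aspect[k] <- f[3]
  }
  out
}

write_tsv_lines <- function(df, path = NULL) {
  header <- paste(names(df), collapse = "\t")
  body <- apply(df, 1L, function(r) {
    paste(ifelse(is.na(r), "", r), collapse = "\t")
  })
  lines <- c(header, if (nrow(df)) body)
  text <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeChar(text, con, eos = NULL)
    return(invisible(text))
  }
  text
}
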