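## Phenotype -> gene function recovery: extract the GO classes embedded
## in formalized phenotype expressions, compare them per GO aspect with
## the gene's existing GO annotations, and surface the unmatched
## predictions as novel candidate annotations.

#' Extract the GO classes mentioned in expressions
#'
#' All `GO:`-prefixed atoms anywhere in the expressions, including
#' `during` fillers; deterministic CURIE order.
#'
#' @param exprs A `class_expression` or a list of them.
#' @return Sorted character vector of GO CURIEs (no duplicates).
#' @export
extract_go_terms <- function(exprs) {
  if (inherits(exprs, "class_expression")) exprs <- list(exprs)
  walk <- function(e) {
    if (inherits(e, "ce_atom")) return(e$curie)
    if (inherits(e, "ce_some")) return(walk(e$filler))
    unlist(lapply(e$operands, walk))
  }
  atoms <- unlist(lapply(exprs, walk))
  sort(unique(atoms[startsWith(atoms, "GO:")]), method = "radix")
}

# ancestors in the combined is_a + part_of graph, excluding the start
go_ancestors <- function(curie, ontology, cache) {
  hit <- cache[[curie]]
  if (!is.null(hit)) return(hit)
  seen <- character(0)
  queue <- curie
  while (length(queue)) {
    x <- queue[[1]]
    queue <- queue[-1]
    if (x %in% seen) next
    seen <- c(seen, x)
    t <- ontology$terms[[x]]
    if (is.null(t)) next
    queue <- c(queue, t$is_a)
    for (r in t$relationships) {
      if (norm_relation_name(r$relation) == "part-of") {
        queue <- c(queue, r$target)
      }
    }
  }
  res <- setdiff(seen, curie)
  cache[[curie]] <- res
  res
}

terms_match <- function(p, t, ontology, cache, match) {
  if (p == t) return(TRUE)
  if (match == "exact") return(FALSE)
  p %in% go_ancestors(t, ontology, cache) ||
    t %in% go_ancestors(p, ontology, cache)
}

#' Compare phenotype-derived GO terms against existing annotations
#'
#' An existing annotation `(gene, t)` counts as *recovered* when some
#' phenotype-derived term `p` for that gene equals `t` or is an
#' ancestor or descendant of `t` in the combined is_a/part_of closure
#' (`match = "ancestor"`, the default; `match = "exact"` requires
#' identity). Duplicate GO annotation lines are deduplicated before
#' counting. Predicted terms that recover none of their gene's
#' annotations are emitted as novel candidate annotations.
#'
#' @param predicted Data frame with columns `gene_id`, `go_id` and
#'   optionally `genotype_id` (provenance for candidates); or a named
#'   list mapping gene ids to GO CURIE vectors.
#' @param goa Data frame from [read_gene_go_annotations()].
#' @param ontology Merged `ontology` containing the GO terms (for
#'   ancestor computation).
#' @param match `"ancestor"` or `"exact"`.
#' @return A `recovery_report`: list with `counts` (data frame
#'   `aspect`, `recovered`, `total`, `percentage`; aspects ordered P,
#'   F, C; percentage `NA` for empty aspects) and `candidates` (data
#'   frame `gene_id`, `go_id`, `genotypes`).
#' @export
compare_to_goa <- function(predicted, goa, ontology,
                           match = c("ancestor", "exact")) {
  match <- match.arg(match)
  if (!is.data.frame(predicted)) {
    predicted <- data.frame(
      gene_id = rep(names(predicted), lengths(predicted)),
      go_id = unlist(predicted, use.names = FALSE),
      stringsAsFactors = FALSE
    )
  }
  if (!"genotype_id" %in% names(predicted)) {
    predicted$genotype_id <- rep(NA_character_, nrow(predicted))
  }
  goa <- unique(goa[, c("gene_id", "go_id", "aspect")])
  cache <- new.env(parent = emptyenv())
  aspects <- c("P", "F", "C")
  recovered <- stats::setNames(integer(3), aspects)
  total <- stats::setNames(integer(3), aspects)
  pred_by_gene <- split(seq_len(nrow(predicted)), predicted$gene_id)
  pred_used <- rep(FALSE, nrow(predicted))
  for (k in seq_len(nrow(goa))) {
    g <- goa$gene_id[k]
    t <- goa$go_id[k]
    a <- goa$aspect[k]
    total[a] <- total[a] + 1L
    idx <- pred_by_gene[[g]]
    if (is.null(idx)) next
    hit <- FALSE
    for (i in idx) {
      if (terms_match(predicted$go_id[i], t, ontology, cache, match)) {
        hit <- TRUE
        pred_used[i] <- TRUE
      }
    }
    if (hit) recovered[a] <- recovered[a] + 1L
  }
  # a predicted (gene, term) is a candidate when no occurrence of it
  # recovered anything for that gene
  cand <- data.frame(gene_id = character(0), go_id = character(0),
                     genotypes = character(0), stringsAsFactors = FALSE)
  if (nrow(predicted)) {
    key <- paste(predicted$gene_id, predicted$go_id, sep = "\r")
    used_by_key <- tapply(pred_used, key, any)
    cand_keys <- names(used_by_key)[!used_by_key]
    if (length(cand_keys)) {
      rows <- lapply(cand_keys, function(kk) {
        sel <- key == kk
        gt <- sort(unique(stats::na.omit(predicted$genotype_id[sel])),
                   method = "radix")
        parts <- strsplit(kk, "\r", fixed = TRUE)[[1]]
        data.frame(gene_id = parts[1], go_id = parts[2],
                   genotypes = paste(gt, collapse = ","),
                   stringsAsFactors = FALSE)
      })
      cand <- do.call(rbind, rows)
      cand <- cand[order(cand$gene_id, cand$go_id, method = "radix"), ,
                   drop = FALSE]
      rownames(cand) <- NULL
    }
  }
  counts <- data.frame(
    aspect = aspects,
    recovered = as.integer(recovered),
    total = as.integer(total),
    percentage = ifelse(total > 0, 100 * recovered / total, NA_real_),
    stringsAsFactors = FALSE
  )
  structure(list(counts = counts, candidates = cand, match = match),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("recovery report (match rule: ", x$match, ")\n", sep = "")
  print(x$counts, row.names = FALSE)
  cat(nrow(x$candidates), "novel candidate annotation(s)\n")
  invisible(x)
}

#' Serialize / read a recovery report
#'
#' TSV layout: a header line, one `aspect` row per GO aspect with the
#' recovered/total counts and the percentage to one decimal (`NA` for
#' a 0/0 aspect), then one `candidate` row per novel candidate with
#' its supporting genotype ids comma-joined. Deterministic ordering.
#'
#' @param report A `recovery_report`.
#' @param path Optional output file.
#' @return The report text (invisibly when `path` is given).
#' @export
write_report <- function(report, path = NULL) {
  stopifnot(inherits(report, "recovery_report"))
  lines <- "record\tfield1\tfield2\tfield3"
  for (k in seq_len(nrow(report$counts))) {
    r <- report$counts[k, ]
    pct <- if (is.na(r$percentage)) "NA" else sprintf("%.1f", r$percentage)
    lines <- c(lines, paste("aspect", r$aspect,
                            paste0(r$recovered, "/", r$total), pct,
                            sep = "\t"))
  }
  for (k in seq_len(nrow(report$candidates))) {
    r <- report$candidates[k, ]
    lines <- c(lines, paste("candidate", r$gene_id, r$go_id,
                            r$genotypes, sep = "\t"))
  }
  text <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeChar(text, con, eos = NULL)
    return(invisible(text))
  }
  text
}

#' @rdname write_report
#' @param text Report text or file path.
#' @export
read_report <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text)) {
    lines <- readLines(text, warn = FALSE)
  } else if (length(text) == 1L) {
    lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  } else {
    lines <- text
  }
  lines <- lines[nzchar(lines)]
  lines <- lines[-1]  # header
  fields <- strsplit(lines, "\t", fixed = TRUE)
  counts <- list()
  cand <- list()
  for (f in fields) {
    if (f[1] == "aspect") {
      rt <- strsplit(f[3], "/", fixed = TRUE)[[1]]
      counts[[length(counts) + 1L]] <- data.frame(
        aspect = f[2], recovered = as.integer(rt[1]),
        total = as.integer(rt[2]),
        percentage = suppressWarnings(as.numeric(f[4])),
        stringsAsFactors = FALSE
      )
    } else if (f[1] == "candidate") {
      cand[[length(cand) + 1L]] <- data.frame(
        gene_id = f[2], go_id = f[3],
        genotypes = if (length(f) >= 4L) f[4] else "",
        stringsAsFactors = FALSE
      )
    }
  }
  structure(
    list(
      counts = do.call(rbind, counts),
      candidates = if (length(cand)) {
        do.call(rbind, cand)
      } else {
        data.frame(gene_id = character(0), go_id = character(0),
                   genotypes = character(0), stringsAsFactors = FALSE)
      },
      match = NA_character_
    ),
    class = "recovery_report"
  )
}

#' Run the full phenotype-to-function recovery pipeline
#'
#' Formalizes every phenotype annotation (unformalizable ones --
#' observables without an EQ definition -- are skipped and counted),
#' extracts the GO terms per gene with genotype provenance, and
#' compares against the gene-GO table.
#'
#' @param phenotypes Data frame from [read_phenotype_annotations()].
#' @param goa Data frame from [read_gene_go_annotations()].
#' @param ontologies Merged `ontology`.
#' @param table Qualifier table.
#' @param match Matching rule, see [compare_to_goa()].
#' @param overrides Optional category overrides.
#' @return A `recovery_report` with an extra `n_unformalizable` field.
#' @export
recover_functions <- function(phenotypes, goa, ontologies,
                              table = default_qualifier_table(),
                              match = c("ancestor", "exact"),
                              overrides = NULL) {
  match <- match.arg(match)
  pred <- list()
  skipped <- 0L
  for (k in seq_len(nrow(phenotypes))) {
    ann <- phenotypes[k, ]
    expr <- tryCatch(
      formalize_annotation(ann, ontologies, table,
                           overrides = overrides),
      error = function(e) NULL
    )
    if (is.null(expr)) {
      skipped <- skipped + 1L
      message("skipping unformalizable annotation for ",
              ann$genotype_id, " (", ann$observable, ")")
      next
    }
    gos <- extract_go_terms(expr)
    if (length(gos)) {
      pred[[length(pred) + 1L]] <- data.frame(
        gene_id = ann$gene_id, go_id = gos,
        genotype_id = ann$genotype_id, stringsAsFactors = FALSE
      )
    }
  }
  predicted <- if (length(pred)) {
    do.call(rbind, pred)
  } else {
    data.frame(gene_id = character(0), go_id = character(0),
               genotype_id = character(0), stringsAsFactors = FALSE)
  }
  report <- compare_to_goa(predicted, goa, ontologies, match)
  report$n_unformalizable <- skipped
  report
}
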