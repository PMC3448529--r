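cell_wall_stanza <- c(
  "format-version: 1.2",
  "",
  "[Term]",
  "id: APO:0000053 ! cell wall morphology",
  "name: cell wall morphology",
  "namespace: observable",
  "intersection_of: PATO:0000051 ! morphology",
  "intersection_of: inheres_in GO:0005618"
)

test_that("the cell-wall-morphology stanza parses into genus + differentium", {
  onto <- suppressMessages(parse_obo(cell_wall_stanza))
  expect_length(onto$terms, 1L)
  t <- onto$terms[["APO:0000053"]]
  expect_equal(t$name, "cell wall morphology")
  eq <- eq_definition(t)
  expect_equal(eq$quality, "PATO:0000051")
  expect_equal(eq$bearer, "GO:0005618")
  expect_true(is.na(eq$during) && is.na(eq$towards))
  # comments are stripped, cross-ontology references recorded as dangling
  expect_setequal(onto$dangling, c("PATO:0000051", "GO:0005618"))
})

test_that("parser rejects malformed stanzas with the offending id", {
  dup <- c("[Term]", "id: A:1", "[Term]", "id: A:1")
  expect_error(suppressMessages(parse_obo(dup)), "duplicate term id: A:1")
  no_genus <- c("[Term]", "id: A:1", "intersection_of: inheres_in B:2")
  expect_error(suppressMessages(parse_obo(no_genus)),
               "A:1.*no genus")
  two_genus <- c("[Term]", "id: A:1", "intersection_of: B:2",
                 "intersection_of: C:3")
  expect_error(suppressMessages(parse_obo(two_genus)),
               "A:1.*2 genus")
})

test_that("empty documents and non-Term stanzas are handled", {
  expect_length(parse_obo("")$terms, 0L)
  doc <- c("[Typedef]", "id: part_of", "[Term]", "id: A:1")
  onto <- suppressWarnings(suppressMessages(parse_obo(doc)))
  expect_length(onto$terms, 1L)
  expect_equal(onto$skipped_stanzas, 1L)
  expect_warning(suppressMessages(parse_obo(doc)), "skipping stanza")
})

test_that("no [Term] stanza is silently dropped", {
  doc <- c("[Term]", "id: A:1", "", "[Typedef]", "id: r", "",
           "[Term]", "id: B:2", "is_a: A:1")
  onto <- suppressWarnings(suppressMessages(parse_obo(doc)))
  n_stanzas <- sum(grepl("^\\[", doc))
  expect_equal(length(onto$terms) + onto$skipped_stanzas, n_stanzas)
})

test_that("write/parse is a fixpoint on every fixture ontology", {
  for (nm in c("mini_go", "mini_pato", "mini_chebi", "mini_apo")) {
    o1 <- fx[[nm]]
    text1 <- write_obo(o1)
    o2 <- suppressMessages(parse_obo(text1))
    text2 <- write_obo(o2)
    expect_identical(text1, text2, info = nm)
    # deep comparison of the reparsed terms against the originals
    expect_setequal(names(o2$terms), names(o1$terms))
    for (id in names(o1$terms)) {
      a <- o1$terms[[id]]
      b <- o2$terms[[id]]
      expect_identical(sort(a$is_a), sort(b$is_a), info = id)
      expect_identical(a$intersection_of, b$intersection_of, info = id)
    }
  }
})

test_that("write_obo reproduces the published intersection_of lines", {
  onto <- suppressMessages(parse_obo(cell_wall_stanza))
  text <- write_obo(onto)
  expect_match(text, "intersection_of: PATO:0000051\n", fixed = TRUE)
  expect_match(text, "intersection_of: inheres_in GO:0005618\n",
               fixed = TRUE)
  # an empty ontology serializes to a header-only document
  expect_equal(write_obo(parse_obo("")), "format-version: 1.2\n\n")
})

test_that("unknown clause types survive a write/parse round trip", {
  doc <- c("[Term]", "id: A:1", "name: thing",
           "def: \"something\" [PMID:1]", "xref: X:9")
  o1 <- suppressMessages(parse_obo(doc))
  expect_length(o1$terms[["A:1"]]$extra, 2L)
  o2 <- suppressMessages(parse_obo(write_obo(o1)))
  expect_identical(o1$terms[["A:1"]]$extra, o2$terms[["A:1"]]$extra)
})

phen_header <- paste("genotype_id", "gene_id", "observable_id",
                     "qualifier_id", "chemical_id", "condition",
                     sep = "\t")

test_that("phenotype annotation reader handles pairs and triples", {
  lines <- c(
    "! comment",
    phen_header,
    "S000029075\tCDC28\tAPO:0000147\tAPO:0000004\t\t",
    "S000029075\tCDC28\tAPO:0000024\tAPO:0000005\t\t",
    "S000029075\tCDC28\tAPO:0000253\tAPO:0000250\t\t",
    "S000000649\tENA1\tAPO:0000089\tAPO:0000003\tCHEBI:26710\t"
  )
  anns <- read_phenotype_annotations(lines)
  expect_equal(nrow(anns), 4L)
  s75 <- anns[anns$genotype_id == "S000029075", ]
  expect_equal(nrow(s75), 3L)
  expect_true(all(is.na(s75$chemical)))
  expect_equal(anns$chemical[anns$genotype_id == "S000000649"],
               "CHEBI:26710")
  # header-only file gives an empty table
  expect_equal(nrow(read_phenotype_annotations(phen_header)), 0L)
})

test_that("annotation reader errors carry line numbers", {
  bad_cols <- c(phen_header, "S1\tG1\tAPO:0000147\tAPO:0000004")
  expect_error(read_phenotype_annotations(bad_cols), "line 2")
  bad_curie <- c(phen_header,
                 "S1\tG1\tnot-a-curie\tAPO:0000004\t\t")
  expect_error(read_phenotype_annotations(bad_curie),
               "line 2.*not a CURIE")
})

test_that("gene-GO reader validates aspects and preserves duplicates", {
  goa <- read_gene_go_annotations(
    c("gene_id\tgo_id\taspect",
      "CLN3\tGO:0000080\tP",
      "CLN3\tGO:0000080\tP")
  )
  expect_equal(nrow(goa), 2L)  # deduplication is the comparator's job
  expect_equal(goa$aspect[1], "P")
  expect_equal(nrow(read_gene_go_annotations("gene_id\tgo_id\taspect")),
               0L)
  expect_error(
    read_gene_go_annotations(c("gene_id\tgo_id\taspect",
                               "CLN3\tGO:0000080\tX")),
    "line 2.*unknown aspect"
  )
})

test_that("annotation reader is total on well-formed files", {
  bench <- simulate_benchmark(5L, 0.5, 7L)
  text <- write_phenotype_annotations(bench$phenotypes)
  back <- read_phenotype_annotations(text)
  expect_equal(nrow(back), nrow(bench$phenotypes))
  expect_equal(back$observable, bench$phenotypes$observable)
})

test_that("merging ontologies rejects duplicate CURIEs", {
  expect_error(merge_ontologies(fx$mini_go, fx$mini_go),
               "duplicate CURIE")
  merged <- merge_ontologies(fx$mini_go, fx$mini_pato)
  expect_length(merged$terms,
                length(fx$mini_go$terms) + length(fx$mini_pato$terms))
})
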