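test_that("GO classes are extracted from expressions, including during fillers", {
  heat <- formalize_annotation(fx_anns[1, ], fx_all)
  arrest <- formalize_annotation(fx_anns[3, ], fx_all)
  expect_equal(extract_go_terms(list(heat, arrest)),
               c("GO:0009408", "GO:0022402"))
  # PATO/ChEBI-only expressions contribute nothing
  no_go <- ce_and(ce_atom("PATO:0001457"),
                  ce_some("towards", ce_atom("CHEBI:26710")))
  expect_length(extract_go_terms(no_go), 0L)
  # planted atoms in nested during/towards positions are all found
  nested <- ce_some(
    "phenotype-of",
    ce_some("has-part",
            ce_and(ce_atom("GO:0005623"),
                   ce_some("has-quality",
                           ce_and(ce_atom("PATO:0000117"),
                                  ce_some("towards", ce_atom("GO:0016301")))),
                   ce_some("during", ce_atom("GO:0031576"))))
  )
  expect_equal(extract_go_terms(nested),
               c("GO:0005623", "GO:0016301", "GO:0031576"))
})

test_that("perfect predictions give 100% recovery and no candidates", {
  goa <- data.frame(gene_id = c("G1", "G1", "G2"),
                    go_id = c("GO:0009408", "GO:0016301", "GO:0005618"),
                    aspect = c("P", "F", "C"),
                    stringsAsFactors = FALSE)
  predicted <- data.frame(gene_id = goa$gene_id, go_id = goa$go_id,
                          stringsAsFactors = FALSE)
  rep <- compare_to_goa(predicted, goa, fx_all)
  expect_equal(rep$counts$percentage, c(100, 100, 100))
  expect_equal(nrow(rep$candidates), 0L)
})

test_that("ancestor rule matches in both directions; exact rule does not", {
  goa <- data.frame(gene_id = "G1", go_id = "GO:0007049", aspect = "P",
                    stringsAsFactors = FALSE)
  pred <- data.frame(gene_id = "G1", go_id = "GO:0022402",
                     stringsAsFactors = FALSE)
  # predicted term is a part_of descendant of the annotated term
  expect_equal(compare_to_goa(pred, goa, fx_all)$counts$recovered[1], 1L)
  expect_equal(
    compare_to_goa(pred, goa, fx_all, match = "exact")$counts$recovered[1],
    0L
  )
  # ancestor direction: predicted high-level term recovers a specific one
  goa2 <- data.frame(gene_id = "G1", go_id = "GO:0000080", aspect = "P",
                     stringsAsFactors = FALSE)
  pred2 <- data.frame(gene_id = "G1", go_id = "GO:0009987",
                      stringsAsFactors = FALSE)
  expect_equal(compare_to_goa(pred2, goa2, fx_all)$counts$recovered[1], 1L)
})

test_that("the CLN3 scenario yields a novel candidate annotation", {
  rep <- recover_functions(fx_anns, fx_goa, fx_all)
  cand <- rep$candidates
  hit <- cand[cand$gene_id == "CLN3" & cand$go_id == "GO:0000080", ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$genotypes, "S000031234")
  # CDC28's cell-cycle prediction recovered its cell-cycle GO line
  expect_equal(rep$counts$recovered[rep$counts$aspect == "P"], 1L)
  # genes with GOA but no predictions count toward totals only
  extra_goa <- rbind(fx_goa,
                     data.frame(gene_id = "NOPRED", go_id = "GO:0005634",
                                aspect = "C", stringsAsFactors = FALSE))
  rep2 <- recover_functions(fx_anns, extra_goa, fx_all)
  expect_equal(rep2$counts$total[rep2$counts$aspect == "C"],
               rep$counts$total[rep$counts$aspect == "C"] + 1L)
  expect_equal(rep2$counts$recovered[rep2$counts$aspect == "C"],
               rep$counts$recovered[rep$counts$aspect == "C"])
})

test_that("recovery is invariant to duplicated GOA lines", {
  rep1 <- recover_functions(fx_anns, fx_goa, fx_all)
  rep2 <- recover_functions(fx_anns, rbind(fx_goa, fx_goa), fx_all)
  expect_identical(rep1$counts, rep2$counts)
})

test_that("adding predictions never decreases recovered counts", {
  goa <- fx_goa
  base <- data.frame(gene_id = "CDC28", go_id = "GO:0022402",
                     stringsAsFactors = FALSE)
  more <- rbind(base,
                data.frame(gene_id = "CDC28", go_id = "GO:0016301",
                           stringsAsFactors = FALSE))
  r_base <- compare_to_goa(base, goa, fx_all)$counts$recovered
  r_more <- compare_to_goa(more, goa, fx_all)$counts$recovered
  expect_true(all(r_more >= r_base))
})

test_that("reports serialize with NA for empty aspects and round-trip", {
  empty <- compare_to_goa(
    data.frame(gene_id = character(0), go_id = character(0)),
    data.frame(gene_id = character(0), go_id = character(0),
               aspect = character(0)),
    fx_all
  )
  text <- write_report(empty)
  expect_match(text, "aspect\tP\t0/0\tNA", fixed = TRUE)
  rep <- recover_functions(fx_anns, fx_goa, fx_all)
  back <- read_report(write_report(rep))
  expect_equal(back$counts$recovered, rep$counts$recovered)
  expect_equal(back$counts$total, rep$counts$total)
  expect_equal(round(back$counts$percentage, 1),
               round(rep$counts$percentage, 1))
  expect_equal(back$candidates$gene_id, rep$candidates$gene_id)
  expect_equal(back$candidates$go_id, rep$candidates$go_id)
})

test_that("pipeline recovery equals the generator's planted ground truth", {
  for (cfg in list(list(n = 50L, rate = 0.3, seed = 11L),
                   list(n = 80L, rate = 0.7, seed = 12L))) {
    bench <- simulate_benchmark(cfg$n, cfg$rate, cfg$seed)
    rep <- recover_functions(bench$phenotypes, bench$goa, fx_all)
    expect_identical(rep$counts[, c("aspect", "recovered", "total")],
                     bench$expected[, c("aspect", "recovered", "total")],
                     info = paste("rate", cfg$rate))
  }
})

test_that("estimated recovery converges to the planted rate", {
  # rising n tightens the estimate around the planted rate
  b_small <- simulate_benchmark(200L, 0.5, 42L)
  rep_small <- recover_functions(b_small$phenotypes, b_small$goa, fx_all)
  b_big <- simulate_benchmark(2000L, 0.5, 42L)
  rep_big <- recover_functions(b_big$phenotypes, b_big$goa, fx_all)
  # 99% binomial envelopes at the two sample sizes (400 and 4000 lines
  # per aspect)
  for (k in 1:3) {
    n_small <- rep_small$counts$total[k]
    expect_lt(abs(rep_small$counts$percentage[k] - 50),
              100 * 2.576 * sqrt(0.25 / n_small))
    n_big <- rep_big$counts$total[k]
    expect_lt(abs(rep_big$counts$percentage[k] - 50),
              100 * 2.576 * sqrt(0.25 / n_big))
  }
})
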