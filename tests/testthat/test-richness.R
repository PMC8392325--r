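anc <- ancestral_gene_order()

single_family_catalog <- function() {
  ord <- parse_gene_order(paste0(
    "CR-~trnQ-trnI-trnM-ND2-trnW-~trnC-~trnY-COI-trnL2-COII-trnK-trnD-",
    "ATP8-ATP6-COIII-trnG-ND3-trnA-trnR-trnN-trnS1-trnE-~trnF-~ND5-~trnH-",
    "~ND4-~ND4L-trnT-~trnP-ND6-CYTB-trnS2-~ND1-~trnL1-~rrnL-~trnV-~rrnS"))
  catalog(list(catalog_record("only", "X", "Famx", 1L, ord)))
}

test_that("a lone rearranged record scores 100% in its unit", {
  idx <- build_index(single_family_catalog())
  expect_length(idx$union[["1"]], 1L)
  expect_length(idx$by_family[["1"]][["Famx"]], 1L)
  tab <- richness(idx)
  expect_equal(tab[["1"]], 1)
  expect_equal(tab[["whole"]], 1)
  expect_true(is.na(tab[["2"]]))
})

test_that("the packaged catalog yields the published union sizes", {
  cat0 <- heteroptera_catalog()
  idx <- build_index(cat0)
  expect_length(idx$union[["whole"]], 20L)
  expect_length(idx$union[["4"]], 4L)
  expect_length(idx$union[["1"]], 7L)
  # numerators summed over families never fall below the union size
  for (cl in idx$columns) {
    numer <- sum(lengths(idx$by_family[[cl]]))
    expect_gte(numer, length(idx$union[[cl]]))
  }
})

test_that("shared arrangements count once in the union, once per family", {
  cat0 <- heteroptera_catalog()
  idx <- build_index(cat0)
  # trnI loss is shared between Nabidae and Reduviidae
  shared <- intersect(idx$by_family[["1"]][["Nabidae"]],
                      idx$by_family[["1"]][["Reduviidae"]])
  expect_length(shared, 1L)
  expect_equal(sum(idx$union[["1"]] == shared), 1L)
})

test_that("survey counts degrade gracefully on an empty catalog", {
  empty <- catalog(list())
  sv <- survey_counts(empty)
  expect_equal(sv$n_distinct_orders, 1L)
  expect_equal(sv$n_rearranged_orders, 0L)
  expect_equal(sv$n_rearranged_species, 0L)
  expect_equal(sv$n_families_with_rearrangement, 0L)
  expect_length(build_index(empty)$union[["whole"]], 0L)
})

test_that("block diversity is zero without rearrangements", {
  ord <- anc
  ord$taxon <- "plain"
  cat1 <- catalog(list(catalog_record("plain", "X", "F", 3L, ord)))
  expect_equal(unname(block_diversity(cat1)), c(0L, 0L, 0L))
})

test_that("a globally novel arrangement raises one numerator and all denominators", {
  plan <- random_catalog_plan(42)
  g <- generate_catalog(plan)
  idx0 <- build_index(g$catalog)
  # craft a unit-4 arrangement not present in the plan: a duplication
  sym <- anc$symbol; str <- anc$strand
  i <- which(sym == "trnT")
  sym <- append(sym, "trnT", after = i)
  str <- append(str, "+", after = i)
  novel <- gene_order(sym, str, taxon = "novel")
  recs <- c(g$catalog$records,
            list(catalog_record("novel", "X", plan$families[1], 1L, novel)))
  idx1 <- build_index(catalog(recs))
  expect_equal(length(idx1$union[["4"]]), length(idx0$union[["4"]]) + 1L)
  expect_equal(length(idx1$union[["whole"]]),
               length(idx0$union[["whole"]]) + 1L)
  f1 <- plan$families[1]
  expect_equal(length(idx1$by_family[["4"]][[f1]]),
               length(idx0$by_family[["4"]][[f1]]) + 1L)
})

test_that("percentages render with one decimal, half away from zero", {
  expect_equal(percent1(3 / 7), 42.9)
  expect_equal(percent1(2 / 7), 28.6)
  expect_equal(percent1(1 / 7), 14.3)
  expect_equal(percent1(0.005), 0.5)
  expect_equal(percent1(0.5), 50)
  tab <- richness(build_index(single_family_catalog()))
  out <- format_richness(tab)
  expect_equal(out[["whole"]], "100.0%")
  expect_equal(out[["2"]], "-")
})
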