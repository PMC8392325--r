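anc <- ancestral_gene_order()
units <- unit_definitions()

plemur_order <- function() {
  parse_gene_order(paste0(
    "CR-trnI-trnW-~trnQ-trnM-ND2-~trnC-~trnY-COI-trnL2-COII-trnK-trnD-",
    "ATP8-ATP6-COIII-trnG-ND3-trnA-trnR-trnN-trnS1-trnE-~trnF-~ND5-~trnH-",
    "~ND4-~ND4L-trnT-~trnP-ND6-CYTB-trnS2-~ND1-~trnL1-~rrnL-~trnV-~rrnS"),
    taxon = "P. lemur")
}

test_that("the ancestral order classifies as unrearranged", {
  call <- classify_events(anc, anc)
  expect_false(call$rearranged)
  expect_length(call$event_types, 0L)
  expect_length(call$moved_genes, 0L)
  expect_length(call$affected_units, 0L)
})

test_that("the trnW translocation is called with units 1 and 2 affected", {
  call <- classify_events(plemur_order(), anc)
  expect_equal(call$event_types, "translocation")
  expect_equal(call$moved_genes, "trnW")
  expect_equal(call$affected_units, c("1", "2"))
})

test_that("tandem duplication of trnF is duplication only", {
  ord <- parse_gene_order(paste0(
    "CR-trnI-~trnQ-trnM-ND2-trnW-~trnC-~trnY-COI-trnL2-COII-trnK-trnD-",
    "ATP8-ATP6-COIII-trnG-ND3-trnA-trnR-trnN-trnS1-trnE-~trnF-~trnF-~ND5-",
    "~trnH-~ND4-~ND4L-trnT-~trnP-ND6-CYTB-trnS2-~ND1-~trnL1-~rrnL-~trnV-",
    "~rrnS"))
  call <- classify_events(ord, anc)
  expect_equal(call$event_types, "duplication")
  expect_equal(call$duplicated_genes, "trnF")
  expect_length(call$moved_genes, 0L)
})

test_that("an uncertain absence is unresolved, not a loss", {
  cat0 <- heteroptera_catalog()
  ih <- Filter(function(r) r$taxon == "Ischnobaenella hainana",
               cat0$records)[[1]]
  call <- classify_events(ih$order, anc)
  expect_equal(call$event_types, "translocation")
  expect_equal(call$moved_genes, "trnV")
  expect_equal(call$unresolved_genes, "trnY")
  expect_length(call$lost_genes, 0L)
})

test_that("classification is invariant under rotation of the input", {
  ord <- plemur_order()
  ref <- classify_events(ord, anc)
  for (k in c(3L, 17L, 30L)) {
    rot <- rotate_order(ord, k)
    call <- classify_events(rot, anc)
    for (f in c("event_types", "moved_genes", "duplicated_genes",
                "lost_genes", "inverted_genes", "affected_units")) {
      expect_identical(call[[f]], ref[[f]])
    }
  }
})

test_that("unit signatures capture the occupied window", {
  sig <- unit_signature(anc, units[["1"]], anc)
  expect_equal(sig$tokens, c("trnI", "~trnQ", "trnM"))
  expect_false(is_unit_rearranged(sig, anc))

  sig <- unit_signature(plemur_order(), units[["1"]], anc)
  expect_equal(sig$tokens, c("trnI", "trnW", "~trnQ", "trnM"))
  expect_true(is_unit_rearranged(sig, anc))

  a1 <- parse_gene_order(paste0(
    "CR-~trnQ-trnI-trnM-ND2-trnW-~trnC-~trnY-COI-trnL2-COII-trnK-trnD-",
    "ATP8-ATP6-COIII-trnG-ND3-trnA-trnR-trnN-trnS1-trnE-~trnF-~ND5-~trnH-",
    "~ND4-~ND4L-trnT-~trnP-ND6-CYTB-trnS2-~ND1-~trnL1-~rrnL-~trnV-~rrnS"))
  sig <- unit_signature(a1, units[["1"]], anc)
  expect_equal(sig$tokens, c("~trnQ", "trnI", "trnM"))
  expect_true(is_unit_rearranged(sig, anc))
})

test_that("a strand flip alone makes a unit rearranged", {
  flipped <- anc
  i <- which(flipped$symbol == "trnW")
  flipped$strand[i] <- "-"
  sig <- unit_signature(flipped, units[["2"]], anc)
  expect_true(is_unit_rearranged(sig, anc))
  call <- classify_events(flipped, anc)
  expect_equal(call$inverted_genes, "trnW")
  expect_true("inversion" %in% call$event_types)
})

test_that("units falling wholly in unsequenced regions are unknown", {
  cat0 <- heteroptera_catalog()
  cer <- Filter(function(r) "Ceratocombidae" %in% r$families,
                cat0$records)[[1]]
  sig5 <- unit_signature(cer$order, units[["5"]], anc)
  expect_true(sig5$unknown)
  expect_false(is_unit_rearranged(sig5, anc))
  expect_true(is.na(signature_key(sig5)))
  # ... while the relocated trnV unit is visible and rearranged
  sig6 <- unit_signature(cer$order, units[["6"]], anc)
  expect_false(sig6$unknown)
  expect_true(is_unit_rearranged(sig6, anc))
})

test_that("affected units agree with per-unit rearrangement tests", {
  cat0 <- heteroptera_catalog()
  for (rec in cat0$records) {
    call <- classify_events(rec$order, anc)
    by_unit <- names(Filter(isTRUE, lapply(units, function(u) {
      is_unit_rearranged(unit_signature(rec$order, u, anc), anc)
    })))
    expect_identical(call$affected_units, by_unit)
  }
})

test_that("orders sharing no genes with the ancestral order are rejected", {
  expect_error(classify_events(parse_gene_order("NCR-NCR"), anc),
               "no comparison basis")
})
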