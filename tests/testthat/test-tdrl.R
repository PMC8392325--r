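anc <- ancestral_gene_order()

plemur_target <- function() {
  parse_gene_order(paste0(
    "CR-trnI-trnW-~trnQ-trnM-ND2-~trnC-~trnY-COI-trnL2-COII-trnK-trnD-",
    "ATP8-ATP6-COIII-trnG-ND3-trnA-trnR-trnN-trnS1-trnE-~trnF-~ND5-~trnH-",
    "~ND4-~ND4L-trnT-~trnP-ND6-CYTB-trnS2-~ND1-~trnL1-~rrnL-~trnV-~rrnS"))
}

ihainana_target <- function() {
  parse_gene_order(paste0(
    "CR-~trnV-trnI-~trnQ-trnM-ND2-trnW-~trnC-~trnY-COI-trnL2-COII-trnK-",
    "trnD-ATP8-ATP6-COIII-trnG-ND3-trnA-trnR-trnN-trnS1-trnE-~trnF-~ND5-",
    "~trnH-~ND4-~ND4L-trnT-~trnP-ND6-CYTB-trnS2-~ND1-~trnL1-~rrnL-~rrnS"))
}

test_that("applying the published duplication-loss patterns works", {
  # duplicate trnQ-trnM-ND2-trnW; lose Q,M,ND2 from copy 1 and W from copy 2
  step <- tdrl_step(3L, 4L, c("first", "first", "first", "second"))
  got <- apply_tdrl(anc, step)
  expect_true(gene_order_equal(got, plemur_target()))

  # duplicate trnV-rrnS-CR (wrapping); lose V copy 1, rrnS and CR copy 2
  step <- tdrl_step(37L, 3L, c("first", "second", "second"))
  got <- apply_tdrl(anc, step)
  expect_true(gene_order_equal(got, ihainana_target()))

  # losing the whole second copy is a no-op
  step <- tdrl_step(5L, 6L, rep("second", 6L))
  expect_true(gene_order_equal(apply_tdrl(anc, step), anc))
})

test_that("TDRL never touches strands and conserves gene content", {
  for (seed in 1:25) {
    ord <- random_toy_order(seed, n_min = 6L, n_max = 12L)
    set.seed(seed)
    n <- length(ord)
    len <- sample(1:(n - 1L), 1L)
    step <- tdrl_step(sample(n, 1L), len,
                      sample(c("first", "second"), len, replace = TRUE))
    got <- apply_tdrl(ord, step)
    expect_setequal(unique(got$symbol), unique(ord$symbol))
    before <- stats::setNames(ord$strand, ord$symbol)
    expect_true(all(got$strand == before[got$symbol]))
  }
})

test_that("full gene loss needs the extension flag", {
  expect_error(
    apply_tdrl(anc, tdrl_step(2L, 1L, "both")),
    "gene extinction not permitted")
  got <- apply_tdrl(anc, tdrl_step(2L, 1L, "both"), allow_loss = TRUE)
  expect_equal(got$absent, "trnI")
  expect_false("trnI" %in% got$symbol)
})

test_that("single-step enumeration matches the brute-force oracle", {
  expect_length(enumerate_single_tdrl(anc, 0L), 0L)

  genes3 <- c("trnA", "trnC", "trnD")
  got <- enumerate_single_tdrl(gene_order(genes3), 2L)
  got_norm <- sort(unname(vapply(got, function(o) norm_circle(o$symbol),
                                 "")))
  expect_identical(got_norm, brute_single_tdrl(genes3, 2L))
  expect_true(norm_circle(c("trnA", "trnC", "trnD")) %in% got_norm)
  expect_true(norm_circle(c("trnC", "trnA", "trnD")) %in% got_norm)

  genes5 <- c("trnA", "trnC", "trnD", "trnE", "trnF")
  got <- enumerate_single_tdrl(gene_order(genes5), 4L)
  expect_identical(
    sort(unname(vapply(got, function(o) norm_circle(o$symbol), ""))),
    brute_single_tdrl(genes5, 4L))
})

test_that("the trnW translocation is reachable in one step", {
  reach <- enumerate_single_tdrl(anc, 6L)
  expect_true(gene_order_key(plemur_target()) %in% names(reach))
})

test_that("search handles identity, bad parameters and unreachable targets", {
  sc <- search_scenarios(anc, anc)
  expect_length(sc, 1L)
  expect_length(sc[[1]]$steps, 0L)
  expect_error(search_scenarios(anc, anc, max_steps = 0L), "max_steps")
  expect_error(search_scenarios(anc, anc, max_segment = 0L), "max_segment")

  # inversions are outside the model: flipping a strand is unreachable
  flipped <- anc
  flipped$strand[flipped$symbol == "trnW"] <- "-"
  expect_length(
    search_scenarios(anc, flipped, max_steps = 1L, max_segment = 4L), 0L)
})

test_that("search returns replay-sound minimal scenarios", {
  src <- gene_order(c("trnA", "trnC", "trnD", "trnE", "trnF", "trnG"))
  set.seed(8)
  for (rep in 1:10) {
    len1 <- sample(3L, 1L)
    s1 <- tdrl_step(sample(6L, 1L), len1,
                    sample(c("first", "second"), len1, replace = TRUE))
    mid <- apply_tdrl(src, s1)
    len2 <- sample(3L, 1L)
    s2 <- tdrl_step(sample(6L, 1L), len2,
                    sample(c("first", "second"), len2, replace = TRUE))
    tgt <- apply_tdrl(mid, s2)
    sc <- search_scenarios(src, tgt, max_steps = 2L, max_segment = 5L)
    expect_gt(length(sc), 0L)
    expect_lte(length(sc[[1]]$steps), 2L)
    for (s in sc) {
      expect_true(gene_order_equal(replay_scenario(s), tgt))
    }
    # if the target is single-step reachable, search must say so
    one <- names(enumerate_single_tdrl(src, 5L))
    if (gene_order_key(tgt) %in% one) {
      expect_lte(length(sc[[1]]$steps), 1L)
    }
  }
})

test_that("remnant prediction traces deleted copies to final adjacencies", {
  # empty scenario: no remnants
  sc0 <- search_scenarios(anc, anc)[[1]]
  expect_equal(nrow(predict_remnants(sc0)$sites), 0L)

  sc <- search_scenarios(anc, plemur_target(), max_steps = 1L,
                         max_segment = 6L)
  segs <- vapply(sc, function(s) {
    paste(s$steps[[1]]$segment_genes, collapse = "-")
  }, "")
  broad <- sc[[which(segs == "trnI-~trnQ-trnM-ND2-trnW")]]
  sites <- predict_remnants(broad, plemur_target())$sites
  expect_setequal(paste(sites$left, sites$right),
                  c("trnI trnW", "trnW ~trnQ", "ND2 ~trnC"))

  strict <- sc[[which(segs == "~trnQ-trnM-ND2-trnW")]]
  sites <- predict_remnants(strict, plemur_target())$sites
  # the strict boundary cannot explain a trnW/trnQ spacer
  expect_setequal(paste(sites$left, sites$right),
                  c("trnI trnW", "ND2 ~trnC"))

  sc2 <- search_scenarios(anc, ihainana_target(), max_steps = 1L,
                          max_segment = 6L)
  segs2 <- vapply(sc2, function(s) {
    paste(s$steps[[1]]$segment_genes, collapse = "-")
  }, "")
  vdup <- sc2[[which(segs2 == "~trnV-~rrnS-CR")]]
  sites2 <- predict_remnants(vdup, ihainana_target())$sites
  expect_setequal(paste(sites2$left, sites2$right),
                  c("~rrnL ~rrnS", "~trnV trnI"))

  # replay verification rejects a scenario for the wrong target
  expect_error(predict_remnants(broad, ihainana_target()),
               "unverified scenario")
})
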