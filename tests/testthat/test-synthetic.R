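anc <- ancestral_gene_order()

test_that("simulated evolution is seed-deterministic", {
  p <- evolution_plan(2L, seed = 31L)
  a <- simulate_tdrl_evolution(anc, p)
  b <- simulate_tdrl_evolution(anc, p)
  expect_true(gene_order_equal(a$order, b$order))
  expect_identical(
    lapply(a$scenario$steps, `[`, c("start", "len", "losses")),
    lapply(b$scenario$steps, `[`, c("start", "len", "losses")))
})

test_that("zero events return the ancestral order and an empty scenario", {
  sim <- simulate_tdrl_evolution(anc, evolution_plan(0L, seed = 1L))
  expect_true(gene_order_equal(sim$order, anc))
  expect_length(sim$scenario$steps, 0L)
})

test_that("single simulated events land in the one-step reachable set", {
  reach <- names(enumerate_single_tdrl(anc, 4L))
  for (seed in 1:10) {
    sim <- simulate_tdrl_evolution(
      anc, evolution_plan(1L, max_segment = 4L, seed = seed))
    expect_true(gene_order_key(sim$order) %in% reach)
    expect_true(gene_order_equal(replay_scenario(sim$scenario), sim$order))
    # an event is a real event: the order changed
    expect_false(gene_order_equal(sim$order, anc))
  }
})

test_that("simulation conserves gene content without the loss extension", {
  for (seed in 1:10) {
    sim <- simulate_tdrl_evolution(
      anc, evolution_plan(2L, max_segment = 5L, seed = seed))
    expect_setequal(unique(sim$order$symbol), unique(anc$symbol))
    expect_length(sim$order$absent, 0L)
  }
})

test_that("generated catalogs reproduce their planted richness", {
  units <- unit_definitions()
  # a plan shaped like the published survey: 11 families, one arrangement
  # shared across three of them
  fams <- paste0("Fam", 1:11)
  arr <- list(
    list(unit = "1", perm = c("trnQ", "trnI", "trnM")),
    list(unit = "1", perm = c("trnM", "trnI", "trnQ")),
    list(unit = "4", perm = c("trnP", "trnT")),
    list(unit = "6", perm = c("rrnS", "trnV", "rrnL")))
  m <- matrix(FALSE, 11, 4)
  m[1:3, 1] <- TRUE          # shared across three families
  m[4, 2] <- TRUE
  m[5:11, 3] <- TRUE
  m[5, 4] <- TRUE
  plan <- catalog_plan(fams, arr, m)
  g <- generate_catalog(plan)
  got <- richness(build_index(g$catalog))
  expect_equal(got, g$planted, ignore_attr = TRUE)
  # shared arrangements are byte-identical across families
  k1 <- vapply(g$catalog$records[1:3],
               function(r) gene_order_key(r$order), "")
  expect_length(unique(k1), 1L)
})

test_that("families sharing every arrangement have identical rows", {
  arr <- list(list(unit = "4", perm = c("trnP", "trnT")),
              list(unit = "2", perm = c("trnY", "trnC", "trnW")))
  m <- matrix(TRUE, 2, 2)
  plan <- catalog_plan(c("A", "B"), arr, m)
  tab <- richness(build_index(generate_catalog(plan)$catalog))
  expect_equal(unlist(tab[1, -1]), unlist(tab[2, -1]),
               ignore_attr = TRUE)
})

test_that("inconsistent plans fail at construction", {
  arr <- list(list(unit = "4", perm = c("trnP", "trnT")))
  expect_error(catalog_plan("A", arr, matrix(FALSE, 1, 1)),
               "carried by no family")
  expect_error(
    catalog_plan("A", list(list(unit = "4", perm = c("trnT", "trnP"))),
                 matrix(TRUE, 1, 1)),
    "differ from the ancestral")
  expect_error(
    catalog_plan("A", list(list(unit = "4", perm = c("trnT", "trnT"))),
                 matrix(TRUE, 1, 1)),
    "exactly the members")
  arr2 <- list(list(unit = "4", perm = c("trnP", "trnT")),
               list(unit = "4", perm = c("trnP", "trnT")))
  expect_error(catalog_plan("A", arr2, matrix(TRUE, 1, 2)),
               "pairwise distinct")
})

test_that("random plans are always consistent and recoverable", {
  for (seed in 101:110) {
    plan <- random_catalog_plan(seed)
    g <- generate_catalog(plan)
    got <- richness(build_index(g$catalog))
    expect_equal(got, g$planted, ignore_attr = TRUE)
  }
})

test_that("random sequences hit their composition targets", {
  expect_identical(random_sequence(20L, 1, 1, seed = 2L),
                   strrep("A", 20L))
  expect_identical(random_sequence(500L, 0.5, 0.1, -0.1, seed = 9L),
                   random_sequence(500L, 0.5, 0.1, -0.1, seed = 9L))
  expect_error(random_sequence(10L, 0.5, at_skew = 1.5), "infeasible")
  expect_error(random_sequence(0L, 0.5), "length")

  x <- random_sequence(1e5L, 0.756, 0.15, -0.25, seed = 4L)
  cc <- composition(x)
  se_at <- sqrt(0.756 * (1 - 0.756) / 1e5)
  expect_lt(abs(cc$at_content - 0.756), 3 * se_at)
  expect_lt(abs(cc$at_skew - 0.15), 0.02)
  expect_lt(abs(cc$gc_skew + 0.25), 0.02)
})
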