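# Neighborhood lookup, the hypergeometric upper tail, and the feature matrix.
# (the exhaustive enumeration oracle lives in helper-oracles.R)

test_that("neighbors returns direct partners, excludes self, honors scores", {
  net <- toy_network()
  expect_setequal(neighbors(net, "b"), c("a", "c"))
  expect_identical(neighbors(net, "d"), character(0))
  expect_error(neighbors(net, "zz"), "zz")

  scored <- gene_network(rbind(c("a", "b"), c("a", "c")),
                         scores = c(700, 150))
  expect_setequal(neighbors(scored, "a", min_score = 400), "b")
  expect_setequal(neighbors(scored, "a", min_score = 0), c("b", "c"))
})

test_that("hypergeometric upper tail matches hand-enumerated draws", {
  expect_equal(hypergeom_upper_tail(10, 4, 3, 2), 40 / 120, tolerance = 1e-14)
  expect_equal(hypergeom_upper_tail(10, 4, 3, 3), 4 / 120, tolerance = 1e-14)
  expect_equal(hypergeom_upper_tail(10, 4, 3, 0), 1.0)
  expect_equal(hypergeom_upper_tail(50, 50, 7, 7), 1.0)  # M = N forces certainty
  expect_error(hypergeom_upper_tail(10, 11, 3, 1), "exceed")
  expect_error(hypergeom_upper_tail(10, 4, 3, 4), "min")
})

test_that("upper tail is non-decreasing in the overlap direction", {
  for (n in c(3, 6, 9)) {
    m <- 0:min(n, 8)
    p <- hypergeom_upper_tail(rep(20, length(m)), rep(8, length(m)),
                              rep(n, length(m)), m)
    expect_true(all(diff(p) <= 1e-15))
  }
})

test_that("enrichment score transforms and caps p-values", {
  expect_equal(enrichment_score(1), 0)
  expect_equal(enrichment_score(1 / 3), -log10(1 / 3), tolerance = 1e-12)
  expect_equal(enrichment_score(0), 300)      # underflowed p maps to the cap
  expect_equal(enrichment_score(1e-310, cap = 100), 100)
  expect_error(enrichment_score(-0.1), "\\[0, 1\\]")
  expect_error(enrichment_score(1.2), "\\[0, 1\\]")
})

test_that("matrix entries follow the worked example and conventions", {
  em <- build_matrix(toy_catalog(), toy_enrichment_network())
  # gene x: neighbors {g1,g2,g5}, overlap 2 with the 4-gene term, N = 11
  expected_p <- hypergeom_upper_tail(11, 4, 3, 2)
  expect_equal(em$scores["x", "T1"], -log10(expected_p), tolerance = 1e-12)
  # isolated genes get an all-zero row
  expect_true(all(em$scores["g6", ] == 0))
  expect_true(all(em$scores >= 0 & is.finite(em$scores)))
})

test_that("a term annotating the whole universe scores zero everywhere", {
  cat_all <- annotation_catalog("ALL", "BP", list(toy_universe()),
                                universe = toy_universe())
  em <- build_matrix(cat_all, toy_enrichment_network())
  expect_true(all(em$scores == 0))
})

test_that("row values do not depend on gene insertion order", {
  cat <- toy_catalog()
  net <- toy_enrichment_network()
  fwd <- build_matrix(cat, net, genes = c("x", "g1", "g5"))
  rev <- build_matrix(cat, net, genes = c("g5", "g1", "x"))
  for (g in c("x", "g1", "g5")) {
    expect_equal(fwd$scores[g, ], rev$scores[g, ])
  }
})

test_that("universe mismatches are reported with the offending genes", {
  cat <- toy_catalog()
  net <- gene_network(rbind(c("a", "b")), universe = c("a", "b"))
  expect_error(build_matrix(cat, net), "universes differ")
  expect_error(build_matrix(cat, toy_enrichment_network(), genes = "nope"),
               "nope")
})

test_that("feature columns keep catalog order, GO before pathways", {
  cfg <- small_synth_config()
  ds <- generate_dataset(cfg)
  em <- build_matrix(ds$catalog, ds$network)
  expect_identical(colnames(em$scores), ds$catalog$term_id)
  ns <- em$features$namespace
  expect_true(max(which(ns != "PATHWAY")) < min(which(ns == "PATHWAY")))
})
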