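# Synthetic benchmark generator: catalogs, planted networks, file round trips.

test_that("catalog respects configured term counts and sizes", {
  cfg <- synthetic_config(n_genes = 100, n_terms_per_namespace = c(BP = 10),
                          term_size_range = c(5, 5), n_positive = 10,
                          n_causal_terms = 2, seed = 3)
  cat10 <- generate_catalog(cfg)
  expect_length(cat10$term_id, 10)
  expect_true(all(lengths(cat10$genes) == 5))
  expect_true(all(cat10$namespace == "BP"))

  # identical config and seed => identical catalog
  expect_identical(generate_catalog(cfg), cat10)
})

test_that("term sizes are uniform over the configured range", {
  cfg <- synthetic_config(n_genes = 200, n_terms_per_namespace = c(BP = 200),
                          term_size_range = c(5, 15), n_positive = 20,
                          n_causal_terms = 1, seed = 11)
  sizes <- lengths(generate_catalog(cfg)$genes)
  expect_true(all(sizes >= 5 & sizes <= 15))
  expect_gte(mean(sizes), 9)   # uniform mean is 10
  expect_lte(mean(sizes), 11)
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(n_genes = 50, n_positive = 5,
                                term_size_range = c(10, 60)),
               "exceeds n_genes")
  expect_error(synthetic_config(n_positive = 500, n_genes = 100), "n_positive")
  expect_error(synthetic_config(effect_strength = 1.5), "effect_strength")
  expect_error(synthetic_config(n_terms_per_namespace = c(BP = 2),
                                n_causal_terms = 5), "total term count")
})

test_that("network is simple, undirected, and diagonal-free", {
  ds <- generate_dataset(small_synth_config(seed = 5))
  ed <- ds$network$edges
  expect_true(all(ed$gene1 != ed$gene2))
  expect_false(any(duplicated(paste(ed$gene1, ed$gene2))))
  # symmetry: neighbor relation works from both endpoints
  g <- ed$gene1[1]; h <- ed$gene2[1]
  expect_true(h %in% neighbors(ds$network, g))
  expect_true(g %in% neighbors(ds$network, h))
})

test_that("zero effect strength removes any positive/negative asymmetry", {
  cfg <- small_synth_config(seed = 9, effect_strength = 0)
  cat9 <- generate_catalog(cfg)
  some_terms <- cat9$term_id[1:2]
  with_pos <- generate_network(cfg, cat9, positives = cat9$universe[1:30],
                               causal_terms = some_terms)
  without_pos <- generate_network(cfg, cat9, positives = character(0),
                                  causal_terms = some_terms)
  expect_identical(with_pos$edges, without_pos$edges)
})

test_that("planted neighborhoods raise causal-term enrichment for positives", {
  cfg <- synthetic_config(n_genes = 300, mean_degree = 8,
                          effect_strength = 0.9, n_positive = 30,
                          n_causal_terms = 3, seed = 21)
  ds <- generate_dataset(cfg)
  em <- build_matrix(ds$catalog, ds$network)
  causal_scores <- rowMeans(em$scores[, ds$causal_terms, drop = FALSE])
  pos <- em$genes %in% ds$positives
  expect_gt(mean(causal_scores[pos]), mean(causal_scores[!pos]))
})

test_that("datasets round-trip through GMT/edge-list/label files", {
  ds <- generate_dataset(small_synth_config(seed = 2))
  dir <- withr::local_tempdir()
  paths <- write_dataset(ds, dir)
  expect_length(readLines(paths[["catalog"]]),
                length(ds$catalog$term_id))  # one GMT line per term

  back <- read_dataset(dir)
  expect_identical(back$catalog$term_id, ds$catalog$term_id)
  expect_identical(back$catalog$genes, ds$catalog$genes)
  expect_identical(back$catalog$namespace, ds$catalog$namespace)
  expect_identical(back$catalog$universe, ds$catalog$universe)
  expect_identical(back$network$edges, ds$network$edges)
  expect_identical(back$positives, ds$positives)
  expect_identical(back$causal_terms, ds$causal_terms)

  # same seed => byte-identical files
  dir2 <- withr::local_tempdir()
  write_dataset(generate_dataset(small_synth_config(seed = 2)), dir2)
  for (f in basename(paths)) {
    expect_identical(readLines(file.path(dir, f)), readLines(file.path(dir2, f)))
  }
})

test_that("an empty positive set is written with a warning", {
  cfg <- small_synth_config(seed = 4)
  cfg$n_positive <- 0L
  ds <- generate_dataset(cfg)
  dir <- withr::local_tempdir()
  expect_warning(write_dataset(ds, dir), "empty")
  expect_identical(read_gene_list(file.path(dir, "positives.txt")), character(0))
})
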