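# Small in-code fixtures shared across test files.

# triangle a-b, b-c, a-c plus an isolated gene d
toy_network <- function() {
  gene_network(rbind(c("a", "b"), c("b", "c"), c("a", "c")),
               universe = c("a", "b", "c", "d"))
}

# 10-gene universe with one 4-gene term and a gene x whose neighbors are
# {g1, g2, g5}; the enrichment of x against the term is the worked
# hypergeometric example P = 1/3.
toy_universe <- function() c(paste0("g", 1:10), "x")

toy_catalog <- function() {
  annotation_catalog("T1", "BP", list(c("g1", "g2", "g3", "g4")),
                     universe = toy_universe())
}

toy_enrichment_network <- function() {
  gene_network(rbind(c("x", "g1"), c("x", "g2"), c("x", "g5")),
               universe = toy_universe())
}

# labeled noise matrix: n samples, p iid N(0,1) features, balanced labels
noise_data <- function(n = 200, p = 20, seed = 1) {
  set.seed(seed)
  X <- matrix(stats::rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("F", seq_len(p))))
  list(X = X, y = rep(c(0L, 1L), length.out = n)[order(stats::runif(n))])
}

# a quick low-cost synthetic config for pipeline-level tests
small_synth_config <- function(seed = 1, effect_strength = 0.9) {
  synthetic_config(
    n_genes = 150,
    n_terms_per_namespace = c(BP = 8, CC = 3, MF = 3, PATHWAY = 2),
    term_size_range = c(5, 15),
    mean_degree = 6,
    n_positive = 30,
    n_causal_terms = 2,
    effect_strength = effect_strength,
    seed = seed
  )
}

small_boruta_config <- function(seed = 1) {
  boruta_config(n_trees = 150, max_iter = 40, seed = seed)
}
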