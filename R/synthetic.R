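#' Configuration for the synthetic benchmark generator
#'
#' Describes a synthetic study: a gene universe with overlapping term
#' annotations in four namespaces, a sparse background interaction network,
#' and a set of planted positive (disease-associated) genes whose network
#' neighborhoods are enriched for a chosen subset of "causal" terms. The
#' signal is planted through edges, not through direct annotation of the
#' positives, because the feature encoding scores a gene's neighbor set
#' rather than the gene itself.
#'
#' Defaults describe the reference study condition used throughout the test
#' suite: 500 genes, 50 terms (25 BP / 10 CC / 10 MF / 5 PATHWAY), mean
#' background degree 8, 75 positives, and 3 causal BP terms at effect
#' strength 0.9.
#'
#' @param n_genes number of genes in the universe.
#' @param n_terms_per_namespace named integer vector over `BP`, `CC`, `MF`,
#'   `PATHWAY`; omitted namespaces get zero terms.
#' @param term_size_range length-2 integer vector, min/max genes per term
#'   (sampled uniformly).
#' @param mean_degree expected background network degree.
#' @param n_positive number of positive genes.
#' @param n_causal_terms number of signal-carrying terms.
#' @param effect_strength probability in \[0, 1\] that each candidate extra
#'   edge of a positive gene is realized, attaching a member of a causal
#'   term's gene set; at 0 no extra edges exist and positives follow the
#'   same neighbor-generation law as negatives.
#' @param causal_namespace namespace the causal terms are drawn from
#'   (default `"BP"`).
#' @param seed integer RNG seed; identical seeds give bit-identical output.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 500,
                             n_terms_per_namespace = c(BP = 25, CC = 10,
                                                       MF = 10, PATHWAY = 5),
                             term_size_range = c(10, 40),
                             mean_degree = 8,
                             n_positive = 75,
                             n_causal_terms = 3,
                             effect_strength = 0.9,
                             causal_namespace = "BP",
                             seed = 1) {
  assert_count(n_genes, "n_genes", 2L)
  assert_count(n_positive, "n_positive", 0L)
  assert_count(n_causal_terms, "n_causal_terms", 0L)
  if (n_positive >= n_genes) stop("n_positive must be < n_genes")
  if (effect_strength < 0 || effect_strength > 1) {
    stop("effect_strength must lie in [0, 1]")
  }
  n_terms_per_namespace <- n_terms_per_namespace[n_terms_per_namespace > 0]
  bad <- setdiff(names(n_terms_per_namespace), NAMESPACES)
  if (length(bad)) stop("unknown namespace(s): ", paste(bad, collapse = ", "))
  if (length(term_size_range) != 2 || term_size_range[1] > term_size_range[2] ||
      term_size_range[1] < 1) {
    stop("term_size_range must be (min, max) with 1 <= min <= max")
  }
  if (term_size_range[2] > n_genes) {
    stop("term_size_range max exceeds n_genes")
  }
  if (n_causal_terms > sum(n_terms_per_namespace)) {
    stop("n_causal_terms exceeds total term count")
  }
  if (!causal_namespace %in% names(n_terms_per_namespace) && n_causal_terms > 0) {
    stop("causal_namespace has no terms configured")
  }
  if (mean_degree <= 0 || mean_degree > n_genes - 1) {
    stop("mean_degree must lie in (0, n_genes - 1]")
  }
  structure(
    list(n_genes = as.integer(n_genes),
         n_terms_per_namespace = n_terms_per_namespace,
         term_size_range = as.integer(term_size_range),
         mean_degree = mean_degree,
         n_positive = as.integer(n_positive),
         n_causal_terms = as.integer(n_causal_terms),
         effect_strength = effect_strength,
         causal_namespace = causal_namespace,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

gene_ids <- function(n) sprintf("g%04d", seq_len(n))

#' Generate a synthetic annotation catalog
#'
#' Term gene sets are sampled uniformly from the universe with sizes drawn
#' uniformly from `term_size_range`; namespaces are laid out GO-first
#' (BP, CC, MF) and PATHWAY last, fixing the feature-column order.
#'
#' @param cfg a [synthetic_config()].
#' @return an [annotation_catalog()].
#' @export
generate_catalog <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(derive_seed(cfg$seed, "catalog"))
  universe <- gene_ids(cfg$n_genes)
  ns_order <- intersect(NAMESPACES, names(cfg$n_terms_per_namespace))
  term_id <- character(0); namespace <- character(0); genes <- list()
  for (ns in ns_order) {
    k <- cfg$n_terms_per_namespace[[ns]]
    ids <- sprintf("%s%04d", ns, seq_len(k))
    size_pool <- seq(cfg$term_size_range[1], cfg$term_size_range[2])
    sizes <- size_pool[sample.int(length(size_pool), k, replace = TRUE)]
    sets <- lapply(sizes, function(s) sample(universe, s))
    term_id <- c(term_id, ids)
    namespace <- c(namespace, rep(ns, k))
    genes <- c(genes, sets)
  }
  annotation_catalog(term_id, namespace, genes, universe = universe,
                     description = rep("synthetic term", length(term_id)))
}

#' Generate a synthetic interaction network with planted signal
#'
#' The background is an Erdos-Renyi graph with edge probability
#' `mean_degree / (n_genes - 1)`. On top of it, every positive gene is given
#' `mean_degree` candidate extra edges; each candidate is realized with
#' probability `effect_strength`, and a realized edge attaches a uniformly
#' chosen member of a uniformly chosen causal term. At
#' `effect_strength = 0` no candidate is realized, so positives and
#' negatives are exchangeable.
#'
#' @param cfg a [synthetic_config()].
#' @param catalog the catalog supplying the universe and causal gene sets.
#' @param positives character vector of positive gene ids.
#' @param causal_terms character vector of causal term ids.
#' @return a [gene_network()] with STRING-style integer confidence scores.
#' @export
generate_network <- function(cfg, catalog, positives, causal_terms) {
  stopifnot(inherits(cfg, "synthetic_config"),
            inherits(catalog, "annotation_catalog"))
  universe <- catalog$universe
  if (!all(positives %in% universe)) stop("positives must lie in the universe")
  if (!all(causal_terms %in% catalog$term_id)) {
    stop("causal_terms must be catalog terms")
  }
  set.seed(derive_seed(cfg$seed, "network"))
  n <- length(universe)
  p_edge <- cfg$mean_degree / (n - 1)

  # background: Bernoulli over all unordered pairs
  i <- rep(seq_len(n - 1), times = (n - 1):1)
  j <- sequence((n - 1):1) + i
  on <- stats::runif(length(i)) < p_edge
  e1 <- universe[i[on]]
  e2 <- universe[j[on]]

  # planted edges toward causal-term members
  if (length(causal_terms) > 0 && cfg$effect_strength > 0) {
    causal_sets <- catalog$genes[causal_terms]
    for (g in positives) {
      realized <- stats::runif(cfg$mean_degree) < cfg$effect_strength
      for (r in which(realized)) {
        set <- causal_sets[[sample.int(length(causal_sets), 1)]]
        nb <- sample(set, 1)
        if (nb != g) {
          e1 <- c(e1, g)
          e2 <- c(e2, nb)
        }
      }
    }
  }
  scores <- round(stats::runif(length(e1), 150, 999))
  gene_network(cbind(e1, e2), universe = universe, scores = scores)
}

#' Generate a complete labeled synthetic dataset
#'
#' Draws the catalog, the positive gene set, the causal terms (without
#' replacement from the configured causal namespace), and the planted
#' network, all deterministically from `cfg$seed`.
#'
#' @param cfg a [synthetic_config()].
#' @return an object of class `synthetic_dataset`: list with `catalog`,
#'   `network`, `positives`, `causal_terms` and the generating `config`.
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  catalog <- generate_catalog(cfg)
  set.seed(derive_seed(cfg$seed, "labels"))
  positives <- sort(sample(catalog$universe, cfg$n_positive))
  pool <- catalog$term_id[catalog$namespace == cfg$causal_namespace]
  if (cfg$n_causal_terms > length(pool)) {
    stop("not enough terms in causal namespace")
  }
  causal_terms <- sort(sample(pool, cfg$n_causal_terms))
  network <- generate_network(cfg, catalog, positives, causal_terms)
  structure(
    list(catalog = catalog, network = network, positives = positives,
         causal_terms = causal_terms, config = cfg),
    class = "synthetic_dataset"
  )
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("synthetic_dataset:", length(x$catalog$universe), "genes,",
      length(x$positives), "positives,",
      nrow(x$network$edges), "edges,",
      length(x$causal_terms), "causal terms\n")
  invisible(x)
}

#' Write a synthetic dataset to plain-text files
#'
#' Emits the catalog as GMT, the network as a scored edge-list TSV, the
#' positives as a one-gene-per-line label file, and a JSON truth sidecar
#' recording the causal term ids and the full gene universe (the GMT and
#' edge list alone cannot represent isolated, unannotated genes).
#'
#' @param ds a `synthetic_dataset`.
#' @param out_dir output directory (created if needed).
#' @return named character vector of the four file paths, invisibly.
#' @export
write_dataset <- function(ds, out_dir) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    catalog = file.path(out_dir, "catalog.gmt"),
    network = file.path(out_dir, "network.tsv"),
    positives = file.path(out_dir, "positives.txt"),
    truth = file.path(out_dir, "truth.json")
  )
  write_gmt(ds$catalog, paths[["catalog"]])
  write_edge_list(ds$network, paths[["network"]])
  if (length(ds$positives) == 0) {
    warning("writing an empty positive gene list")
  }
  write_gene_list(ds$positives, paths[["positives"]])
  jsonlite::write_json(
    list(causal_terms = ds$causal_terms, universe = ds$catalog$universe),
    paths[["truth"]]
  )
  invisible(paths)
}

#' Read a synthetic dataset written by [write_dataset()]
#' @param dir directory containing `catalog.gmt`, `network.tsv`,
#'   `positives.txt` and `truth.json`.
#' @return a `synthetic_dataset` (without the generating config).
#' @export
read_dataset <- function(dir) {
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  universe <- truth$universe
  catalog <- read_gmt(file.path(dir, "catalog.gmt"), universe = universe)
  network <- read_edge_list(file.path(dir, "network.tsv"), universe = universe)
  positives <- read_gene_list(file.path(dir, "positives.txt"))
  structure(
    list(catalog = catalog, network = network, positives = positives,
         causal_terms = truth$causal_terms, config = NULL),
    class = "synthetic_dataset"
  )
}
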