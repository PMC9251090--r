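#' Annotation catalog: term -> gene-set map
#'
#' An ordered collection of annotation terms (GO-like namespaces BP/CC/MF and
#' a PATHWAY namespace), each mapping to a set of gene identifiers, plus the
#' gene universe used as the population of the hypergeometric tests. The term
#' order is fixed and defines the feature-column order of the enrichment
#' matrix, GO namespaces first, pathways last.
#'
#' @param term_id character vector of unique term identifiers.
#' @param namespace character vector, one of `"BP"`, `"CC"`, `"MF"`,
#'   `"PATHWAY"`, parallel to `term_id`.
#' @param genes list of character vectors, annotated genes per term.
#' @param universe character vector of all gene identifiers forming the test
#'   population; defaults to the union of all annotated genes.
#' @param description optional character vector of term descriptions.
#' @return An object of class `annotation_catalog` with fields `term_id`,
#'   `namespace`, `description`, `genes` (named list) and `universe`.
#' @export
annotation_catalog <- function(term_id, namespace, genes, universe = NULL,
                               description = NULL) {
  term_id <- as.character(term_id)
  namespace <- as.character(namespace)
  if (anyDuplicated(term_id)) stop("term ids must be unique")
  if (length(namespace) != length(term_id) || length(genes) != length(term_id)) {
    stop("term_id, namespace and genes must have equal length")
  }
  bad <- setdiff(unique(namespace), NAMESPACES)
  if (length(bad)) stop("unknown namespace(s): ", paste(bad, collapse = ", "))
  genes <- lapply(genes, function(g) unique(as.character(g)))
  if (any(lengths(genes) == 0)) stop("every term must annotate at least one gene")
  if (is.null(universe)) universe <- sort(unique(unlist(genes)))
  universe <- as.character(universe)
  missing <- setdiff(unique(unlist(genes)), universe)
  if (length(missing)) {
    stop("annotated genes absent from universe: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  names(genes) <- term_id
  structure(
    list(term_id = term_id, namespace = namespace,
         description = description %||% rep("", length(term_id)),
         genes = genes, universe = universe),
    class = "annotation_catalog"
  )
}

#' @export
print.annotation_catalog <- function(x, ...) {
  cat("annotation_catalog:", length(x$term_id), "terms,",
      length(x$universe), "genes in universe\n")
  print(table(factor(x$namespace, levels = NAMESPACES)))
  invisible(x)
}

#' Undirected gene/protein interaction network
#'
#' A simple undirected graph over a gene universe, with optional per-edge
#' confidence scores on the STRING 0-1000 convention. Self-loops are
#' rejected; duplicate (unordered) edges are collapsed, keeping the first
#' score seen.
#'
#' @param edges two-column character matrix or data.frame of endpoints.
#' @param universe character vector of all genes; defaults to the union of
#'   the endpoints. Isolated genes are allowed in the universe.
#' @param scores optional numeric vector of edge scores in \[0, 1000\].
#' @return An object of class `gene_network` with fields `universe`, `edges`
#'   (data.frame `gene1`, `gene2`, `score`) and an adjacency index.
#' @export
gene_network <- function(edges, universe = NULL, scores = NULL) {
  edges <- as.matrix(edges)
  if (ncol(edges) < 2) stop("edges must have two endpoint columns")
  g1 <- as.character(edges[, 1])
  g2 <- as.character(edges[, 2])
  if (any(g1 == g2)) stop("self-loops are not allowed")
  if (!is.null(scores)) {
    scores <- as.numeric(scores)
    if (length(scores) != length(g1)) stop("scores must match edge count")
    if (any(!is.na(scores) & (scores < 0 | scores > 1000))) {
      stop("edge scores must lie in [0, 1000]")
    }
  } else {
    scores <- rep(NA_real_, length(g1))
  }
  a <- pmin(g1, g2)
  b <- pmax(g1, g2)
  keep <- !duplicated(paste(a, b, sep = "\r"))
  ed <- data.frame(gene1 = a[keep], gene2 = b[keep], score = scores[keep],
                   stringsAsFactors = FALSE)
  if (is.null(universe)) universe <- sort(unique(c(ed$gene1, ed$gene2)))
  universe <- as.character(universe)
  outside <- setdiff(unique(c(ed$gene1, ed$gene2)), universe)
  if (length(outside)) {
    stop("edge endpoints absent from universe: ",
         paste(utils::head(outside, 5), collapse = ", "))
  }
  src <- c(ed$gene1, ed$gene2)
  dst <- c(ed$gene2, ed$gene1)
  sc <- c(ed$score, ed$score)
  adj_nb <- split(dst, factor(src, levels = unique(src)))
  adj_sc <- split(sc, factor(src, levels = unique(src)))
  structure(
    list(universe = universe, edges = ed, adj_nb = adj_nb, adj_sc = adj_sc),
    class = "gene_network"
  )
}

#' @export
print.gene_network <- function(x, ...) {
  cat("gene_network:", length(x$universe), "genes,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Direct neighbors of a gene
#'
#' Returns the set of genes sharing an edge with `g` whose score is at least
#' `min_score`. Edges without scores always pass the filter. The gene itself
#' is never a member of its own neighbor set.
#'
#' @param net a [gene_network()].
#' @param g a gene identifier present in the network universe.
#' @param min_score minimum edge confidence score (default 0 = keep all).
#' @return character vector of neighbor gene ids (possibly empty).
#' @export
neighbors <- function(net, g, min_score = 0) {
  stopifnot(inherits(net, "gene_network"))
  if (!g %in% net$universe) stop("gene not in network universe: ", g)
  nb <- net$adj_nb[[g]]
  if (is.null(nb)) return(character(0))
  sc <- net$adj_sc[[g]]
  keep <- is.na(sc) | sc >= min_score
  unique(nb[keep])
}
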