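#' Upper-tail hypergeometric probability
#'
#' Computes `P(X >= m)` where `X` is the number of annotated genes in a
#' neighborhood of size `n` drawn without replacement from a universe of `N`
#' genes of which `M` carry the annotation. This is the one-sided enrichment
#' test behind every feature score: the sum runs from `k = m` up to
#' `min(n, M)` (terms beyond `M` successes are identically zero).
#'
#' All four arguments may be vectors and are recycled; the computation uses
#' the numerically stable survival function of the hypergeometric
#' distribution rather than summing binomial-coefficient ratios.
#'
#' @param N universe size.
#' @param M number of annotated genes in the universe.
#' @param n neighborhood size (draws).
#' @param m observed overlap between neighborhood and annotation set.
#' @return probability in (0, 1].
#' @export
hypergeom_upper_tail <- function(N, M, n, m) {
  vars <- cbind(N = N, M = M, n = n, m = m)
  if (any(is.na(vars)) || any(vars != round(vars)) || any(vars < 0)) {
    stop("N, M, n, m must be nonnegative integers")
  }
  N <- vars[, "N"]; M <- vars[, "M"]; n <- vars[, "n"]; m <- vars[, "m"]
  if (any(M > N) || any(n > N)) stop("M and n must not exceed N")
  if (any(m > pmin(n, M))) stop("m must not exceed min(n, M)")
  p <- stats::phyper(m - 1, M, N - M, n, lower.tail = FALSE)
  unname(pmin(p, 1))
}

#' Enrichment score: -log10 of a p-value, capped
#'
#' Transforms an enrichment p-value into the nonnegative feature score
#' `-log10(p)`. Scores are capped (default 300) so that underflowed
#' p-values (including an exact floating-point zero) still yield a finite
#' feature value.
#'
#' @param p p-value(s) in \[0, 1\]; `p = 0` is treated as underflow and maps
#'   to the cap.
#' @param cap maximum score (default 300).
#' @return nonnegative score(s).
#' @export
enrichment_score <- function(p, cap = 300) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p must lie in [0, 1]")
  }
  out <- ifelse(p == 0, cap, pmin(-log10(p), cap))
  pmax(out, 0)
}

#' Build the genes x terms enrichment-feature matrix
#'
#' Encodes each gene `g` as a vector of enrichment scores: for every term,
#' the `-log10` upper-tail hypergeometric p-value of the overlap between the
#' direct network neighbors of `g` and the term's gene set, with the shared
#' catalog/network universe as the population. Genes with no (passing)
#' neighbors receive an all-zero row. Column order equals catalog term
#' order (GO namespaces first, then pathways).
#'
#' @param catalog an [annotation_catalog()].
#' @param net a [gene_network()] over the same universe.
#' @param genes ordered gene ids to encode (rows); default: whole universe.
#' @param min_score minimum edge confidence to count a neighbor (default 0).
#' @param cap score cap passed to [enrichment_score()].
#' @param include_self if `TRUE`, the gene itself is added to its own
#'   neighbor set before testing (off by default: the neighborhood is the
#'   set of direct neighbors, excluding the gene).
#' @return an object of class `enrichment_matrix`: list with `scores`
#'   (numeric matrix), `genes`, `features` (term_id, namespace) and
#'   `n_universe`.
#' @export
build_matrix <- function(catalog, net, genes = NULL, min_score = 0,
                         cap = 300, include_self = FALSE) {
  stopifnot(inherits(catalog, "annotation_catalog"), inherits(net, "gene_network"))
  if (!setequal(catalog$universe, net$universe)) {
    off <- c(setdiff(catalog$universe, net$universe),
             setdiff(net$universe, catalog$universe))
    stop("catalog and network universes differ; offending genes: ",
         paste(utils::head(off, 10), collapse = ", "))
  }
  universe <- catalog$universe
  if (is.null(genes)) genes <- universe
  genes <- as.character(genes)
  unknown <- setdiff(genes, universe)
  if (length(unknown)) {
    stop("genes outside the universe: ", paste(utils::head(unknown, 10), collapse = ", "))
  }
  N <- length(universe)
  n_terms <- length(catalog$term_id)

  # sparse membership: universe x terms
  ann_i <- match(unlist(catalog$genes, use.names = FALSE), universe)
  ann_j <- rep(seq_len(n_terms), lengths(catalog$genes))
  A <- Matrix::sparseMatrix(i = ann_i, j = ann_j, x = 1,
                            dims = c(N, n_terms))

  # sparse neighborhood indicator: requested genes x universe
  ed <- net$edges
  keep <- is.na(ed$score) | ed$score >= min_score
  ed <- ed[keep, , drop = FALSE]
  src <- c(ed$gene1, ed$gene2)
  dst <- c(ed$gene2, ed$gene1)
  in_rows <- src %in% genes
  gi <- match(src[in_rows], genes)
  gj <- match(dst[in_rows], universe)
  if (include_self) {
    gi <- c(gi, seq_along(genes))
    gj <- c(gj, match(genes, universe))
  }
  B <- Matrix::sparseMatrix(i = gi, j = gj, x = 1,
                            dims = c(length(genes), N))
  B@x[] <- 1  # guard against duplicate accumulation

  m_mat <- as.matrix(B %*% A)
  n_vec <- Matrix::rowSums(B)
  M_vec <- Matrix::colSums(A)

  Mm <- matrix(M_vec, nrow = length(genes), ncol = n_terms, byrow = TRUE)
  nn <- matrix(n_vec, nrow = length(genes), ncol = n_terms)
  logp <- stats::phyper(m_mat - 1, Mm, N - Mm, nn,
                        lower.tail = FALSE, log.p = TRUE)
  scores <- pmin(-logp / log(10), cap)
  scores <- pmax(scores, 0)
  scores[n_vec == 0, ] <- 0
  dimnames(scores) <- list(genes, catalog$term_id)

  structure(
    list(scores = scores, genes = genes,
         features = data.frame(term_id = catalog$term_id,
                               namespace = catalog$namespace,
                               stringsAsFactors = FALSE),
         n_universe = N),
    class = "enrichment_matrix"
  )
}

#' @export
print.enrichment_matrix <- function(x, ...) {
  cat("enrichment_matrix:", length(x$genes), "genes x",
      nrow(x$features), "terms (universe", x$n_universe, "genes)\n")
  invisible(x)
}
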