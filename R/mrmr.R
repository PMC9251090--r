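#' Discretize a continuous feature into three bins
#'
#' Maps values below `mean - t*sd` to category 0, values above `mean + t*sd`
#' to category 2, and the rest to category 1 (sample standard deviation).
#' A constant vector has `sd = 0` and maps entirely to category 1. With
#' `kind = "none"` the input is returned as integer categories unchanged.
#'
#' @param x numeric vector.
#' @param kind `"three-bin-mean-sigma"` (default) or `"none"`.
#' @param t positive threshold multiplier (default 1).
#' @return integer vector of categories in `{0, 1, 2}` (or the input
#'   categories for `kind = "none"`).
#' @export
discretize <- function(x, kind = c("three-bin-mean-sigma", "none"), t = 1) {
  kind <- match.arg(kind)
  if (length(x) == 0) stop("x must be nonempty")
  if (t <= 0) stop("t must be positive")
  if (kind == "none") return(as.integer(x))
  mu <- mean(x)
  s <- stats::sd(x)
  if (is.na(s) || s == 0) return(rep(1L, length(x)))
  out <- rep(1L, length(x))
  out[x < mu - t * s] <- 0L
  out[x > mu + t * s] <- 2L
  out
}

#' Plug-in mutual information between two categorical vectors, in bits
#'
#' `I(a, b) = sum p(x, y) log2( p(x, y) / (p(x) p(y)) )` over the observed
#' joint cells, with the `0 log 0 = 0` convention. Symmetric, nonnegative,
#' and equal to the entropy `H(a)` when `a = b`.
#'
#' @param a,b equal-length category vectors.
#' @return mutual information in bits.
#' @export
mutual_information <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  if (length(a) == 0) stop("vectors must be nonempty")
  joint <- table(a, b) / length(a)
  pa <- rowSums(joint)
  pb <- colSums(joint)
  expected <- outer(pa, pb)
  nz <- joint > 0
  sum(joint[nz] * log2(joint[nz] / expected[nz]))
}

#' Greedy max-relevance min-redundancy feature ranking
#'
#' Ranks features by the mRMR criterion with mutual information estimated
#' on discretized values: the first feature maximizes relevance `I(f; y)`;
#' each subsequent pick maximizes `I(f; y) - mean_{s in S} I(f; s)` (the
#' additive MID criterion; `"MIQ"` divides instead) over the features not
#' yet selected, `S` being the selected set. Ties go to the smaller
#' original column index. All features end up in the list.
#'
#' @param X numeric feature matrix (samples x features).
#' @param y binary labels (used as categories directly).
#' @param scheme discretization passed to [discretize()]: list with `kind`
#'   and `t`.
#' @param criterion `"MID"` (default) or `"MIQ"`.
#' @return object of class `ranked_features`: data.frame with columns
#'   `rank`, `feature_id`, `relevance` (bits), `score` (criterion value at
#'   selection time; equal to the relevance for the first pick).
#' @export
mrmr_rank <- function(X, y, scheme = list(kind = "three-bin-mean-sigma", t = 1),
                      criterion = c("MID", "MIQ")) {
  criterion <- match.arg(criterion)
  X <- as.matrix(X)
  if (ncol(X) < 1) stop("X must have at least one feature")
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  y <- as_binary_labels(y)
  if (nrow(X) != length(y)) stop("rows of X must align with y")
  p <- ncol(X)
  D <- apply(X, 2, discretize, kind = scheme$kind %||% "three-bin-mean-sigma",
             t = scheme$t %||% 1)
  relevance <- apply(D, 2, mutual_information, b = y)

  selected <- integer(0)
  remaining <- seq_len(p)
  red_sum <- rep(0, p)           # sum of I(f; s) over selected s
  scores <- rep(NA_real_, p)
  while (length(remaining) > 0) {
    if (length(selected) == 0) {
      crit <- relevance[remaining]
    } else if (criterion == "MID") {
      crit <- relevance[remaining] - red_sum[remaining] / length(selected)
    } else {
      crit <- relevance[remaining] / pmax(red_sum[remaining] / length(selected), 1e-12)
    }
    # ties (within float tolerance) go to the smallest original column index
    pick <- remaining[which(crit >= max(crit) - 1e-12)[1]]
    scores[pick] <- max(crit)
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
    if (length(remaining) > 0) {
      red_new <- apply(D[, remaining, drop = FALSE], 2,
                       mutual_information, b = D[, pick])
      red_sum[remaining] <- red_sum[remaining] + red_new
    }
  }
  out <- data.frame(
    rank = seq_len(p),
    feature_id = colnames(X)[selected],
    relevance = unname(relevance[selected]),
    score = unname(scores[selected]),
    stringsAsFactors = FALSE
  )
  class(out) <- c("ranked_features", "data.frame")
  out
}

#' Write a ranked feature list as TSV
#' @param rf a `ranked_features` data.frame.
#' @param path output path.
#' @param meta optional data.frame (`term_id`, `namespace`) to annotate each
#'   feature with its namespace.
#' @return the path, invisibly.
#' @export
write_ranked_tsv <- function(rf, path, meta = NULL) {
  out <- as.data.frame(rf)
  if (!is.null(meta)) {
    out$namespace <- meta$namespace[match(out$feature_id, meta$term_id)]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
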