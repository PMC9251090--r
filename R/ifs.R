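#' Incremental-feature-selection configuration
#'
#' @param step prefix-size increment of the ranked feature list (default 5).
#' @param folds cross-validation folds (default 10).
#' @param smote_k neighbor count for SMOTE interpolation (default 5).
#' @param min_split,min_bucket,max_depth CART growth controls; defaults grow
#'   an effectively unrestricted Gini tree (`min_split = 2`,
#'   `min_bucket = 1`, `max_depth = 30`, complexity penalty 0).
#' @param seed integer RNG seed.
#' @return object of class `ifs_config`.
#' @export
ifs_config <- function(step = 5, folds = 10, smote_k = 5,
                       min_split = 2, min_bucket = 1, max_depth = 30,
                       seed = 1) {
  assert_count(step, "step", 1L)
  assert_count(folds, "folds", 2L)
  assert_count(smote_k, "smote_k", 1L)
  structure(list(step = as.integer(step), folds = as.integer(folds),
                 smote_k = as.integer(smote_k),
                 min_split = as.integer(min_split),
                 min_bucket = as.integer(min_bucket),
                 max_depth = as.integer(max_depth),
                 seed = as.integer(seed)),
            class = "ifs_config")
}

#' SMOTE: synthetic minority oversampling by kNN interpolation
#'
#' Each synthetic sample is `x_i + u * (x_nn - x_i)` with
#' `u ~ Uniform(0, 1)`, where `x_i` is a uniformly chosen minority row and
#' `x_nn` one of its `k` nearest minority neighbors (Euclidean). Every
#' synthetic coordinate therefore lies between its two parents'
#' coordinates. `k` is clamped to `nrow(X_min) - 1`.
#'
#' @param X_min numeric matrix of minority-class rows (at least 2).
#' @param n_new number of synthetic rows to generate.
#' @param k neighbor count (default 5).
#' @param seed optional seed; `NULL` uses the current RNG state.
#' @return `n_new x ncol(X_min)` matrix with attribute `"parents"`, a
#'   data.frame (`i`, `nn`, `u`) recording each row's provenance.
#' @export
smote_oversample <- function(X_min, n_new, k = 5, seed = NULL) {
  X_min <- as.matrix(X_min)
  if (nrow(X_min) < 2) stop("SMOTE needs at least 2 minority samples")
  assert_count(n_new, "n_new", 0L)
  if (!is.null(seed)) set.seed(seed)
  out <- matrix(numeric(0), nrow = 0, ncol = ncol(X_min),
                dimnames = list(NULL, colnames(X_min)))
  parents <- data.frame(i = integer(0), nn = integer(0), u = numeric(0))
  if (n_new == 0) {
    attr(out, "parents") <- parents
    return(out)
  }
  k <- min(k, nrow(X_min) - 1)
  dm <- as.matrix(stats::dist(X_min))
  diag(dm) <- Inf
  # k nearest minority neighbors of each row, ties by index
  nn_idx <- apply(dm, 1, function(d) order(d)[seq_len(k)])
  nn_idx <- matrix(nn_idx, nrow = k)

  base <- sample.int(nrow(X_min), n_new, replace = TRUE)
  pick <- sample.int(k, n_new, replace = TRUE)
  nn <- nn_idx[cbind(pick, base)]
  u <- stats::runif(n_new)
  out <- X_min[base, , drop = FALSE] +
    u * (X_min[nn, , drop = FALSE] - X_min[base, , drop = FALSE])
  rownames(out) <- NULL
  attr(out, "parents") <- data.frame(i = base, nn = nn, u = u)
  out
}

#' Stratified cross-validation fold assignment
#'
#' Shuffles each class independently and deals its members round-robin over
#' the folds, so per-class fold counts differ by at most one and every
#' sample lands in exactly one fold.
#'
#' @param y binary labels.
#' @param folds fold count; every class must have at least `folds` members.
#' @param seed integer seed.
#' @return integer vector of fold ids in `1..folds`, aligned with `y`.
#' @export
stratified_folds <- function(y, folds, seed = 1) {
  y <- as_binary_labels(y)
  assert_count(folds, "folds", 2L)
  tab <- table(y)
  if (any(tab < folds)) {
    stop("every class needs at least ", folds, " members for ", folds, "-fold CV")
  }
  set.seed(seed)
  assignment <- integer(length(y))
  for (cls in c(0L, 1L)) {
    idx <- sample(which(y == cls))
    assignment[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assignment
}

#' Classification metrics from pooled confusion counts
#'
#' Accuracy, sensitivity (recall), specificity, precision, F1 on the
#' positive class, and the Matthews correlation coefficient. Any metric
#' whose denominator is zero is defined as 0.
#'
#' @param counts named list or vector with `tp`, `tn`, `fp`, `fn`.
#' @return data.frame row with `acc`, `sn`, `sp`, `precision`, `f1`, `mcc`.
#' @export
evaluate_metrics <- function(counts) {
  tp <- as.numeric(counts[["tp"]]); tn <- as.numeric(counts[["tn"]])
  fp <- as.numeric(counts[["fp"]]); fn <- as.numeric(counts[["fn"]])
  if (any(c(tp, tn, fp, fn) < 0)) stop("confusion counts must be nonnegative")
  total <- tp + tn + fp + fn
  if (total == 0) stop("confusion counts are all zero")
  safe_div <- function(num, den) if (den == 0) 0 else num / den
  acc <- (tp + tn) / total
  sn <- safe_div(tp, tp + fn)
  sp <- safe_div(tn, tn + fp)
  precision <- safe_div(tp, tp + fp)
  f1 <- safe_div(2 * precision * sn, precision + sn)
  mcc_den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- if (mcc_den == 0) 0 else (tp * tn - fp * fn) / mcc_den
  data.frame(acc = acc, sn = sn, sp = sp, precision = precision,
             f1 = f1, mcc = mcc)
}

# Fit an unrestricted Gini CART on a labeled matrix. Feature names are
# mapped to syntactic placeholders so arbitrary term ids (e.g. GO:0042113)
# survive the formula interface; the map is kept on the fit.
fit_cart <- function(X, y, cfg) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  vnames <- paste0(".f", seq_len(ncol(X)))
  df <- as.data.frame(X)
  colnames(df) <- vnames
  df$.y <- factor(y, levels = c(0, 1))
  fit <- rpart::rpart(
    .y ~ ., data = df, method = "class",
    control = rpart::rpart.control(
      minsplit = cfg$min_split, minbucket = cfg$min_bucket,
      cp = 0, maxdepth = cfg$max_depth, xval = 0,
      maxcompete = 0, maxsurrogate = 0, usesurrogate = 0
    )
  )
  attr(fit, "feature_map") <- stats::setNames(colnames(X), vnames)
  fit
}

predict_cart <- function(fit, X) {
  X <- as.matrix(X)
  df <- as.data.frame(X)
  colnames(df) <- paste0(".f", seq_len(ncol(X)))
  as.integer(as.character(predict(fit, df, type = "class")))
}

#' Cross-validated evaluation of a SMOTE-balanced CART
#'
#' Stratified k-fold cross-validation in which SMOTE is applied to the
#' training portion of each fold only, bringing the minority class to exact
#' parity with the majority; the held-out fold is predicted untouched and
#' never contains synthetic samples. Confusion counts are pooled over folds
#' and metrics computed once from the pooled table.
#'
#' @param X numeric feature matrix.
#' @param y binary labels (positives = 1).
#' @param cfg an [ifs_config()].
#' @param fold_id optional precomputed fold assignment (from
#'   [stratified_folds()]); by default derived from `cfg$seed`.
#' @return one-row data.frame of metrics with the pooled counts attached as
#'   attribute `"counts"`.
#' @export
cv_evaluate <- function(X, y, cfg = ifs_config(), fold_id = NULL) {
  X <- as.matrix(X)
  y <- as_binary_labels(y)
  if (is.null(fold_id)) {
    fold_id <- stratified_folds(y, cfg$folds, seed = derive_seed(cfg$seed, "ifs"))
  }
  counts <- c(tp = 0L, tn = 0L, fp = 0L, fn = 0L)
  for (f in sort(unique(fold_id))) {
    te <- fold_id == f
    Xtr <- X[!te, , drop = FALSE]; ytr <- y[!te]
    tab <- table(factor(ytr, levels = c(0, 1)))
    minority <- as.integer(names(tab)[which.min(tab)])
    n_new <- as.integer(abs(diff(as.numeric(tab))))
    if (n_new > 0 && sum(ytr == minority) >= 2) {
      syn <- smote_oversample(Xtr[ytr == minority, , drop = FALSE],
                              n_new, k = cfg$smote_k,
                              seed = derive_seed(cfg$seed, "ifs") + f)
      Xtr <- rbind(Xtr, syn)
      ytr <- c(ytr, rep(minority, n_new))
    }
    fit <- fit_cart(Xtr, ytr, cfg)
    pred <- predict_cart(fit, X[te, , drop = FALSE])
    truth <- y[te]
    counts["tp"] <- counts["tp"] + sum(pred == 1 & truth == 1)
    counts["tn"] <- counts["tn"] + sum(pred == 0 & truth == 0)
    counts["fp"] <- counts["fp"] + sum(pred == 1 & truth == 0)
    counts["fn"] <- counts["fn"] + sum(pred == 0 & truth == 1)
  }
  metrics <- evaluate_metrics(as.list(counts))
  attr(metrics, "counts") <- counts
  metrics
}

# Best point of an IFS curve: maximum F1, ties to the smaller prefix.
ifs_best <- function(points) {
  best <- which(points$f1 == max(points$f1))[1]
  points[best, , drop = FALSE]
}

#' Incremental feature selection over a ranked feature list
#'
#' Evaluates nested prefixes of the (mRMR-ordered) feature columns of sizes
#' `step, 2 step, ...` up to the full width (a final partial prefix is
#' included), each with [cv_evaluate()], and selects the prefix maximizing
#' F1 (ties to the smaller prefix). The same fold assignment is reused
#' across prefixes so curves are comparable point to point.
#'
#' @param X_ranked matrix whose columns are already in ranked order.
#' @param y binary labels.
#' @param cfg an [ifs_config()].
#' @return object of class `ifs_curve`: list with `points` (data.frame
#'   `n_features` + metrics) and `best` (single row).
#' @export
ifs_run <- function(X_ranked, y, cfg = ifs_config()) {
  X_ranked <- as.matrix(X_ranked)
  p <- ncol(X_ranked)
  if (p < 1) stop("X_ranked must have at least one column")
  sizes <- unique(c(seq(min(cfg$step, p), p, by = cfg$step), p))
  y <- as_binary_labels(y)
  fold_id <- stratified_folds(y, cfg$folds, seed = derive_seed(cfg$seed, "ifs"))
  rows <- lapply(sizes, function(s) {
    m <- cv_evaluate(X_ranked[, seq_len(s), drop = FALSE], y, cfg,
                     fold_id = fold_id)
    cbind(n_features = s, m)
  })
  points <- do.call(rbind, rows)
  rownames(points) <- NULL
  structure(list(points = points, best = ifs_best(points)),
            class = "ifs_curve")
}

#' @export
print.ifs_curve <- function(x, ...) {
  cat("ifs_curve over", nrow(x$points), "prefix sizes; best:",
      x$best$n_features, "features, F1 =", round(x$best$f1, 4), "\n")
  invisible(x)
}

#' Plot an IFS curve (feature count vs F1)
#' @param x an `ifs_curve`.
#' @param ... passed to [plot()].
#' @export
plot.ifs_curve <- function(x, ...) {
  plot(x$points$n_features, x$points$f1, type = "b",
       xlab = "number of features", ylab = "F1-measure", ...)
  graphics::abline(v = x$best$n_features, lty = 2)
  invisible(x)
}

#' Write an IFS curve as TSV
#' @param curve an `ifs_curve`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_ifs_tsv <- function(curve, path) {
  utils::write.table(curve$points, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
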