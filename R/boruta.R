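#' Boruta configuration
#'
#' @param n_trees trees per random forest (default 500).
#' @param max_iter maximum shadow-comparison iterations (default 100).
#' @param alpha significance level of the per-iteration binomial test
#'   (default 0.05), Bonferroni-corrected over the undecided features.
#' @param percentile reference percentile of the shadow importances a real
#'   feature must beat to score a hit (default 100 = the best shadow).
#' @param subsample fraction of samples (stratified by class, drawn without
#'   replacement) used in each iteration (default 0.5). Refreshing the rows
#'   each round makes iterations approximately independent replicates of
#'   the real-vs-shadow comparison, which is what the binomial hit model
#'   assumes; with all rows reused every round (`subsample = 1`) a noise
#'   feature whose chance association happens to be the strongest in the
#'   dataset beats the fresh shadows persistently and gets falsely
#'   confirmed.
#' @param resolve_tentative resolve features still undecided at `max_iter`
#'   by comparing their median importance with the median best-shadow
#'   importance across iterations (default `TRUE`).
#' @param seed integer RNG seed.
#' @return object of class `boruta_config`.
#' @export
boruta_config <- function(n_trees = 500, max_iter = 100, alpha = 0.05,
                          percentile = 100, subsample = 0.5,
                          resolve_tentative = TRUE, seed = 1) {
  assert_count(n_trees, "n_trees", 1L)
  assert_count(max_iter, "max_iter", 1L)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (percentile <= 0 || percentile > 100) stop("percentile must lie in (0, 100]")
  if (subsample <= 0 || subsample > 1) stop("subsample must lie in (0, 1]")
  structure(list(n_trees = as.integer(n_trees), max_iter = as.integer(max_iter),
                 alpha = alpha, percentile = percentile, subsample = subsample,
                 resolve_tentative = isTRUE(resolve_tentative),
                 seed = as.integer(seed)),
            class = "boruta_config")
}

#' Augment a feature matrix with shadow features
#'
#' Appends one shadow column per original column, each an independent row
#' permutation of its source, destroying any association with the outcome
#' while preserving the marginal distribution. Shadow columns are named
#' `shadow_<original>`.
#'
#' @param X numeric matrix with at least one feature and two rows.
#' @return matrix with twice the columns; originals unchanged.
#' @export
add_shadows <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 1 || nrow(X) < 2) {
    stop("X must have at least 1 feature and 2 samples")
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  shadows <- apply(X, 2, sample)
  colnames(shadows) <- paste0("shadow_", colnames(X))
  cbind(X, shadows)
}

#' All-relevant feature selection with shadow features
#'
#' Repeatedly fits a random forest (class-balanced weights, impurity
#' importance) on the real features plus freshly permuted shadow copies.
#' A real feature scores a "hit" in an iteration when its importance exceeds
#' the configured percentile of the shadow importances. After every
#' iteration a two-sided binomial test (hit probability 0.5, Bonferroni
#' corrected over the undecided features) confirms features with
#' significantly many hits and rejects (and drops) features with
#' significantly few. Iteration stops when no feature is undecided or at
#' `max_iter`; leftovers are resolved by the median-importance heuristic
#' unless `resolve_tentative` is off.
#'
#' @param X numeric feature matrix (samples x features).
#' @param y binary labels aligned with the rows of `X`.
#' @param cfg a [boruta_config()].
#' @return object of class `boruta_result`: `confirmed`, `rejected`,
#'   `tentative` (feature ids, original column order; a partition of the
#'   input features), `hit_history` (iterations x features 0/1 matrix),
#'   and `n_iter`.
#' @export
boruta_run <- function(X, y, cfg = boruta_config()) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  feats <- colnames(X)
  y <- as_binary_labels(y)
  if (nrow(X) != length(y)) stop("rows of X must align with y")
  set.seed(cfg$seed)
  yf <- factor(y, levels = c(0, 1))
  cw <- as.numeric(length(y) / (2 * table(yf)))
  names(cw) <- levels(yf)
  idx0 <- which(y == 0L)
  idx1 <- which(y == 1L)
  n_sub0 <- min(length(idx0), max(2L, round(cfg$subsample * length(idx0))))
  n_sub1 <- min(length(idx1), max(2L, round(cfg$subsample * length(idx1))))

  status <- stats::setNames(rep("tentative", length(feats)), feats)
  hits <- stats::setNames(rep(0L, length(feats)), feats)
  hit_history <- NULL
  imp_history <- matrix(NA_real_, nrow = 0, ncol = length(feats),
                        dimnames = list(NULL, feats))
  shadow_max_history <- numeric(0)
  iter <- 0L

  while (any(status == "tentative") && iter < cfg$max_iter) {
    iter <- iter + 1L
    active <- feats[status != "rejected"]
    rows <- c(sample(idx0, n_sub0), sample(idx1, n_sub1))
    Xi <- X[rows, , drop = FALSE]
    # The shadow pool keeps the full original width even after rejections:
    # a shrinking pool would weaken the max-shadow reference and let
    # chance-correlated survivors accumulate spurious hits.
    shadows <- apply(Xi, 2, sample)
    colnames(shadows) <- paste0("shadow_", feats)
    Xa <- cbind(Xi[, active, drop = FALSE], shadows)
    fit <- ranger::ranger(
      x = Xa, y = yf[rows],
      num.trees = cfg$n_trees, importance = "impurity",
      class.weights = cw, num.threads = 1,
      seed = derive_seed(cfg$seed, "boruta") + iter
    )
    imp <- fit$variable.importance
    shadow_imp <- imp[grepl("^shadow_", names(imp))]
    real_imp <- imp[active]
    thr <- stats::quantile(shadow_imp, cfg$percentile / 100, names = FALSE)

    hit_now <- as.integer(real_imp > thr)
    hits[active] <- hits[active] + hit_now
    row <- stats::setNames(rep(0L, length(feats)), feats)
    row[active] <- hit_now
    hit_history <- rbind(hit_history, row)
    imp_row <- stats::setNames(rep(NA_real_, length(feats)), feats)
    imp_row[active] <- real_imp
    imp_history <- rbind(imp_history, imp_row)
    shadow_max_history <- c(shadow_max_history, max(shadow_imp))

    undecided <- feats[status == "tentative"]
    k <- length(undecided)
    p_hi <- stats::pbinom(hits[undecided] - 1, iter, 0.5, lower.tail = FALSE)
    p_lo <- stats::pbinom(hits[undecided], iter, 0.5)
    status[undecided[p_hi <= cfg$alpha / k]] <- "confirmed"
    status[undecided[p_lo <= cfg$alpha / k]] <- "rejected"
  }

  if (cfg$resolve_tentative && any(status == "tentative")) {
    med_shadow <- stats::median(shadow_max_history)
    for (f in feats[status == "tentative"]) {
      med_f <- stats::median(imp_history[, f], na.rm = TRUE)
      status[f] <- if (isTRUE(med_f > med_shadow)) "confirmed" else "rejected"
    }
  }

  rownames(hit_history) <- NULL
  structure(
    list(confirmed = feats[status == "confirmed"],
         rejected = feats[status == "rejected"],
         tentative = feats[status == "tentative"],
         hit_history = hit_history,
         n_iter = iter),
    class = "boruta_result"
  )
}

#' @export
print.boruta_result <- function(x, ...) {
  cat("boruta_result:", length(x$confirmed), "confirmed,",
      length(x$rejected), "rejected,", length(x$tentative), "tentative",
      paste0("(", x$n_iter, " iterations)\n"))
  invisible(x)
}

#' Write a Boruta result as JSON
#' @param res a `boruta_result`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_boruta_json <- function(res, path) {
  stopifnot(inherits(res, "boruta_result"))
  jsonlite::write_json(
    list(confirmed = res$confirmed, rejected = res$rejected,
         tentative = res$tentative, n_iter = res$n_iter),
    path
  )
  invisible(path)
}
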