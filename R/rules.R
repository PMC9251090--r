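#' Train the final CART tree on all samples
#'
#' Mirrors the classifier-construction recipe of the cross-validation stage:
#' the minority class of the full dataset is brought to parity with SMOTE
#' and an unrestricted Gini CART is grown on the balanced set. The real
#' (non-synthetic) samples are kept on the object so that rule supports can
#' be reported on real data only.
#'
#' @param X_best matrix restricted to the best IFS feature prefix.
#' @param y binary labels (positives = 1).
#' @param cfg an [ifs_config()] (supplies SMOTE k, tree controls, seed).
#' @return object of class `final_tree`: list with the `rpart` fit (`tree`),
#'   `feature_ids`, the real training data (`X_real`, `y_real`) and the
#'   number of synthetic rows appended (`n_synthetic`).
#' @export
fit_final_tree <- function(X_best, y, cfg = ifs_config()) {
  X_best <- as.matrix(X_best)
  if (is.null(colnames(X_best))) {
    colnames(X_best) <- paste0("V", seq_len(ncol(X_best)))
  }
  y <- as_binary_labels(y)
  tab <- table(factor(y, levels = c(0, 1)))
  minority <- as.integer(names(tab)[which.min(tab)])
  n_new <- as.integer(abs(diff(as.numeric(tab))))
  Xtr <- X_best; ytr <- y
  if (n_new > 0 && sum(y == minority) >= 2) {
    syn <- smote_oversample(X_best[y == minority, , drop = FALSE], n_new,
                            k = cfg$smote_k,
                            seed = derive_seed(cfg$seed, "rules"))
    Xtr <- rbind(X_best, syn)
    ytr <- c(y, rep(minority, n_new))
  }
  fit <- fit_cart(Xtr, ytr, cfg)
  structure(
    list(tree = fit, feature_ids = colnames(X_best),
         X_real = X_best, y_real = y, n_synthetic = n_new),
    class = "final_tree"
  )
}

# Walk the rpart frame and return, per leaf, the simplified bound
# conditions of its root-to-leaf path. Requires the tree to have been grown
# with maxcompete = 0 and maxsurrogate = 0 so that split rows align with
# internal nodes in frame order.
leaf_paths <- function(tree, feature_map) {
  frame <- tree$frame
  node_id <- as.integer(rownames(frame))
  is_leaf <- frame$var == "<leaf>"
  leaves <- node_id[is_leaf]
  if (all(is_leaf)) {
    return(stats::setNames(list(list()), leaves))  # root-only tree
  }
  splits <- tree$splits
  internal <- node_id[!is_leaf]
  split_var <- unname(feature_map[as.character(frame$var[!is_leaf])])
  split_thr <- splits[seq_along(internal), "index"]
  split_ncat <- splits[seq_along(internal), "ncat"]
  names(split_var) <- names(split_thr) <- names(split_ncat) <- internal

  paths <- lapply(leaves, function(leaf) {
    conds <- list()
    node <- leaf
    while (node > 1) {
      parent <- node %/% 2
      left <- node %% 2 == 0
      key <- as.character(parent)
      thr <- split_thr[[key]]
      # rpart continuous splits: ncat == -1 sends x < threshold left,
      # ncat == +1 sends x >= threshold left
      goes_low <- (split_ncat[[key]] == -1) == left
      conds[[length(conds) + 1]] <- list(
        feature = split_var[[key]],
        relation = if (goes_low) "<=" else ">",
        threshold = thr
      )
      node <- parent
    }
    rev(conds)
  })
  names(paths) <- leaves
  paths
}

simplify_conditions <- function(conds) {
  if (length(conds) == 0) {
    return(data.frame(feature = character(0), relation = character(0),
                      threshold = numeric(0), stringsAsFactors = FALSE))
  }
  df <- data.frame(
    feature = vapply(conds, `[[`, "", "feature"),
    relation = vapply(conds, `[[`, "", "relation"),
    threshold = vapply(conds, `[[`, 0, "threshold"),
    stringsAsFactors = FALSE
  )
  parts <- split(df, paste(df$feature, df$relation))
  out <- do.call(rbind, lapply(parts, function(d) {
    # tightest bound: minimum upper bound, maximum lower bound
    thr <- if (d$relation[1] == "<=") min(d$threshold) else max(d$threshold)
    data.frame(feature = d$feature[1], relation = d$relation[1],
               threshold = thr, stringsAsFactors = FALSE)
  }))
  out <- out[order(out$feature, out$relation), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract mutually exclusive, exhaustive IF-THEN rules from a final tree
#'
#' One rule per leaf: the conjunction of the edge conditions on the
#' root-to-leaf path, simplified per feature to the tightest lower/upper
#' bound. The predicted class is the leaf majority on the (balanced)
#' training data; supports are counted on real samples only. Rules are
#' ordered by descending real-sample support.
#'
#' @param ft a `final_tree` from [fit_final_tree()].
#' @return object of class `rule_set`: list with `rules` (each a list with
#'   `conditions` data.frame, `predicted_class`, `support` = named vector
#'   `n_positive`/`n_negative`, `node`) and `feature_universe`.
#' @export
extract_rules <- function(ft) {
  stopifnot(inherits(ft, "final_tree"))
  tree <- ft$tree
  fmap <- attr(tree, "feature_map")
  frame <- tree$frame
  node_id <- as.integer(rownames(frame))
  is_leaf <- frame$var == "<leaf>"
  paths <- leaf_paths(tree, fmap)

  # leaf node of every REAL training sample, for support counts
  leaf_of_row <- node_id[tree$where]
  n_real <- nrow(ft$X_real)
  real_leaf <- leaf_of_row[seq_len(n_real)]

  classes <- attr(tree, "ylevels") %||% levels(tree$model$.y) %||% c("0", "1")
  rules <- lapply(seq_along(paths), function(k) {
    leaf <- as.integer(names(paths)[k])
    row <- which(node_id == leaf & is_leaf)
    yval <- frame$yval[row]
    pred <- if (classes[yval] == "1") "positive" else "negative"
    in_leaf <- real_leaf == leaf
    list(
      conditions = simplify_conditions(paths[[k]]),
      predicted_class = pred,
      support = c(n_positive = sum(in_leaf & ft$y_real == 1),
                  n_negative = sum(in_leaf & ft$y_real == 0)),
      node = leaf
    )
  })
  ord <- order(vapply(rules, function(r) sum(r$support), 0), decreasing = TRUE)
  structure(list(rules = rules[ord], feature_universe = ft$feature_ids),
            class = "rule_set")
}

#' @export
print.rule_set <- function(x, ...) {
  cat("rule_set:", length(x$rules), "rules over",
      length(x$feature_universe), "features\n")
  invisible(x)
}

rule_matches <- function(rule, x) {
  conds <- rule$conditions
  if (nrow(conds) == 0) return(TRUE)
  v <- x[conds$feature]
  all(ifelse(conds$relation == "<=", v <= conds$threshold, v > conds$threshold))
}

#' Classify a feature vector with an extracted rule set
#'
#' Exactly one rule must match (the rules partition the feature space); any
#' other outcome is an internal-consistency failure and raises an error.
#'
#' @param rs a `rule_set`.
#' @param x named numeric vector covering `rs$feature_universe`.
#' @return `"positive"` or `"negative"`.
#' @export
predict_with_rules <- function(rs, x) {
  stopifnot(inherits(rs, "rule_set"))
  missing <- setdiff(rs$feature_universe, names(x))
  if (length(missing)) {
    stop("feature vector does not cover the rule features: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  hit <- which(vapply(rs$rules, rule_matches, TRUE, x = x))
  if (length(hit) != 1) {
    stop("internal consistency breach: ", length(hit),
         " rules match (expected exactly 1)")
  }
  rs$rules[[hit]]$predicted_class
}

#' Write a rule set as JSON and as indented IF-THEN text
#'
#' @param rs a `rule_set`.
#' @param json_path output JSON path (full-precision thresholds).
#' @param text_path optional text-report path (4 significant digits).
#' @return `json_path`, invisibly.
#' @export
write_rules <- function(rs, json_path, text_path = NULL) {
  stopifnot(inherits(rs, "rule_set"))
  payload <- lapply(rs$rules, function(r) {
    list(conditions = r$conditions, predicted_class = r$predicted_class,
         support = as.list(r$support), node = r$node)
  })
  jsonlite::write_json(
    list(rules = payload, feature_universe = rs$feature_universe),
    json_path, auto_unbox = TRUE, digits = NA
  )
  if (!is.null(text_path)) {
    lines <- unlist(lapply(seq_along(rs$rules), function(k) {
      r <- rs$rules[[k]]
      conds <- if (nrow(r$conditions) == 0) "  TRUE" else
        paste0("  ", r$conditions$feature, " ", r$conditions$relation, " ",
               signif(r$conditions$threshold, 4))
      c(sprintf("RULE %d (support: %d positive, %d negative)", k,
                r$support[["n_positive"]], r$support[["n_negative"]]),
        "IF", conds, paste0("THEN class = ", r$predicted_class), "")
    }))
    writeLines(lines, text_path)
  }
  invisible(json_path)
}
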