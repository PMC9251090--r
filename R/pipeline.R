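#' Pipeline configuration
#'
#' Either `synthetic` (a [synthetic_config()]) or `paths` (named list with
#' `catalog`, `network`, `positives` file paths) must be supplied, not both.
#' Stage sub-configurations default to the package defaults with seeds
#' fanned out deterministically from the global `seed`.
#'
#' @param synthetic optional [synthetic_config()].
#' @param paths optional named list of input file paths.
#' @param out_dir optional output directory; when given, every intermediate
#'   artifact is persisted in the documented plain-text formats.
#' @param seed global integer seed.
#' @param min_score minimum edge confidence for the neighborhood (default 0).
#' @param boruta a [boruta_config()] (seed overridden by the fan-out).
#' @param ifs an [ifs_config()] (seed overridden by the fan-out).
#' @param mrmr_scheme discretization scheme for [mrmr_rank()].
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = NULL, paths = NULL, out_dir = NULL,
                            seed = 1, min_score = 0,
                            boruta = boruta_config(), ifs = ifs_config(),
                            mrmr_scheme = list(kind = "three-bin-mean-sigma",
                                               t = 1)) {
  if (is.null(synthetic) == is.null(paths)) {
    stop("supply exactly one of `synthetic` or `paths`")
  }
  if (!is.null(paths)) {
    need <- c("catalog", "network", "positives")
    if (!all(need %in% names(paths))) {
      stop("paths must name: ", paste(need, collapse = ", "))
    }
  }
  boruta$seed <- derive_seed(seed, "boruta")
  ifs$seed <- derive_seed(seed, "ifs")
  structure(list(synthetic = synthetic, paths = paths, out_dir = out_dir,
                 seed = as.integer(seed), min_score = min_score,
                 boruta = boruta, ifs = ifs, mrmr_scheme = mrmr_scheme),
            class = "pipeline_config")
}

stage_try <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Namespace breakdown of a feature selection
#'
#' Counts how many selected features fall in each annotation namespace
#' (BP, CC, MF, PATHWAY); counts always sum to the selection size.
#'
#' @param features character vector of selected feature (term) ids.
#' @param meta data.frame with `term_id` and `namespace` columns.
#' @return named integer vector over the four namespaces.
#' @export
namespace_breakdown <- function(features, meta) {
  idx <- match(features, meta$term_id)
  if (anyNA(idx)) {
    stop("features missing from metadata: ",
         paste(utils::head(features[is.na(idx)], 5), collapse = ", "))
  }
  tab <- table(factor(meta$namespace[idx], levels = NAMESPACES))
  stats::setNames(as.integer(tab), NAMESPACES)
}

#' Run the full disease-gene classification pipeline
#'
#' Executes featurize (neighborhood enrichment matrix) -> Boruta filter ->
#' mRMR ranking -> incremental feature selection with a SMOTE-balanced CART
#' under stratified cross-validation -> final tree and IF-THEN rule
#' extraction. If Boruta confirms no feature (e.g. on null data) the
#' pipeline warns and ranks all features instead of aborting.
#'
#' @param cfg a [pipeline_config()].
#' @return object of class `pipeline_report`: list with `best_n_features`,
#'   `metrics` (best prefix row), `curve`, `boruta`, `ranking`, `rules`,
#'   `rule_count`, `namespace_breakdown`, `n_confirmed`, and for synthetic
#'   inputs `causal_terms` plus `causal_confirmed` (how many causal-term
#'   features Boruta confirmed).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))

  # ---- inputs ----
  if (!is.null(cfg$synthetic)) {
    ds <- stage_try("simulate", generate_dataset(cfg$synthetic))
    if (!is.null(cfg$out_dir)) write_dataset(ds, file.path(cfg$out_dir, "data"))
    catalog <- ds$catalog; network <- ds$network; positives <- ds$positives
    causal_terms <- ds$causal_terms
  } else {
    catalog <- stage_try("featurize", read_gmt(cfg$paths$catalog))
    universe <- sort(unique(c(catalog$universe)))
    network <- stage_try("featurize",
                         read_edge_list(cfg$paths$network, universe = universe))
    positives <- stage_try("featurize", read_gene_list(cfg$paths$positives))
    causal_terms <- NULL
  }

  # ---- featurize ----
  em <- stage_try("featurize",
                  build_matrix(catalog, network, min_score = cfg$min_score))
  y <- as.integer(em$genes %in% positives)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_matrix_tsv(em, file.path(cfg$out_dir, "enrichment_matrix.tsv"))
  }

  # ---- boruta ----
  bres <- stage_try("boruta", boruta_run(em$scores, y, cfg$boruta))
  kept <- bres$confirmed
  if (length(kept) == 0) {
    warning("Boruta confirmed no features; ranking all features instead")
    kept <- colnames(em$scores)
  }
  if (!is.null(cfg$out_dir)) {
    write_boruta_json(bres, file.path(cfg$out_dir, "boruta.json"))
  }

  # ---- mrmr ----
  ranking <- stage_try("mrmr",
                       mrmr_rank(em$scores[, kept, drop = FALSE], y,
                                 scheme = cfg$mrmr_scheme))
  if (!is.null(cfg$out_dir)) {
    write_ranked_tsv(ranking, file.path(cfg$out_dir, "mrmr_ranking.tsv"),
                     meta = em$features)
  }

  # ---- ifs ----
  X_ranked <- em$scores[, ranking$feature_id, drop = FALSE]
  curve <- stage_try("ifs", ifs_run(X_ranked, y, cfg$ifs))
  best_n <- curve$best$n_features
  if (!is.null(cfg$out_dir)) {
    write_ifs_tsv(curve, file.path(cfg$out_dir, "ifs_curve.tsv"))
    jsonlite::write_json(
      list(best_n_features = best_n,
           best_features = ranking$feature_id[seq_len(best_n)],
           metrics = as.list(curve$best)),
      file.path(cfg$out_dir, "best_subset.json"), auto_unbox = TRUE, digits = NA
    )
  }

  # ---- rules ----
  ft <- stage_try("rules",
                  fit_final_tree(X_ranked[, seq_len(best_n), drop = FALSE],
                                 y, cfg$ifs))
  rules <- stage_try("rules", extract_rules(ft))
  if (!is.null(cfg$out_dir)) {
    write_rules(rules, file.path(cfg$out_dir, "rules.json"),
                file.path(cfg$out_dir, "rules.txt"))
  }

  best_features <- ranking$feature_id[seq_len(best_n)]
  report <- list(
    best_n_features = best_n,
    metrics = curve$best,
    curve = curve,
    boruta = bres,
    ranking = ranking,
    rules = rules,
    rule_count = length(rules$rules),
    namespace_breakdown = namespace_breakdown(best_features, em$features),
    n_confirmed = length(bres$confirmed),
    causal_terms = causal_terms,
    causal_confirmed = if (!is.null(causal_terms)) {
      sum(causal_terms %in% bres$confirmed)
    } else NA_integer_
  )
  class(report) <- "pipeline_report"
  if (!is.null(cfg$out_dir)) {
    jsonlite::write_json(
      list(best_n_features = report$best_n_features,
           metrics = as.list(report$metrics),
           rule_count = report$rule_count,
           n_confirmed = report$n_confirmed,
           namespace_breakdown = as.list(report$namespace_breakdown),
           causal_terms = causal_terms,
           causal_confirmed = report$causal_confirmed),
      file.path(cfg$out_dir, "report.json"), auto_unbox = TRUE, digits = NA
    )
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report\n")
  cat("  Boruta confirmed:", x$n_confirmed, "features\n")
  cat("  best prefix:", x$best_n_features, "features\n")
  m <- x$metrics
  cat(sprintf("  metrics: ACC %.3f  SN %.3f  SP %.3f  precision %.3f  F1 %.3f  MCC %.3f\n",
              m$acc, m$sn, m$sp, m$precision, m$f1, m$mcc))
  cat("  rules:", x$rule_count, "\n")
  cat("  namespaces:",
      paste(names(x$namespace_breakdown), x$namespace_breakdown,
            sep = "=", collapse = " "), "\n")
  if (!is.null(x$causal_terms)) {
    cat("  causal terms confirmed:", x$causal_confirmed, "of",
        length(x$causal_terms), "\n")
  }
  invisible(x)
}
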