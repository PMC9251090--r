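# Readers/writers for the plain-text interchange formats:
# GMT gene sets, STRING-style edge lists, one-gene-per-line label files,
# TSV feature matrices with a JSON column-metadata sidecar.

#' Read a GMT gene-set file
#'
#' GMT is tab-separated: term id, description, then one gene id per column.
#' Namespaces are recovered from a `namespace` attribute column embedded in
#' the description as `"<namespace>|<free text>"` when present, otherwise
#' every term is assigned to `"BP"`.
#'
#' @param path file path.
#' @param universe optional gene universe; defaults to union of the sets.
#' @return an [annotation_catalog()].
#' @export
read_gmt <- function(path, universe = NULL) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 3)) stop("malformed GMT line (need id, description, >=1 gene)")
  term_id <- vapply(parts, `[[`, "", 1L)
  desc <- vapply(parts, `[[`, "", 2L)
  genes <- lapply(parts, function(p) p[-(1:2)])
  ns <- rep("BP", length(term_id))
  has_ns <- grepl("^(BP|CC|MF|PATHWAY)\\|", desc)
  ns[has_ns] <- sub("\\|.*$", "", desc[has_ns])
  desc[has_ns] <- sub("^(BP|CC|MF|PATHWAY)\\|", "", desc[has_ns])
  annotation_catalog(term_id, ns, genes, universe = universe, description = desc)
}

#' Write an annotation catalog as GMT
#'
#' The namespace is embedded in the description column as
#' `"<namespace>|<description>"` so that [read_gmt()] round-trips it.
#'
#' @param catalog an [annotation_catalog()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_gmt <- function(catalog, path) {
  stopifnot(inherits(catalog, "annotation_catalog"))
  lines <- vapply(seq_along(catalog$term_id), function(i) {
    paste(c(catalog$term_id[i],
            paste0(catalog$namespace[i], "|", catalog$description[i]),
            catalog$genes[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a whitespace/tab-separated edge list
#'
#' Expects two endpoint columns and an optional third numeric confidence
#' column on the STRING 0-1000 convention. A header line is detected and
#' skipped when the third field of the first line is non-numeric.
#'
#' @param path file path.
#' @param universe optional gene universe.
#' @return a [gene_network()].
#' @export
read_edge_list <- function(path, universe = NULL) {
  if (!file.exists(path)) stop("edge list file not found: ", path)
  first <- readLines(path, n = 1)
  f <- strsplit(trimws(first), "[ \t]+")[[1]]
  has_header <- length(f) >= 3 && is.na(suppressWarnings(as.numeric(f[3])))
  if (length(f) == 2 && any(f %in% c("gene1", "gene2", "protein1", "protein2"))) {
    has_header <- TRUE
  }
  tab <- utils::read.table(path, header = has_header, colClasses = "character",
                           comment.char = "", stringsAsFactors = FALSE)
  scores <- if (ncol(tab) >= 3) as.numeric(tab[[3]]) else NULL
  gene_network(tab[, 1:2], universe = universe, scores = scores)
}

#' Write a network as a tab-separated edge list
#' @param net a [gene_network()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "gene_network"))
  ed <- net$edges
  if (all(is.na(ed$score))) {
    utils::write.table(ed[, c("gene1", "gene2")], path, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  } else {
    utils::write.table(ed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a gene list (one identifier per line)
#' @param path file path.
#' @return character vector.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("gene list file not found: ", path)
  x <- readLines(path)
  x[nzchar(trimws(x))]
}

#' Write a gene list (one identifier per line)
#' @param genes character vector.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}

#' Write an enrichment matrix as TSV plus column-metadata JSON
#'
#' The TSV has a header of term ids and the gene id as the first column;
#' the sidecar JSON maps each term id to its namespace.
#'
#' @param em an `enrichment_matrix` from [build_matrix()].
#' @param path output TSV path; the metadata is written next to it with a
#'   `.meta.json` suffix.
#' @return the TSV path, invisibly.
#' @export
write_matrix_tsv <- function(em, path) {
  stopifnot(inherits(em, "enrichment_matrix"))
  df <- data.frame(gene = em$genes, em$scores, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- as.list(stats::setNames(em$features$namespace, em$features$term_id))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read an enrichment matrix written by [write_matrix_tsv()]
#' @param path TSV path (its `.meta.json` sidecar must sit next to it).
#' @param n_universe the universe size to record on the object.
#' @return an `enrichment_matrix`.
#' @export
read_matrix_tsv <- function(path, n_universe = NA_integer_) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE)
  meta_path <- paste0(path, ".meta.json")
  ns <- if (file.exists(meta_path)) {
    m <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    unlist(m)[colnames(tab)[-1]]
  } else {
    rep("BP", ncol(tab) - 1)
  }
  scores <- as.matrix(tab[, -1, drop = FALSE])
  rownames(scores) <- tab[[1]]
  structure(
    list(scores = scores, genes = tab[[1]],
         features = data.frame(term_id = colnames(scores),
                               namespace = unname(ns),
                               stringsAsFactors = FALSE),
         n_universe = n_universe),
    class = "enrichment_matrix"
  )
}
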