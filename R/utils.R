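# Internal helpers shared across modules.

NAMESPACES <- c("BP", "CC", "MF", "PATHWAY")

# Deterministic fan-out of one user-facing seed into per-stage seeds.
# Kept below 2^31 - 1 so the result is always a valid R integer.
derive_seed <- function(seed, stage) {
  offsets <- c(
    catalog = 101L, network = 211L, labels = 307L, shadows = 809L,
    boruta = 401L, mrmr = 503L, ifs = 601L, rules = 701L
  )
  if (!stage %in% names(offsets)) {
    stop("unknown stage for seed derivation: ", stage)
  }
  as.integer((as.numeric(seed) %% 65536 * 32003 + offsets[[stage]] * 97) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_count <- function(x, name, min = 0L) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x != round(x) || x < min) {
    stop(name, " must be a single integer >= ", min, call. = FALSE)
  }
  invisible(as.integer(x))
}

as_binary_labels <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  if (is.logical(y)) y <- as.integer(y)
  u <- sort(unique(y))
  if (length(u) < 2) {
    stop("labels must contain both classes; found only: ",
         paste(u, collapse = ", "), call. = FALSE)
  }
  if (length(u) > 2) {
    stop("labels must be binary; found ", length(u), " classes", call. = FALSE)
  }
  as.integer(y == u[2])
}
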