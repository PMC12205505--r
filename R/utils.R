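# Internal helpers shared across modules.

#' Derive a named substream seed from a master seed
#'
#' Each stochastic component (LFQ generator, TMT generator, imputation,
#' K-means, ...) draws from its own substream so that adding one generator
#' never perturbs the stream of another. The substream seed is a
#' deterministic 31-bit hash of the master seed and the stream name.
#'
#' @param seed master integer seed.
#' @param name substream name.
#' @return integer seed in [0, 2^31).
#' @export
substream_seed <- function(seed, name) {
  stopifnot(length(seed) == 1, is.finite(seed))
  h <- as.double(seed %% 2147483647)
  for (b in utf8ToInt(name)) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

# Polynomial byte hash of an arbitrary R object; used to stamp output files
# with a config fingerprint for provenance.
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, connection = NULL, version = 3))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Precision and recall of a predicted gene set against truth
#'
#' @param predicted,truth character vectors of gene symbols.
#' @return list with precision, recall, tp, fp, fn. Precision of an empty
#'   prediction is 1 when the truth is also empty, otherwise NA.
#' @export
set_metrics <- function(predicted, truth) {
  predicted <- unique(predicted); truth <- unique(truth)
  tp <- length(intersect(predicted, truth))
  fp <- length(setdiff(predicted, truth))
  fn <- length(setdiff(truth, predicted))
  precision <- if (tp + fp == 0) (if (length(truth) == 0) 1 else NA_real_) else tp / (tp + fp)
  recall <- if (tp + fn == 0) 1 else tp / (tp + fn)
  list(precision = precision, recall = recall, tp = tp, fp = fp, fn = fn)
}

# Write a data.frame as TSV with a provenance header comment.
write_tsv_prov <- function(df, path, provenance = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(provenance))
    writeLines(paste0("# ", provenance), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
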