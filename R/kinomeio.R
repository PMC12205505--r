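#' Read a MaxQuant-style protein-groups table into an intensity matrix
#'
#' Expects a tab-separated table whose first column (`gene`) holds gene
#' symbols (multi-gene protein groups separated by ";") and whose remaining
#' columns are raw (linear-scale) intensities named by sample id. Rows are
#' restricted to roster kinases, decoy/contaminant rows (prefix-matched) are
#' dropped, zero or NA intensities become missing, duplicate symbol rows are
#' summed on the raw scale, and values are log2-transformed.
#'
#' @param path TSV file path.
#' @param roster a [kinase_roster()]; only `is_kinase` symbols are kept.
#' @param metadata sample metadata covering every intensity column.
#' @param decoy_prefixes row prefixes marking reverse/contaminant entries.
#' @return an [intensity_matrix()].
#' @export
read_protein_groups <- function(path, roster, metadata,
                                decoy_prefixes = c("REV__", "CON__")) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (nrow(tab) == 0 || ncol(tab) < 2) stop("format error: empty table")
  metadata <- validate_metadata(metadata)
  sample_cols <- setdiff(names(tab), names(tab)[1])
  if (!setequal(sample_cols, metadata$sample))
    stop("schema error: intensity columns do not match metadata samples; ",
         "missing from metadata: ",
         paste(setdiff(sample_cols, metadata$sample), collapse = ", "))

  genes_raw <- as.character(tab[[1]])
  decoy <- Reduce(`|`, lapply(decoy_prefixes, function(p) startsWith(genes_raw, p)),
                  accumulate = FALSE)
  tab <- tab[!decoy, , drop = FALSE]
  genes_raw <- genes_raw[!decoy]

  # multi-gene protein groups collapse to the first listed symbol
  first_symbol <- sub(";.*$", "", genes_raw)
  if (any(first_symbol != genes_raw))
    message("collapsed ", sum(first_symbol != genes_raw),
            " multi-gene protein groups to their first symbol")

  kin <- roster$symbol[roster$is_kinase]
  keep <- first_symbol %in% kin
  tab <- tab[keep, , drop = FALSE]
  symbols <- first_symbol[keep]

  vals <- as.matrix(tab[, metadata$sample, drop = FALSE])
  storage.mode(vals) <- "double"
  vals[is.na(vals)] <- 0  # 0 and NA both mean undetected on disk

  if (anyDuplicated(symbols)) {
    warning("summing raw intensities of duplicate protein-group rows for: ",
            paste(unique(symbols[duplicated(symbols)]), collapse = ", "))
    vals <- rowsum(vals, group = symbols, reorder = FALSE)
    symbols <- rownames(vals)
  }
  rownames(vals) <- symbols
  out <- ifelse(vals > 0, log2(vals), NA_real_)
  rownames(out) <- symbols
  intensity_matrix(out, metadata)
}

#' Write an intensity matrix back to the protein-groups dialect
#'
#' Inverse of [read_protein_groups()]: values are de-logged (2^x) and
#' missing entries written as 0.
#'
#' @param m an [intensity_matrix()].
#' @param path output TSV path.
#' @export
write_protein_groups <- function(m, path) {
  stopifnot(inherits(m, "intensity_matrix"))
  raw <- 2^m$values
  raw[is.na(raw)] <- 0
  df <- data.frame(gene = rownames(m$values), raw, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-level count matrix
#'
#' @param path TSV with a `gene` first column and integer sample columns.
#' @param metadata sample metadata whose samples match the columns.
#' @return a [count_matrix()].
#' @export
read_counts <- function(path, metadata) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("format error: empty file")
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (nrow(tab) == 0 || ncol(tab) < 2) stop("format error: empty table")
  metadata <- validate_metadata(metadata)
  sample_cols <- setdiff(names(tab), names(tab)[1])
  if (!setequal(sample_cols, metadata$sample))
    stop("schema error: count columns do not match metadata samples")
  cts <- as.matrix(tab[, metadata$sample, drop = FALSE])
  storage.mode(cts) <- "double"
  if (anyNA(cts) || any(cts < 0) || any(cts != round(cts)))
    stop("format error: counts must be non-negative integers")
  rownames(cts) <- as.character(tab[[1]])
  count_matrix(cts, metadata)
}

#' Write a count matrix as TSV
#'
#' @param cm a [count_matrix()].
#' @param path output path.
#' @export
write_counts <- function(cm, path) {
  stopifnot(inherits(cm, "count_matrix"))
  df <- data.frame(gene = rownames(cm$counts), cm$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a signature set as GMT-style lines
#'
#' One line per signature: `name<TAB>provenance<TAB>gene[:direction]...`.
#' The exclusion audit trail is persisted separately with
#' [write_exclusion_log()].
#'
#' @param sigs a [signature_set()].
#' @param path output path.
#' @param provenance_comment optional `# ...` header line (config hash, seed).
#' @export
write_signatures <- function(sigs, path, provenance_comment = NULL) {
  stopifnot(inherits(sigs, "signature_set"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(provenance_comment))
    writeLines(paste0("# ", provenance_comment), con)
  for (nm in names(sigs$signatures)) {
    s <- sigs$signatures[[nm]]
    toks <- ifelse(is.na(s$direction), s$gene,
                   paste0(s$gene, ":", s$direction))
    writeLines(paste(c(nm, sigs$provenance[[nm]], toks), collapse = "\t"),
               con)
  }
  invisible(path)
}

#' Read a GMT-style signature file
#'
#' @param path file written by [write_signatures()] (or any GMT file;
#'   genes may carry `:up` / `:down` suffixes).
#' @return a [signature_set()] with an empty exclusion log.
#' @export
read_signatures <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  signatures <- list(); provenance <- character(0)
  for (i in seq_along(lines)) {
    if (!nzchar(lines[i])) next
    toks <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(toks) < 2)
      stop("parse error at line ", i, ": expected name<TAB>description")
    nm <- toks[1]
    genes <- toks[-(1:2)]
    dir <- rep(NA_character_, length(genes))
    has_dir <- grepl(":", genes, fixed = TRUE)
    dir[has_dir] <- sub("^.*:", "", genes[has_dir])
    genes[has_dir] <- sub(":.*$", "", genes[has_dir])
    if (any(!is.na(dir) & !(dir %in% c("up", "down"))))
      stop("parse error at line ", i, ": bad direction suffix")
    signatures[[nm]] <- data.frame(gene = genes, direction = dir,
                                   stringsAsFactors = FALSE)
    provenance[nm] <- toks[2]
  }
  signature_set(signatures, provenance)
}

#' Write / read the signature exclusion audit log
#'
#' @param sigs a [signature_set()].
#' @param path TSV path.
#' @export
write_exclusion_log <- function(sigs, path) {
  stopifnot(inherits(sigs, "signature_set"))
  utils::write.table(sigs$exclusions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a ground-truth membership table
#'
#' @param truth data.frame with at least gene/line/condition/direction/l2fc.
#' @param path TSV path.
#' @export
write_truth_table <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
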