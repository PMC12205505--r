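#' Sample metadata columns every matrix carries
#'
#' @keywords internal
#' @noRd
.metadata_cols <- c("sample", "line", "condition", "treatment",
                    "timepoint_h", "batch", "replicate")

.valid_conditions <- c("FS", "SS")

#' Validate a sample-metadata data frame
#'
#' Checks the closed condition vocabulary (full serum `FS` / starved serum
#' `SS`), non-negative timepoints, and uniqueness of sample ids and of the
#' (line, condition, treatment, timepoint, replicate) key.
#'
#' @param samples data.frame with columns sample, line, condition, treatment,
#'   timepoint_h, batch, replicate.
#' @return the validated data.frame (character/numeric columns coerced).
#' @export
validate_metadata <- function(samples) {
  stopifnot(is.data.frame(samples))
  missing_cols <- setdiff(.metadata_cols, names(samples))
  if (length(missing_cols) > 0L)
    stop("metadata is missing columns: ", paste(missing_cols, collapse = ", "))
  samples$sample <- as.character(samples$sample)
  if (anyDuplicated(samples$sample))
    stop("duplicate sample ids in metadata")
  bad_cond <- !is.na(samples$condition) &
    !(samples$condition %in% .valid_conditions)
  if (any(bad_cond))
    stop("condition must be one of ", paste(.valid_conditions, collapse = "/"),
         "; offending: ", paste(unique(samples$condition[bad_cond]), collapse = ", "))
  if (any(samples$timepoint_h < 0, na.rm = TRUE))
    stop("timepoint_h must be >= 0")
  key <- do.call(paste, c(samples[c("line", "condition", "treatment",
                                    "timepoint_h", "replicate")], sep = "\r"))
  if (anyDuplicated(key))
    stop("duplicate (line, condition, treatment, timepoint_h, replicate) keys")
  samples
}

#' Construct an intensity matrix (kinases x samples, log2 scale)
#'
#' The workhorse container for MIB-MS data: a genes-by-samples matrix of
#' log2 protein-group intensities where `NA` encodes a missing (undetected)
#' value, together with per-sample metadata. The missingness mask is
#' `is.na(values)`.
#'
#' @param values numeric matrix, rownames = gene symbols, colnames = sample
#'   ids; NA = missing.
#' @param samples sample metadata (see [validate_metadata()]); row order must
#'   match `colnames(values)`.
#' @return an `intensity_matrix` object.
#' @export
intensity_matrix <- function(values, samples) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("values must have unique gene-symbol rownames")
  if (is.null(colnames(values)))
    stop("values must have sample-id colnames")
  samples <- validate_metadata(samples)
  if (!identical(colnames(values), samples$sample))
    stop("colnames(values) must equal samples$sample in the same order")
  structure(list(values = values, samples = samples),
            class = "intensity_matrix")
}

#' Construct a count matrix (genes x samples, raw RNA-seq counts)
#'
#' @param counts non-negative integer matrix with gene rownames and sample
#'   colnames.
#' @param samples sample metadata; row order must match `colnames(counts)`.
#' @return a `count_matrix` object.
#' @export
count_matrix <- function(counts, samples) {
  stopifnot(is.matrix(counts), is.numeric(counts))
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers with no missing values")
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts)))
    stop("counts must have unique gene-symbol rownames")
  if (is.null(colnames(counts)))
    stop("counts must have sample-id colnames")
  samples <- validate_metadata(samples)
  if (!identical(colnames(counts), samples$sample))
    stop("colnames(counts) must equal samples$sample in the same order")
  structure(list(counts = counts, samples = samples), class = "count_matrix")
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf("intensity_matrix: %d genes x %d samples (%.1f%% missing)\n",
              nrow(x$values), ncol(x$values),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' @export
dim.intensity_matrix <- function(x) dim(x$values)

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Construct a kinase roster
#'
#' Annotation table defining kinome membership and gene-class flags used for
#' filtering (only kinases enter MIB-MS analysis; only protein-coding genes
#' enter RNA-seq analysis). A `special` flag marks exogenous constructs such
#' as the `hEGFR` (EGFRvIII) transgene, which is excluded from signatures.
#'
#' @param symbol character gene symbols (unique).
#' @param is_kinase,is_receptor,is_protein_coding logical flags.
#' @param special character flag ("" for none; e.g. "hEGFR").
#' @return a `kinase_roster` data.frame.
#' @export
kinase_roster <- function(symbol, is_kinase = TRUE, is_receptor = FALSE,
                          is_protein_coding = TRUE, special = "") {
  symbol <- as.character(symbol)
  if (anyDuplicated(symbol)) stop("roster symbols must be unique")
  out <- data.frame(symbol = symbol,
                    is_kinase = rep_len(as.logical(is_kinase), length(symbol)),
                    is_receptor = rep_len(as.logical(is_receptor), length(symbol)),
                    is_protein_coding = rep_len(as.logical(is_protein_coding),
                                                length(symbol)),
                    special = rep_len(as.character(special), length(symbol)),
                    stringsAsFactors = FALSE)
  class(out) <- c("kinase_roster", "data.frame")
  out
}

#' Construct a directional signature set
#'
#' A named collection of directional gene sets (the BL, OL-BL and EGFRi
#' signatures) with provenance labels and an exclusion audit trail recording
#' every gene removed during signature construction and why.
#'
#' @param signatures named list; each element a data.frame with columns
#'   `gene` and `direction` (one of "up", "down", or NA).
#' @param provenance named character, one entry per signature (e.g.
#'   "unique-BL", "OL-BL", "EGFRi-up", "EGFRi-down").
#' @param exclusions data.frame with columns `gene`, `signature`, `reason`.
#' @return a `signature_set` object.
#' @export
signature_set <- function(signatures = list(), provenance = character(0),
                          exclusions = empty_exclusions()) {
  stopifnot(is.list(signatures))
  if (length(signatures) > 0 && is.null(names(signatures)))
    stop("signatures must be named")
  for (nm in names(signatures)) {
    s <- signatures[[nm]]
    if (!is.data.frame(s) || !all(c("gene", "direction") %in% names(s)))
      stop("signature '", nm, "' must be a data.frame(gene, direction)")
    if (anyDuplicated(s$gene))
      stop("signature '", nm, "' contains duplicate genes")
    bad <- !is.na(s$direction) & !(s$direction %in% c("up", "down"))
    if (any(bad)) stop("directions must be up/down/NA in '", nm, "'")
  }
  if (!identical(sort(names(provenance)), sort(names(signatures))))
    stop("provenance must carry one entry per signature")
  stopifnot(is.data.frame(exclusions),
            all(c("gene", "signature", "reason") %in% names(exclusions)))
  structure(list(signatures = signatures,
                 provenance = provenance[names(signatures)],
                 exclusions = exclusions),
            class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("signature_set: %d signatures, %d exclusions\n",
              length(x$signatures), nrow(x$exclusions)))
  for (nm in names(x$signatures))
    cat(sprintf("  %s [%s]: %d genes\n", nm, x$provenance[[nm]],
                nrow(x$signatures[[nm]])))
  invisible(x)
}

#' @rdname signature_set
#' @export
empty_exclusions <- function() {
  data.frame(gene = character(0), signature = character(0),
             reason = character(0), stringsAsFactors = FALSE)
}

#' Genes of one signature
#'
#' @param sigs a `signature_set`.
#' @param name signature name.
#' @return character vector of gene symbols.
#' @export
signature_genes <- function(sigs, name) {
  if (!name %in% names(sigs$signatures)) return(character(0))
  sigs$signatures[[name]]$gene
}
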