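#' Parameters for left-censored (MNAR) imputation
#'
#' Missing MIB-MS intensities are assumed to fall below the detection limit,
#' so they are imputed from a Gaussian shifted left of each sample's
#' observed distribution: Normal(mu_j - shift * sd_j, scale * sd_j). The
#' defaults (shift 3, scale 0.3 sample-SD units) are the standard
#' left-shifted manual imputation settings for this kind of data.
#'
#' @param shift left shift in units of the per-sample SD (>= 0).
#' @param scale width of the imputation distribution in per-sample SD units
#'   (> 0).
#' @param seed integer seed making imputation deterministic.
#' @return an `imputation_params` list.
#' @export
imputation_params <- function(shift = 3, scale = 0.3, seed = 1L) {
  if (shift < 0) stop("shift must be >= 0")
  if (scale <= 0) stop("scale must be > 0")
  structure(list(shift = shift, scale = scale, seed = as.integer(seed)),
            class = "imputation_params")
}

#' Impute missing intensities from a left-shifted Gaussian
#'
#' For each sample j, the observed (non-missing) values define mu_j and
#' sd_j (n-1 denominator); each missing cell is drawn independently from
#' Normal(mu_j - shift * sd_j, scale * sd_j). Observed cells are never
#' touched.
#'
#' @param m an [intensity_matrix()] with missing values.
#' @param params an [imputation_params()].
#' @return a complete [intensity_matrix()].
#' @export
impute_mnar <- function(m, params = imputation_params()) {
  stopifnot(inherits(m, "intensity_matrix"),
            inherits(params, "imputation_params"))
  vals <- m$values
  n_obs <- colSums(!is.na(vals))
  if (any(n_obs == 0))
    stop("all values missing in sample(s): ",
         paste(colnames(vals)[n_obs == 0], collapse = ", "))
  if (any(n_obs < 2))
    stop("need >= 2 observed values per sample; offending: ",
         paste(colnames(vals)[n_obs < 2], collapse = ", "))
  set.seed(substream_seed(params$seed, "impute_mnar"))
  for (j in seq_len(ncol(vals))) {
    miss <- is.na(vals[, j])
    if (!any(miss)) next
    mu <- mean(vals[!miss, j])
    sd_j <- stats::sd(vals[!miss, j])
    vals[miss, j] <- stats::rnorm(sum(miss),
                                  mean = mu - params$shift * sd_j,
                                  sd = params$scale * sd_j)
  }
  intensity_matrix(vals, m$samples)
}

#' Filter low-count and non-protein-coding genes
#'
#' Keeps genes with total count >= `min_total` and nonzero counts in at
#' least `min_samples` samples; when a roster is supplied, non-protein-coding
#' genes are also dropped. Counts in/out are reported via message.
#'
#' @param cm a [count_matrix()].
#' @param min_total minimum total count across samples.
#' @param min_samples minimum number of samples with count > 0.
#' @param roster optional [kinase_roster()] providing `is_protein_coding`.
#' @return the filtered [count_matrix()].
#' @export
filter_low_counts <- function(cm, min_total = 10, min_samples = 2,
                              roster = NULL) {
  stopifnot(inherits(cm, "count_matrix"), min_total >= 0, min_samples >= 0)
  keep <- rowSums(cm$counts) >= min_total &
    rowSums(cm$counts > 0) >= min_samples
  if (!is.null(roster)) {
    coding <- roster$symbol[roster$is_protein_coding]
    keep <- keep & rownames(cm$counts) %in% coding
  }
  message(sprintf("filter_low_counts: %d -> %d genes", nrow(cm$counts),
                  sum(keep)))
  if (!any(keep)) warning("no genes survive the low-count filter")
  count_matrix(cm$counts[keep, , drop = FALSE], cm$samples)
}

#' Median-of-ratios size factors
#'
#' Per sample j, s_j is the median over all-nonzero genes of
#' count_gj / geometric-mean_g(counts), then the factors are rescaled to
#' geometric mean 1.
#'
#' @param cm a [count_matrix()].
#' @return named numeric vector of size factors.
#' @export
size_factors <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  cts <- cm$counts
  ref_ok <- rowSums(cts > 0) == ncol(cts)
  if (!any(ref_ok))
    stop("no gene has nonzero counts in every sample; ",
         "consider a pseudo-reference fallback")
  sub <- cts[ref_ok, , drop = FALSE]
  geo <- exp(rowMeans(log(sub)))  # geometric mean per gene
  s <- apply(sub / geo, 2, stats::median)
  s <- s / exp(mean(log(s)))
  stats::setNames(s, colnames(cts))
}

#' Log2-normalized counts
#'
#' `log2(count / s_j + pseudocount)`; a monotone variance-stabilizing
#' surrogate used for clustering and visualization.
#'
#' @param cm a [count_matrix()].
#' @param s size factors from [size_factors()] (default computed).
#' @param pseudocount positive constant added before the log.
#' @return an [intensity_matrix()]-like object on the log2 scale.
#' @export
normalize_log <- function(cm, s = size_factors(cm), pseudocount = 1) {
  stopifnot(inherits(cm, "count_matrix"), pseudocount > 0)
  vals <- log2(sweep(cm$counts, 2, s[colnames(cm$counts)], "/") + pseudocount)
  intensity_matrix(vals, cm$samples)
}

#' Remove additive batch effects for visualization
#'
#' Per gene, fits a least-squares model with biological group and
#' sum-contrast batch covariates and subtracts the estimated batch term.
#' Used only for visualization/heatmaps; differential tests instead carry
#' batch in their design.
#'
#' @param m an [intensity_matrix()] (complete; impute first).
#' @param batch factor of batch labels per sample (defaults to metadata).
#' @param group factor of biological groups to protect (defaults to
#'   line x condition x treatment x timepoint).
#' @return the batch-corrected [intensity_matrix()].
#' @export
remove_batch <- function(m, batch = NULL, group = NULL) {
  stopifnot(inherits(m, "intensity_matrix"))
  md <- m$samples
  if (is.null(batch)) batch <- md$batch
  if (is.null(group))
    group <- interaction(md$line, md$condition, md$treatment, md$timepoint_h,
                         drop = TRUE)
  batch <- droplevels(as.factor(batch))
  group <- droplevels(as.factor(group))
  if (nlevels(batch) < 2) return(m)
  contrasts(batch) <- stats::contr.sum(nlevels(batch))
  design_group <- stats::model.matrix(~group)
  design_batch <- stats::model.matrix(~batch)[, -1, drop = FALSE]
  X <- cbind(design_group, design_batch)
  if (qr(X)$rank < ncol(X))
    stop("batch is confounded with the biological groups")
  fit <- stats::lm.fit(X, t(m$values))
  nb <- ncol(design_batch)
  beta_batch <- fit$coefficients[seq(ncol(design_group) + 1, ncol(X)), ,
                                 drop = FALSE]
  batch_term <- design_batch %*% beta_batch
  intensity_matrix(m$values - t(batch_term), m$samples)
}

#' Normalize TMT intensities to the untreated 0 h controls
#'
#' Per gene and line, subtracts the mean log2 intensity of that line's 0 h
#' samples, so every 0 h group mean becomes exactly 0 and later timepoints
#' read as log2 ratios to baseline.
#'
#' @param m an [intensity_matrix()] with a 0 h group in every line.
#' @return the baseline-normalized [intensity_matrix()].
#' @export
normalize_tmt_to_baseline <- function(m) {
  stopifnot(inherits(m, "intensity_matrix"))
  vals <- m$values
  for (ln in unique(m$samples$line)) {
    in_line <- m$samples$line == ln
    base <- in_line & m$samples$timepoint_h == 0
    if (!any(base)) stop("no 0 h control group for line ", ln)
    base_mean <- rowMeans(vals[, base, drop = FALSE])
    vals[, in_line] <- vals[, in_line, drop = FALSE] - base_mean
  }
  intensity_matrix(vals, m$samples)
}

#' Normalize to a reference cell line and clip
#'
#' Per gene, subtracts the mean value over the reference line's samples and
#' clips the result to [-clip, clip]; the transform used for supervised
#' signature heatmaps.
#'
#' @param m an [intensity_matrix()].
#' @param ref_line reference line id (e.g. the parental line).
#' @param clip clipping half-range (default 4).
#' @return the normalized, clipped [intensity_matrix()].
#' @export
normalize_to_reference_line <- function(m, ref_line, clip = 4) {
  stopifnot(inherits(m, "intensity_matrix"), clip > 0)
  ref <- m$samples$line == ref_line
  if (!any(ref)) stop("reference line not present: ", ref_line)
  vals <- m$values - rowMeans(m$values[, ref, drop = FALSE])
  vals <- pmin(pmax(vals, -clip), clip)
  intensity_matrix(vals, m$samples)
}
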