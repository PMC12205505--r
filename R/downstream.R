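#' Cross-omics Pearson correlation of fold changes
#'
#' Correlates protein-level and mRNA-level log2 fold changes over the genes
#' of a signature present in both layers.
#'
#' @param protein_l2fc,mrna_l2fc named numeric vectors of log2 fold changes.
#' @param genes optional gene set restricting the comparison (defaults to
#'   all genes shared by the two vectors).
#' @return list(r, p, n): Pearson r, two-sided p from the t transform, and
#'   the number of genes used.
#' @export
crossomics_correlation <- function(protein_l2fc, mrna_l2fc, genes = NULL) {
  common <- intersect(names(protein_l2fc), names(mrna_l2fc))
  if (!is.null(genes)) common <- intersect(common, genes)
  common <- common[is.finite(protein_l2fc[common]) &
                     is.finite(mrna_l2fc[common])]
  if (length(common) < 3)
    stop("need >= 3 genes with values in both omics layers")
  ct <- stats::cor.test(protein_l2fc[common], mrna_l2fc[common],
                        method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(common))
}

#' Hypergeometric over-representation analysis
#'
#' For each collection set S: with population N = |background|, successes
#' K = |S intersect background|, draws n = |query|, and overlap k, the
#' enrichment p-value is the upper tail P(X >= k); q-values are BH-adjusted
#' across collections.
#'
#' @param query gene set of interest (must be a subset of `background`).
#' @param collections named list of gene sets.
#' @param background universe of testable genes.
#' @return data.frame(name, set_size, overlap, p, q) sorted by p.
#' @export
ora_enrichment <- function(query, collections, background) {
  query <- unique(query); background <- unique(background)
  outside <- setdiff(query, background)
  if (length(outside) > 0)
    stop("query gene(s) outside background: ",
         paste(outside, collapse = ", "))
  stopifnot(is.list(collections), !is.null(names(collections)))
  N <- length(background); n <- length(query)
  rows <- lapply(names(collections), function(nm) {
    K <- length(intersect(collections[[nm]], background))
    k <- length(intersect(query, collections[[nm]]))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(name = nm, set_size = K, overlap = k, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out[order(out$p), ]
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of
#' `response = bottom + (top - bottom) / (1 + (dose/ic50)^hill)` with the
#' IC50 parameterized on the log scale and multi-start initialization over
#' a log-spaced IC50 grid to avoid local minima on sparse dose grids. A
#' flat response (relative range below `flat_tol` of its magnitude) is
#' flagged degenerate and returns no IC50.
#'
#' @param d a `dose_response_data` (or data.frame with dose, response).
#' @param flat_tol relative response range below which the fit is declared
#'   degenerate.
#' @return list(bottom, top, ic50, hill, converged, degenerate).
#' @export
fit_4pl <- function(d, flat_tol = 1e-6) {
  stopifnot(all(c("dose", "response") %in% names(d)))
  dose <- d$dose; y <- d$response
  if (any(dose <= 0)) stop("doses must be positive")
  if (length(unique(dose)) < 4) stop("need >= 4 distinct doses")
  rng <- diff(range(y))
  if (rng <= flat_tol * max(abs(y), 1))
    return(list(bottom = mean(y), top = mean(y), ic50 = NA_real_,
                hill = NA_real_, converged = FALSE, degenerate = TRUE))
  starts <- expand.grid(
    lic50 = unname(log(stats::quantile(dose, c(0.1, 0.25, 0.5, 0.75, 0.9)))),
    hill = c(0.5, 1, 2, -1))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(suppressWarnings(minpack.lm::nlsLM(
      y ~ bottom + (top - bottom) / (1 + (dose / exp(lic50))^hill),
      start = list(bottom = min(y), top = max(y),
                   lic50 = starts$lic50[i], hill = starts$hill[i]),
      control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    return(list(bottom = NA_real_, top = NA_real_, ic50 = NA_real_,
                hill = NA_real_, converged = FALSE, degenerate = FALSE))
  cf <- stats::coef(best$fit)
  bottom <- unname(cf["bottom"]); top <- unname(cf["top"])
  hill <- unname(cf["hill"])
  if (hill < 0) {  # equivalent parameterization: swap asymptotes
    tmp <- bottom; bottom <- top; top <- tmp
    hill <- -hill
  }
  list(bottom = bottom, top = top, ic50 = unname(exp(cf["lic50"])),
       hill = hill, converged = TRUE, degenerate = FALSE)
}

#' Evaluate a fitted 4PL curve
#'
#' @param params list with bottom, top, ic50, hill.
#' @param dose doses at which to evaluate.
#' @return predicted responses.
#' @export
predict_4pl <- function(params, dose) {
  params$bottom + (params$top - params$bottom) /
    (1 + (dose / params$ic50)^params$hill)
}

#' Mantel-Cox log-rank test with Kaplan-Meier medians
#'
#' Compares two arms of a survival dataset; medians follow the KM
#' step-function convention (smallest time with S(t) <= 0.5).
#'
#' @param s a `survival_data` data.frame (arm, time, event).
#' @param arm_a,arm_b arm labels to compare.
#' @return list(chi2, p, median_a, median_b).
#' @export
logrank_test <- function(s, arm_a, arm_b) {
  stopifnot(all(c("arm", "time", "event") %in% names(s)))
  sub <- s[s$arm %in% c(arm_a, arm_b), , drop = FALSE]
  if (!any(sub$arm == arm_a) || !any(sub$arm == arm_b))
    stop("both arms must be nonempty")
  if (!any(sub$event)) stop("no events in either arm")
  arm <- factor(sub$arm, levels = c(arm_a, arm_b))
  sd_fit <- survival::survdiff(survival::Surv(time, event) ~ arm, data = sub)
  chi2 <- unname(sd_fit$chisq)
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  med <- function(a) {
    fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                             data = sub[sub$arm == a, , drop = FALSE])
    unname(stats::quantile(fit, probs = 0.5)$quantile)
  }
  list(chi2 = chi2, p = p, median_a = med(arm_a), median_b = med(arm_b))
}
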