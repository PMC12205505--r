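#' Benjamini-Hochberg step-up adjusted p-values
#'
#' q_i = min over j with p_(j) >= p_(i) of m * p_(j) / j, capped at 1, in
#' the original order. NAs propagate and are excluded from m.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return vector of BH-adjusted q-values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  pp <- p[ok]
  m <- length(pp)
  if (m == 0) return(q)
  o <- order(pp, decreasing = TRUE)
  q[ok[o]] <- pmin(1, cummin(m / (m:1) * pp[o]))
  q
}

# Newton inversion of the trigamma function (used by the moment fit of the
# scaled-F prior on residual variances).
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

#' Moment fit of the variance prior (d0, s0^2)
#'
#' Models per-gene residual variances s^2 as s0^2 * F(d, d0) and estimates
#' the prior df d0 and prior variance s0^2 from the mean and variance of
#' log(s^2), matching them to digamma/trigamma moments. Returns d0 = Inf
#' when the observed spread of log-variances is no larger than expected from
#' sampling alone.
#'
#' @param s2 per-gene residual variances (> 0 entries used).
#' @param d residual degrees of freedom (scalar).
#' @return list(d0, s0_sq).
#' @export
fit_variance_prior <- function(s2, d) {
  usable <- is.finite(s2) & s2 > 0
  if (sum(usable) < 2)
    return(list(d0 = 0, s0_sq = if (any(usable)) mean(s2[usable]) else 1))
  z <- log(s2[usable])
  e <- z - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  evar <- stats::var(e) * (sum(usable) - 1) / sum(usable)
  spread <- evar - trigamma(d / 2)
  if (spread > 0) {
    d0 <- 2 * trigamma_inverse(spread)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- exp(emean)
  }
  list(d0 = d0, s0_sq = s0_sq)
}

# Shared design/contrast builder: group and optional batch covariate.
.design_contrast <- function(group, contrast, batch = NULL) {
  group <- as.factor(group)
  if (!all(contrast %in% levels(group)))
    stop("contrast group(s) absent: ",
         paste(setdiff(contrast, levels(group)), collapse = ", "))
  for (g in contrast)
    if (sum(group == g) < 2)
      stop("need >= 2 replicates in contrast group ", g)
  if (!is.null(batch)) {
    batch <- droplevels(as.factor(batch))
    if (nlevels(batch) < 2) batch <- NULL
  }
  if (is.null(batch)) {
    X <- stats::model.matrix(~ 0 + group)
    colnames(X) <- levels(group)
  } else {
    X <- stats::model.matrix(~ 0 + group + batch)
    colnames(X)[seq_len(nlevels(group))] <- levels(group)
    if (qr(X)$rank < ncol(X))
      stop("batch is confounded with the biological groups")
  }
  ct <- as.numeric(colnames(X) == contrast[1]) -
    as.numeric(colnames(X) == contrast[2])
  list(X = X, ct = ct)
}

#' Empirical-Bayes moderated t-test for log2 intensities
#'
#' Per gene, fits a least-squares linear model with group means and an
#' optional batch covariate, then shrinks residual variances toward a
#' moment-fitted prior: s~^2 = (d0 s0^2 + d s^2) / (d0 + d). The moderated
#' t statistic is l2fc / (se_unscaled * s~) on d + d0 degrees of freedom;
#' q-values come from [bh_adjust()].
#'
#' Forcing `d0 = 0` recovers the ordinary two-sample t-test; `d0 = Inf`
#' (with `s0_sq`) uses the prior variance exactly.
#'
#' @param m a complete [intensity_matrix()] (impute first).
#' @param group character/factor of biological group per sample.
#' @param contrast length-2 character: l2fc is group contrast[1] minus
#'   contrast[2].
#' @param batch optional batch labels included as additive covariates.
#' @param d0,s0_sq optional overrides of the fitted prior.
#' @return a `de_result` data.frame: gene, l2fc, se, stat, p, q,
#'   significant, direction (the last two filled by [call_de()]).
#' @export
moderated_t_test <- function(m, group, contrast, batch = NULL,
                             d0 = NULL, s0_sq = NULL) {
  stopifnot(inherits(m, "intensity_matrix"), length(contrast) == 2)
  if (anyNA(m$values))
    stop("matrix contains missing values; run impute_mnar() first")
  dc <- .design_contrast(group, contrast, batch)
  X <- dc$X; ct <- dc$ct
  n <- nrow(X)
  d <- n - ncol(X)
  if (d <= 0) stop("zero residual degrees of freedom")

  Y <- t(m$values)
  fit <- stats::lm.fit(X, Y)
  beta <- fit$coefficients
  res <- Y - X %*% beta
  s2 <- colSums(res^2) / d
  XtXinv <- chol2inv(chol(crossprod(X)))
  se_unscaled <- sqrt(drop(t(ct) %*% XtXinv %*% ct))
  lfc <- drop(t(ct) %*% beta)

  if (is.null(d0) || is.null(s0_sq)) {
    prior <- fit_variance_prior(s2, d)
    if (is.null(d0)) d0 <- prior$d0
    if (is.null(s0_sq)) s0_sq <- prior$s0_sq
  }
  s2_post <- if (is.infinite(d0)) rep(s0_sq, length(s2)) else
    (d0 * s0_sq + d * s2) / (d0 + d)
  se <- se_unscaled * sqrt(s2_post)
  stat <- lfc / se
  stat[se == 0 & lfc == 0] <- 0
  df_total <- d + d0
  p <- 2 * stats::pt(abs(stat), df = df_total, lower.tail = FALSE)
  de_result(rownames(m$values), lfc, se, stat, p)
}

#' Assemble a differential-expression result table
#'
#' @param gene,l2fc,se,stat,p parallel vectors.
#' @return `de_result` data.frame with BH q-values and unset calls.
#' @export
de_result <- function(gene, l2fc, se, stat, p) {
  out <- data.frame(gene = gene, l2fc = unname(l2fc), se = unname(se),
                    stat = unname(stat), p = unname(p),
                    q = bh_adjust(unname(p)),
                    significant = FALSE, direction = NA_character_,
                    stringsAsFactors = FALSE)
  class(out) <- c("de_result", "data.frame")
  out
}

#' Negative-binomial Wald test for RNA-seq counts
#'
#' Per gene: method-of-moments dispersion on size-factor-normalized counts,
#' shrunk on the log scale toward a fitted mean-dispersion trend
#' (alpha_trend = a / mean + b) with weight d / (d + d_prior); then an NB
#' GLM (log link, offsets log s_j, group + optional batch design) and a
#' Wald z = l2fc / se on the contrast. Genes with all-zero counts in both
#' contrast groups, or non-converged fits, are reported with NA p.
#'
#' @param cm a [count_matrix()].
#' @param s size factors (default [size_factors()]).
#' @param group,contrast,batch as in [moderated_t_test()].
#' @param d_prior prior degrees of freedom of the dispersion shrinkage.
#' @return a `de_result` data.frame (l2fc and se in log2 units).
#' @export
nb_wald_test <- function(cm, s = size_factors(cm), group, contrast,
                         batch = NULL, d_prior = 5) {
  stopifnot(inherits(cm, "count_matrix"), length(contrast) == 2)
  dc <- .design_contrast(group, contrast, batch)
  X <- dc$X; ct <- dc$ct
  cts <- cm$counts
  s <- s[colnames(cts)]
  d <- nrow(X) - ncol(X)
  if (d <= 0) stop("zero residual degrees of freedom")

  # method-of-moments dispersion on normalized counts
  k <- sweep(cts, 2, s, "/")
  grp <- as.factor(group)
  grp_means <- t(rowsum(t(k), grp) / as.vector(table(grp)))
  fitted_mean <- grp_means[, as.character(grp), drop = FALSE]
  resid_var <- rowSums((k - fitted_mean)^2) / (ncol(k) - nlevels(grp))
  mu_bar <- rowMeans(k)
  alpha_mom <- pmax((resid_var - mu_bar * mean(1 / s)) / mu_bar^2, 1e-8)
  alpha_mom[!is.finite(alpha_mom)] <- 1e-8

  use <- mu_bar > 0
  trend_fit <- stats::lm(alpha_mom[use] ~ I(1 / mu_bar[use]))
  alpha_trend <- pmax(stats::coef(trend_fit)[1] +
                        stats::coef(trend_fit)[2] / mu_bar, 1e-8)
  alpha_trend[!is.finite(alpha_trend)] <- 1e-8
  w <- d / (d + d_prior)
  alpha <- exp(w * log(alpha_mom) + (1 - w) * log(alpha_trend))

  in_contrast <- group %in% contrast
  off <- log(s)
  n_genes <- nrow(cts)
  lfc <- se <- stat <- p <- rep(NA_real_, n_genes)
  for (g in seq_len(n_genes)) {
    y <- cts[g, ]
    if (all(y[in_contrast] == 0)) next
    fam <- MASS::negative.binomial(theta = 1 / alpha[g], link = "log")
    fit <- tryCatch(
      suppressWarnings(stats::glm.fit(X, y, family = fam, offset = off)),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) next
    V <- tryCatch(chol2inv(chol(crossprod(X * sqrt(fit$weights)))),
                  error = function(e) NULL)
    if (is.null(V)) next
    est <- sum(ct * fit$coefficients)
    se_nat <- sqrt(drop(t(ct) %*% V %*% ct))
    lfc[g] <- est / log(2)
    se[g] <- se_nat / log(2)
    stat[g] <- est / se_nat
    p[g] <- 2 * stats::pnorm(abs(stat[g]), lower.tail = FALSE)
  }
  de_result(rownames(cts), lfc, se, stat, p)
}

#' Apply significance thresholds to a DE result
#'
#' significant iff q < fdr_thresh AND |l2fc| > lfc_thresh (both strict);
#' direction is the sign of l2fc for significant genes. RNA-seq calls use
#' lfc_thresh = 1; protein calls use the q threshold alone (lfc_thresh = 0).
#'
#' @param res a `de_result`.
#' @param lfc_thresh absolute log2-fold-change threshold (strict >).
#' @param fdr_thresh FDR threshold (strict <).
#' @return the `de_result` with significant/direction filled in.
#' @export
call_de <- function(res, lfc_thresh = 0, fdr_thresh = 0.05) {
  stopifnot(inherits(res, "de_result"), lfc_thresh >= 0, fdr_thresh >= 0)
  sig <- !is.na(res$q) & res$q < fdr_thresh & abs(res$l2fc) > lfc_thresh
  res$significant <- sig
  res$direction <- ifelse(sig, ifelse(res$l2fc > 0, "up", "down"),
                          NA_character_)
  res
}

#' Genes called significant in a DE result
#'
#' @param res a `de_result` after [call_de()].
#' @return character vector of significant genes.
#' @export
significant_genes <- function(res) res$gene[res$significant]
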