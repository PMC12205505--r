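# Independent brute-force oracles and small fixture builders used across the
# suite. Oracles are written from first principles and share no code with
# the implementation they check.

# BH step-up directly from the definition:
# q_i = min over j with p_(j) >= p_(i) of m * p_(j) / j, capped at 1.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ranks <- match(seq_len(m), o)  # rank of each p in sorted order
  sapply(seq_len(m), function(i) {
    js <- which(p[o] >= p[i] - 1e-15)
    min(1, min(m * p[o][js] / js))
  })
}

# Median-of-ratios size factors from the definition.
brute_size_factors <- function(counts) {
  ok <- apply(counts > 0, 1, all)
  geo <- exp(rowMeans(log(counts[ok, , drop = FALSE])))
  s <- apply(counts[ok, , drop = FALSE], 2, function(col) median(col / geo))
  s / exp(mean(log(s)))
}

# Exhaustive unique/shared partition + pattern counts over a logical
# membership matrix.
brute_partition <- function(member) {
  units <- colnames(member)
  uniq <- lapply(units, function(u)
    rownames(member)[sapply(rownames(member), function(g)
      member[g, u] && sum(member[g, ]) == 1)])
  shr <- lapply(units, function(u)
    rownames(member)[sapply(rownames(member), function(g)
      member[g, u] && sum(member[g, ]) >= 2)])
  names(uniq) <- names(shr) <- units
  pat_counts <- list()
  for (sz in seq_along(units)) {
    combos <- combn(units, sz, simplify = FALSE)
    for (cc in combos) {
      pat <- paste(cc, collapse = "&")
      pat_counts[[pat]] <- sum(sapply(rownames(member), function(g)
        all(member[g, cc]) && sum(member[g, ]) == length(cc)))
    }
  }
  list(unique = uniq, shared = shr, patterns = unlist(pat_counts))
}

# Log-rank O-E/V by walking the pooled risk tables.
brute_logrank <- function(time, event, is_a) {
  tt <- sort(unique(time[event]))
  O <- E <- V <- 0
  for (t0 in tt) {
    at_risk <- time >= t0
    n <- sum(at_risk); na <- sum(at_risk & is_a)
    d <- sum(time == t0 & event)
    da <- sum(time == t0 & event & is_a)
    O <- O + da
    E <- E + d * na / n
    if (n > 1) V <- V + d * (na / n) * (1 - na / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# Exact hypergeometric upper tail by summation.
brute_hyper_tail <- function(k, K, N, n) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# Minimal metadata for ad-hoc matrices.
toy_metadata <- function(ids, line = "L1", condition = "FS",
                         treatment = "none", timepoint_h = 0, batch = "B1",
                         replicate = seq_along(ids)) {
  data.frame(sample = ids, line = line, condition = condition,
             treatment = treatment, timepoint_h = timepoint_h,
             batch = batch, replicate = replicate,
             stringsAsFactors = FALSE)
}

toy_intensity <- function(values, ...) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("g%03d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  intensity_matrix(values, toy_metadata(colnames(values), ...))
}

# Hand-built zprofile_set for signature tests.
toy_zprofiles <- function(genes, directions, de_flags,
                          timepoints = c(0, 4, 24, 48)) {
  z <- matrix(0, length(genes), length(timepoints),
              dimnames = list(genes, paste0("t", timepoints)))
  structure(list(z = z, timepoints = timepoints,
                 direction = stats::setNames(directions, genes),
                 cluster = stats::setNames(rep(NA_integer_, length(genes)),
                                           genes),
                 temporal_de = stats::setNames(de_flags, genes)),
            class = "zprofile_set")
}

# de_result with chosen significance pattern for set-algebra tests.
toy_de_calls <- function(genes, sig_genes, dirs) {
  res <- de_result(genes, l2fc = rep(0, length(genes)),
                   se = rep(1, length(genes)), stat = rep(0, length(genes)),
                   p = rep(1, length(genes)))
  res$significant <- genes %in% sig_genes
  res$direction <- ifelse(res$significant, dirs[match(genes, sig_genes)],
                          NA_character_)
  res
}
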