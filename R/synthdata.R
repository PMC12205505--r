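#' Simulation configuration for synthetic kinome-rewiring studies
#'
#' Defines the study conditions the generators emulate: a parental
#' EGFRvIII-driven line plus a panel of TKI-resistant derivatives, profiled
#' by MIB-MS under two culture conditions (full serum FS, starved serum SS)
#' at roughly 300 quantified kinases per run, and by 4-timepoint TMT
#' time courses after acute EGFR-inhibitor challenge.
#'
#' Planted-architecture defaults: each resistant line carries its own unique
#' differential kinases plus a pool shared across lines (feeding the BL and
#' OL-BL signatures); the acute time course plants 26 up / 17 down
#' parental-only responders, matching the scale of EGFRi signatures reported
#' for this model system, alongside shared and direction-conflicted genes
#' that exercise the signature exclusion filters.
#'
#' @param n_kinases kinases quantified per MS run (~300).
#' @param parental parental line id.
#' @param resistant character vector of resistant line ids.
#' @param conditions culture conditions, subset of c("FS","SS").
#' @param replicates replicates per group (>= 2).
#' @param timepoints ordered hours for TMT time courses, starting at 0.
#' @param batch_count number of MS batches (LFQ only).
#' @param effect_l2fc planted absolute log2 fold change.
#' @param noise_sd residual SD of log2 intensities between replicates.
#' @param frac_unique,frac_shared fractions of the kinome planted as
#'   line-unique / line-shared differential kinases (sum <= 1).
#' @param dropout_quantile per-sample detection-limit quantile below which
#'   latent intensities go missing (MNAR).
#' @param nb_mean,nb_dispersion negative-binomial mean and dispersion for
#'   RNA-seq counts.
#' @param cross_omics_rho true Pearson correlation between planted protein
#'   and mRNA effects.
#' @param n_acute_up,n_acute_down parental-only acute responders planted up /
#'   down in the TMT time course.
#' @param n_acute_shared acute responders shared between parental and a
#'   resistant line (must not enter the EGFRi signature).
#' @param n_acute_conflict acute responders planted up in parental but down
#'   in a resistant line (removed as direction-ambiguous).
#' @param n_acute_resistant responders unique to each resistant line.
#' @param n_xcond_conflict genes planted unique in one culture condition but
#'   shared in the other (removed during BL reconciliation).
#' @param n_dir_conflict shared genes planted with opposite directions in FS
#'   vs SS (removed from OL-BL).
#' @param include_hegfr plant the exogenous hEGFR construct as a strong
#'   line-unique hit (must be excluded from BL signatures).
#' @param seed master seed; each generator uses a named substream.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_kinases = 300,
                       parental = "CEv3",
                       resistant = c("E4", "E5", "G1", "G5", "G8", "G12"),
                       conditions = c("FS", "SS"),
                       replicates = 3,
                       timepoints = c(0, 4, 24, 48),
                       batch_count = 2,
                       effect_l2fc = 2,
                       noise_sd = 0.3,
                       frac_unique = 0.10,
                       frac_shared = 0.05,
                       dropout_quantile = 0.10,
                       nb_mean = 100,
                       nb_dispersion = 0.1,
                       cross_omics_rho = 0.6,
                       n_acute_up = 26,
                       n_acute_down = 17,
                       n_acute_shared = 6,
                       n_acute_conflict = 4,
                       n_acute_resistant = 5,
                       n_xcond_conflict = 3,
                       n_dir_conflict = 3,
                       include_hegfr = TRUE,
                       seed = 1L) {
  cfg <- mget(names(formals()))
  if (cfg$replicates < 2) stop("invalid config: replicates must be >= 2")
  if (cfg$n_kinases < 10) stop("invalid config: n_kinases too small")
  if (parental %in% resistant) stop("parental line cannot be resistant")
  if (!all(conditions %in% c("FS", "SS")))
    stop("conditions must be a subset of FS/SS")
  if (cfg$frac_unique < 0 || cfg$frac_shared < 0 ||
      cfg$frac_unique > 1 || cfg$frac_shared > 1 ||
      cfg$frac_unique + cfg$frac_shared > 1)
    stop("fractions must lie in [0,1] and sum to <= 1")
  if (length(timepoints) < 2 || timepoints[1] != 0 ||
      any(diff(timepoints) <= 0))
    stop("timepoints must be strictly increasing and start at 0")
  if (cfg$dropout_quantile < 0 || cfg$dropout_quantile >= 1)
    stop("dropout_quantile must lie in [0,1)")
  if (cfg$nb_mean <= 0) stop("nb_mean must be > 0")
  if (cfg$nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  if (abs(cfg$cross_omics_rho) > 1) stop("cross_omics_rho must be in [-1,1]")
  structure(cfg, class = "sim_config")
}

# Gene symbols for one simulated kinome.
.sim_genes <- function(config) {
  n <- config$n_kinases
  if (config$include_hegfr)
    c("hEGFR", sprintf("KIN%04d", seq_len(n - 1)))
  else sprintf("KIN%04d", seq_len(n))
}

# Allocate non-overlapping random gene blocks from a pool; errors if
# exhausted. Sampling (not head-taking) keeps the planted architectures of
# different generators independent of each other.
.take <- function(pool, n) {
  if (n > length(pool$free)) stop("planted architecture exceeds kinome size")
  if (n == 0) return(character(0))
  idx <- sample.int(length(pool$free), n)
  taken <- pool$free[idx]
  pool$free <- pool$free[-idx]
  taken
}

#' Simulate a label-free MIB-MS proteome with MNAR dropout
#'
#' Log2 intensities are Normal(gene baseline + batch offset + planted
#' effect, noise_sd) with gene baselines ~ Normal(20, 2) (typical MS dynamic
#' range) and batch offsets ~ Normal(0, 0.5) shared by all genes in a batch.
#' Missingness is a detection limit: per sample, latent values below the
#' `dropout_quantile` quantile of that sample's latent distribution are
#' censored (missing not at random), mirroring the physics assumed by
#' left-shifted imputation.
#'
#' @param config a [sim_config()].
#' @return list with `matrix` (an [intensity_matrix()]) and `truth`: the
#'   planted membership table (gene, line, condition, direction, l2fc, role),
#'   the uncensored latent matrix, gene baselines and batch offsets, and the
#'   per-line BL / OL-BL truth sets implied by the planting.
#' @export
simulate_lfq_proteome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$replicates < 2) stop("invalid config: replicates must be >= 2")
  set.seed(substream_seed(config$seed, "lfq"))
  genes <- .sim_genes(config)
  lines <- c(config$parental, config$resistant)
  n_res <- length(config$resistant)

  pool <- new.env()
  pool$free <- setdiff(genes, "hEGFR")

  truth <- list()
  add <- function(gene, line, condition, direction, role) {
    truth[[length(truth) + 1]] <<- data.frame(
      gene = gene, line = line, condition = condition,
      direction = direction,
      l2fc = ifelse(direction == "up", 1, -1) * config$effect_l2fc,
      role = role, stringsAsFactors = FALSE)
  }

  # line-unique kinases, consistent across both conditions
  n_u <- max(1L, round(config$frac_unique * config$n_kinases / n_res))
  unique_by_line <- list()
  for (ln in config$resistant) {
    gs <- .take(pool, n_u)
    unique_by_line[[ln]] <- gs
    dirs <- sample(c("up", "down"), n_u, replace = TRUE)
    for (i in seq_along(gs))
      for (cc in config$conditions) add(gs[i], ln, cc, dirs[i], "unique")
  }

  # kinases shared by >= 2 lines, consistent direction everywhere
  n_s <- if (n_res >= 2) round(config$frac_shared * config$n_kinases) else 0L
  shared_genes <- .take(pool, n_s)
  for (g in shared_genes) {
    members <- sample(config$resistant, sample(2:n_res, 1))
    dir <- sample(c("up", "down"), 1)
    for (ln in members) for (cc in config$conditions) add(g, ln, cc, dir, "shared")
  }

  # unique-in-one-condition / shared-in-the-other conflicts (BL exclusions)
  xc_genes <- character(0)
  if (length(config$conditions) == 2 && n_res >= 2) {
    xc_genes <- .take(pool, config$n_xcond_conflict)
    for (i in seq_along(xc_genes)) {
      a <- config$resistant[(i - 1) %% n_res + 1]
      b <- setdiff(config$resistant, a)[1]
      dir <- sample(c("up", "down"), 1)
      add(xc_genes[i], a, "FS", dir, "xcond_conflict")
      add(xc_genes[i], a, "SS", dir, "xcond_conflict")
      add(xc_genes[i], b, "SS", dir, "xcond_conflict")
    }
  }

  # shared genes whose direction flips between conditions (OL-BL exclusions)
  dc_genes <- character(0)
  if (length(config$conditions) == 2 && n_res >= 2) {
    dc_genes <- .take(pool, config$n_dir_conflict)
    for (g in dc_genes) {
      members <- sample(config$resistant, 2)
      for (ln in members) {
        add(g, ln, "FS", "up", "dir_conflict")
        add(g, ln, "SS", "down", "dir_conflict")
      }
    }
  }

  # exogenous construct: strong hit unique to the first resistant line
  if (config$include_hegfr) {
    for (cc in config$conditions) {
      truth[[length(truth) + 1]] <- data.frame(
        gene = "hEGFR", line = config$resistant[1], condition = cc,
        direction = "up", l2fc = 2 * config$effect_l2fc,
        role = "hEGFR", stringsAsFactors = FALSE)
    }
  }
  membership <- do.call(rbind, truth)

  samples <- expand.grid(replicate = seq_len(config$replicates),
                         condition = config$conditions, line = lines,
                         stringsAsFactors = FALSE)
  samples <- data.frame(
    sample = sprintf("%s_%s_r%d", samples$line, samples$condition,
                     samples$replicate),
    line = samples$line, condition = samples$condition,
    treatment = "none", timepoint_h = 0,
    batch = sprintf("B%d", (samples$replicate - 1) %% config$batch_count + 1),
    replicate = samples$replicate, stringsAsFactors = FALSE)

  baseline <- stats::setNames(stats::rnorm(length(genes), 20, 2), genes)
  batches <- sort(unique(samples$batch))
  batch_off <- stats::setNames(stats::rnorm(length(batches), 0, 0.5), batches)

  mu <- matrix(baseline, nrow = length(genes), ncol = nrow(samples),
               dimnames = list(genes, samples$sample))
  mu <- sweep(mu, 2, batch_off[samples$batch], "+")
  for (i in seq_len(nrow(membership))) {
    idx <- samples$line == membership$line[i] &
      samples$condition == membership$condition[i]
    mu[membership$gene[i], idx] <- mu[membership$gene[i], idx] +
      membership$l2fc[i]
  }
  latent <- mu + matrix(stats::rnorm(length(mu), 0, config$noise_sd),
                        nrow = nrow(mu), dimnames = dimnames(mu))

  values <- latent
  if (config$dropout_quantile > 0) {
    for (j in seq_len(ncol(values))) {
      cut <- stats::quantile(latent[, j], config$dropout_quantile)
      values[latent[, j] < cut, j] <- NA_real_
    }
  }

  bl_truth <- unique_by_line
  olbl_truth <- shared_genes
  list(matrix = intensity_matrix(values, samples),
       truth = list(membership = membership, latent = latent,
                    baseline = baseline, batch_offsets = batch_off,
                    bl_truth = bl_truth, olbl_truth = olbl_truth,
                    excluded_xcond = xc_genes, excluded_dir = dc_genes))
}

#' Simulate a TMT MIB-MS time course after acute inhibitor challenge
#'
#' Every line is profiled at the configured timepoints (default 0/4/24/48 h)
#' with complete TMT channels (no missing values). A gene planted "up" in a
#' line rises linearly in expectation from its baseline at 0 h to baseline +
#' effect_l2fc at the final timepoint; "down" genes mirror this. The planted
#' architecture comprises parental-only responders (the EGFRi signature
#' ground truth), responders shared with a resistant line, direction
#' conflicts (up in parental, down in a resistant line), and resistant-only
#' responders.
#'
#' @param config a [sim_config()].
#' @return list with `matrix` (all lines; subset with [subset_samples()])
#'   and `truth` (temporal membership table plus `egfri_up` / `egfri_down`
#'   ground-truth gene sets).
#' @export
simulate_tmt_timecourse <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$timepoints[1] != 0) stop("timepoints must include 0")
  set.seed(substream_seed(config$seed, "tmt"))
  genes <- .sim_genes(config)
  lines <- c(config$parental, config$resistant)
  tps <- config$timepoints

  pool <- new.env()
  pool$free <- setdiff(genes, "hEGFR")

  rows <- list()
  add <- function(gene, line, direction, role) {
    rows[[length(rows) + 1]] <<- data.frame(
      gene = gene, line = line, direction = direction,
      l2fc = ifelse(direction == "up", 1, -1) * config$effect_l2fc,
      role = role, stringsAsFactors = FALSE)
  }

  up_genes <- .take(pool, config$n_acute_up)
  for (g in up_genes) add(g, config$parental, "up", "parental_only")
  down_genes <- .take(pool, config$n_acute_down)
  for (g in down_genes) add(g, config$parental, "down", "parental_only")

  shared <- .take(pool, config$n_acute_shared)
  for (g in shared) {
    dir <- sample(c("up", "down"), 1)
    add(g, config$parental, dir, "shared")
    add(g, sample(config$resistant, 1), dir, "shared")
  }
  conflict <- .take(pool, config$n_acute_conflict)
  for (g in conflict) {
    add(g, config$parental, "up", "conflict")
    add(g, sample(config$resistant, 1), "down", "conflict")
  }
  for (ln in config$resistant) {
    gs <- .take(pool, config$n_acute_resistant)
    for (g in gs) add(g, ln, sample(c("up", "down"), 1), "resistant_only")
  }
  membership <- do.call(rbind, rows)

  grid <- expand.grid(replicate = seq_len(config$replicates),
                      timepoint_h = tps, line = lines,
                      stringsAsFactors = FALSE)
  samples <- data.frame(
    sample = sprintf("%s_t%g_r%d", grid$line, grid$timepoint_h,
                     grid$replicate),
    line = grid$line, condition = "FS",
    treatment = ifelse(grid$timepoint_h == 0, "none", "EGFRi"),
    timepoint_h = grid$timepoint_h, batch = "B1",
    replicate = grid$replicate, stringsAsFactors = FALSE)

  baseline <- stats::setNames(stats::rnorm(length(genes), 20, 2), genes)
  mu <- matrix(baseline, nrow = length(genes), ncol = nrow(samples),
               dimnames = list(genes, samples$sample))
  tmax <- max(tps)
  for (i in seq_len(nrow(membership))) {
    idx <- which(samples$line == membership$line[i])
    mu[membership$gene[i], idx] <- mu[membership$gene[i], idx] +
      membership$l2fc[i] * samples$timepoint_h[idx] / tmax
  }
  values <- mu + matrix(stats::rnorm(length(mu), 0, config$noise_sd),
                        nrow = nrow(mu), dimnames = dimnames(mu))

  list(matrix = intensity_matrix(values, samples),
       truth = list(membership = membership,
                    egfri_up = up_genes, egfri_down = down_genes,
                    shared = shared, conflict = conflict))
}

#' Simulate an RNA-seq count matrix with planted fold changes
#'
#' Counts are negative binomial with mean `size_factor_j * q_g` and the
#' configured dispersion; planted genes multiply `q_g` by `2^l2fc` in the
#' treated group. True size factors are log2-spaced spanning slightly more
#' than 2-fold with geometric mean 1.
#'
#' @param config a [sim_config()].
#' @param n_genes number of genes.
#' @param frac_de fraction of genes planted differential (defaults to
#'   `config$frac_unique`).
#' @return list with `matrix` (a [count_matrix()]) and `truth` (planted
#'   l2fc per gene and the true size factors).
#' @export
simulate_rnaseq_counts <- function(config, n_genes = 2000,
                                   frac_de = config$frac_unique) {
  stopifnot(inherits(config, "sim_config"))
  if (config$nb_mean <= 0) stop("nb_mean must be > 0")
  if (config$nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  set.seed(substream_seed(config$seed, "rnaseq"))
  genes <- sprintf("G%05d", seq_len(n_genes))
  n_rep <- config$replicates
  samples <- data.frame(
    sample = c(sprintf("ctrl_r%d", seq_len(n_rep)),
               sprintf("trt_r%d", seq_len(n_rep))),
    line = config$parental, condition = "FS",
    treatment = rep(c("ctrl", "trt"), each = n_rep),
    timepoint_h = 0, batch = "B1",
    replicate = rep(seq_len(n_rep), 2), stringsAsFactors = FALSE)
  n_s <- nrow(samples)
  sf <- 2^seq(-0.55, 0.55, length.out = n_s)
  sf <- sf / exp(mean(log(sf)))

  n_de <- round(frac_de * n_genes)
  de_genes <- if (n_de > 0) sample(genes, n_de) else character(0)
  l2fc <- stats::setNames(rep(0, n_genes), genes)
  if (n_de > 0)
    l2fc[de_genes] <- sample(c(-1, 1), n_de, replace = TRUE) *
      config$effect_l2fc

  q <- matrix(config$nb_mean, n_genes, n_s, dimnames = list(genes, samples$sample))
  trt <- samples$treatment == "trt"
  q[, trt] <- q[, trt] * 2^l2fc
  mu <- sweep(q, 2, sf, "*")
  counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                  size = 1 / config$nb_dispersion),
                   nrow = n_genes, dimnames = dimnames(mu))
  list(matrix = count_matrix(counts, samples),
       truth = list(l2fc = l2fc, de_genes = de_genes, size_factors = sf))
}

#' Simulate paired protein/mRNA effect sizes with a given correlation
#'
#' Draws per-gene (protein, mRNA) log2 fold changes from a bivariate normal
#' with correlation `rho`, modelling the coupling between the two omics
#' layers used for cross-omics Pearson analysis.
#'
#' @param n_genes number of genes.
#' @param rho true correlation in [-1, 1].
#' @param sd marginal SD of each effect.
#' @param seed integer seed.
#' @return data.frame(gene, protein_l2fc, mrna_l2fc).
#' @export
simulate_crossomics_pairs <- function(n_genes, rho, sd = 1, seed = 1L) {
  if (abs(rho) > 1) stop("rho must lie in [-1,1]")
  set.seed(substream_seed(seed, "crossomics"))
  z1 <- stats::rnorm(n_genes); z2 <- stats::rnorm(n_genes)
  data.frame(gene = sprintf("G%05d", seq_len(n_genes)),
             protein_l2fc = sd * z1,
             mrna_l2fc = sd * (rho * z1 + sqrt(1 - rho^2) * z2),
             stringsAsFactors = FALSE)
}

#' Simulate two-arm survival data with exponential event times
#'
#' Control events are exponential with the given median; the treated arm's
#' hazard is multiplied by `hazard_ratio`, so its median scales as
#' 1/hazard_ratio in expectation. No censoring.
#'
#' @param median_ctrl control-arm median survival (days, > 0).
#' @param hazard_ratio treated/control hazard ratio (> 0).
#' @param n_per_arm animals per arm (>= 2).
#' @param seed integer seed.
#' @param arms arm labels.
#' @return data.frame(arm, time, event) of class `survival_data`.
#' @export
simulate_survival_arms <- function(median_ctrl, hazard_ratio, n_per_arm,
                                   seed = 1L,
                                   arms = c("control", "treated")) {
  if (median_ctrl <= 0) stop("median_ctrl must be > 0")
  if (hazard_ratio <= 0) stop("hazard_ratio must be > 0")
  if (n_per_arm < 2) stop("n_per_arm must be >= 2")
  set.seed(substream_seed(seed, "survival"))
  rate <- log(2) / median_ctrl
  out <- data.frame(
    arm = rep(arms, each = n_per_arm),
    time = c(stats::rexp(n_per_arm, rate),
             stats::rexp(n_per_arm, rate * hazard_ratio)),
    event = TRUE, stringsAsFactors = FALSE)
  class(out) <- c("survival_data", "data.frame")
  out
}

#' Simulate a dose-response experiment from a 4PL curve
#'
#' Responses follow the four-parameter logistic
#' `bottom + (top - bottom) / (1 + (dose/ic50)^hill)` (decreasing viability
#' for hill > 0) plus Gaussian noise, on a log-spaced dose grid spanning
#' `decades` decades centred on the IC50, with `n_replicates` technical
#' replicate wells per dose (viability assays of this kind are plated with
#' at least five technical replicates).
#'
#' @param ic50 true IC50 (same units as dose, > 0).
#' @param hill Hill slope.
#' @param n_doses number of distinct doses (>= 4).
#' @param noise_sd response noise SD.
#' @param seed integer seed.
#' @param bottom,top curve asymptotes.
#' @param decades width of the dose grid in log10 units (>= 2).
#' @param n_replicates technical replicate wells per dose.
#' @return data.frame(dose, response) of class `dose_response_data` with the
#'   true parameters as an attribute.
#' @export
simulate_dose_response <- function(ic50, hill = 1, n_doses = 8,
                                   noise_sd = 0, seed = 1L,
                                   bottom = 0, top = 100, decades = 3,
                                   n_replicates = 5) {
  if (ic50 <= 0) stop("ic50 must be > 0")
  if (n_doses < 4) stop("n_doses must be >= 4")
  if (decades < 2) stop("dose grid must span >= 2 decades")
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  set.seed(substream_seed(seed, "dose"))
  dose <- rep(ic50 * 10^seq(-decades / 2, decades / 2, length.out = n_doses),
              each = n_replicates)
  mu <- bottom + (top - bottom) / (1 + (dose / ic50)^hill)
  out <- data.frame(dose = dose,
                    response = mu + stats::rnorm(length(dose), 0, noise_sd))
  attr(out, "true_params") <- list(bottom = bottom, top = top, ic50 = ic50,
                                   hill = hill)
  class(out) <- c("dose_response_data", "data.frame")
  out
}

#' Subset an intensity or count matrix by sample
#'
#' @param m an [intensity_matrix()] or [count_matrix()].
#' @param keep logical or integer index over samples, or a predicate applied
#'   to the metadata data.frame.
#' @return the subsetted object.
#' @export
subset_samples <- function(m, keep) {
  if (is.function(keep)) keep <- keep(m$samples)
  if (inherits(m, "intensity_matrix"))
    intensity_matrix(m$values[, keep, drop = FALSE], m$samples[keep, , drop = FALSE])
  else if (inherits(m, "count_matrix"))
    count_matrix(m$counts[, keep, drop = FALSE], m$samples[keep, , drop = FALSE])
  else stop("unsupported object")
}
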