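test_that("generators are bit-identical under one seed and differ across seeds", {
  cfg <- sim_config(n_kinases = 60, resistant = c("R1", "R2"),
                    replicates = 2, n_acute_up = 6, n_acute_down = 4,
                    n_acute_shared = 2, n_acute_conflict = 2,
                    n_acute_resistant = 2, seed = 3)
  expect_identical(simulate_lfq_proteome(cfg), simulate_lfq_proteome(cfg))
  expect_identical(simulate_tmt_timecourse(cfg), simulate_tmt_timecourse(cfg))
  expect_identical(simulate_rnaseq_counts(cfg, n_genes = 50),
                   simulate_rnaseq_counts(cfg, n_genes = 50))
  expect_identical(simulate_dose_response(1, seed = 9),
                   simulate_dose_response(1, seed = 9))
  expect_identical(simulate_survival_arms(30, 2, 5, seed = 9),
                   simulate_survival_arms(30, 2, 5, seed = 9))

  cfg2 <- sim_config(n_kinases = 60, resistant = c("R1", "R2"),
                     replicates = 2, n_acute_up = 6, n_acute_down = 4,
                     n_acute_shared = 2, n_acute_conflict = 2,
                     n_acute_resistant = 2, seed = 4)
  expect_false(identical(simulate_lfq_proteome(cfg)$matrix$values,
                         simulate_lfq_proteome(cfg2)$matrix$values))
})

test_that("invalid study configurations are rejected", {
  expect_error(sim_config(replicates = 1), "replicates")
  expect_error(sim_config(timepoints = c(4, 24, 48)), "start at 0")
  expect_error(sim_config(timepoints = c(0, 24, 4)), "increasing")
  expect_error(sim_config(frac_unique = 0.8, frac_shared = 0.3), "sum")
  expect_error(sim_config(nb_mean = 0), "nb_mean")
  expect_error(sim_config(nb_dispersion = -1), "nb_dispersion")
  expect_error(simulate_survival_arms(30, 0, 5), "hazard_ratio")
  expect_error(simulate_survival_arms(-1, 1, 5), "median_ctrl")
  expect_error(simulate_dose_response(1, n_doses = 3), "n_doses")
  expect_error(simulate_dose_response(-2), "ic50")
  # minimal survival case runs
  expect_s3_class(simulate_survival_arms(30, 1, 2), "survival_data")
})

test_that("MNAR dropout censors the latent low tail at the configured rate", {
  cfg <- sim_config(n_kinases = 300, resistant = c("R1", "R2"),
                    replicates = 3, effect_l2fc = 0, frac_unique = 0,
                    frac_shared = 0, n_xcond_conflict = 0, n_dir_conflict = 0,
                    include_hegfr = FALSE, dropout_quantile = 0.2, seed = 11)
  sim <- simulate_lfq_proteome(cfg)
  miss <- is.na(sim$matrix$values)
  expect_equal(mean(miss), 0.2, tolerance = 0.05)
  # latent values behind missing cells sit below the observed ones
  tt <- t.test(sim$truth$latent[miss], sim$truth$latent[!miss],
               alternative = "less")
  expect_lt(tt$p.value, 0.01)

  # null config without dropout: complete matrix, group means agree
  cfg0 <- sim_config(n_kinases = 300, resistant = "R1", replicates = 3,
                     conditions = "FS", effect_l2fc = 0, frac_unique = 0,
                     frac_shared = 0, n_xcond_conflict = 0,
                     n_dir_conflict = 0, include_hegfr = FALSE,
                     dropout_quantile = 0, batch_count = 1, seed = 12)
  sim0 <- simulate_lfq_proteome(cfg0)
  expect_false(anyNA(sim0$matrix$values))
  grp <- sim0$matrix$samples$line
  diffs <- rowMeans(sim0$matrix$values[, grp == "R1"]) -
    rowMeans(sim0$matrix$values[, grp == "CEv3"])
  se <- cfg0$noise_sd * sqrt(2 / 3)
  expect_lt(mean(abs(diffs) > 3 * se), 0.02)
})

test_that("planted effects are recoverable from the generated matrices", {
  cfg <- sim_config(n_kinases = 200, resistant = c("R1", "R2"),
                    replicates = 4, effect_l2fc = 2, dropout_quantile = 0,
                    seed = 21)
  # LFQ: group-mean difference within 3 SE of the planted l2fc
  lfq <- simulate_lfq_proteome(cfg)
  mb <- lfq$truth$membership
  expect_true(all(mb$gene %in% rownames(lfq$matrix$values)))
  md <- lfq$matrix$samples
  for (i in sample(nrow(mb), 10)) {
    idx <- md$line == mb$line[i] & md$condition == mb$condition[i]
    ref <- md$line == cfg$parental & md$condition == mb$condition[i] &
      md$batch %in% md$batch[idx]
    est <- mean(lfq$matrix$values[mb$gene[i], idx]) -
      mean(lfq$matrix$values[mb$gene[i], ref])
    expect_lt(abs(est - mb$l2fc[i]), 3 * cfg$noise_sd * sqrt(2 / 4))
  }
  # TMT: 48h - 0h expectation equals the planted effect
  tmt <- simulate_tmt_timecourse(cfg)
  tm <- tmt$truth$membership
  smd <- tmt$matrix$samples
  g <- tm$gene[tm$direction == "up"][1]; ln <- tm$line[tm$direction == "up"][1]
  d48 <- mean(tmt$matrix$values[g, smd$line == ln & smd$timepoint_h == 48]) -
    mean(tmt$matrix$values[g, smd$line == ln & smd$timepoint_h == 0])
  expect_equal(d48, cfg$effect_l2fc, tolerance = 3 * cfg$noise_sd)
})

test_that("NB counts obey the Poisson limit and planted fold changes", {
  cfg <- sim_config(nb_dispersion = 1e-8, nb_mean = 100, replicates = 5,
                    seed = 31)
  sim <- simulate_rnaseq_counts(cfg, n_genes = 1000, frac_de = 0)
  k <- sweep(sim$matrix$counts, 2, sim$truth$size_factors, "/")
  ratio <- mean(apply(k, 1, var)) / mean(rowMeans(k))
  expect_equal(ratio, 1, tolerance = 0.1)

  cfg2 <- sim_config(nb_mean = 100, nb_dispersion = 0.1, effect_l2fc = 2,
                     replicates = 6, seed = 32)
  sim2 <- simulate_rnaseq_counts(cfg2, n_genes = 500, frac_de = 0.3)
  k2 <- sweep(sim2$matrix$counts, 2, sim2$truth$size_factors, "/")
  trt <- sim2$matrix$samples$treatment == "trt"
  up <- names(sim2$truth$l2fc)[sim2$truth$l2fc == 2]
  ratio_up <- rowMeans(k2[up, trt]) / rowMeans(k2[up, !trt])
  expect_equal(median(ratio_up), 4, tolerance = 0.2 * 4)
  # library sizes vary at least 2-fold
  expect_gte(max(sim2$truth$size_factors) / min(sim2$truth$size_factors), 2)
})

test_that("dose-response and survival generators follow their models", {
  d <- simulate_dose_response(ic50 = 1, hill = 1, n_doses = 6, noise_sd = 0,
                              n_replicates = 1, seed = 5)
  tp <- attr(d, "true_params")
  expect_equal(d$response,
               tp$bottom + (tp$top - tp$bottom) / (1 + (d$dose / tp$ic50)^tp$hill))
  # 4PL midpoint at the IC50
  mid <- simulate_dose_response(ic50 = 2, n_doses = 5, noise_sd = 0,
                                n_replicates = 1, seed = 5)
  expect_equal(predict_4pl(attr(mid, "true_params"), 2), 50)
  expect_gte(log10(max(d$dose) / min(d$dose)), 2)

  s <- simulate_survival_arms(30, 3, 2000, seed = 6)
  med <- tapply(s$time, s$arm, median)
  expect_equal(unname(med["treated"] / med["control"]), 1 / 3,
               tolerance = 0.15)
})

test_that("cross-omics pairs carry the configured correlation", {
  pp <- simulate_crossomics_pairs(5000, rho = 0.6, seed = 8)
  expect_equal(cor(pp$protein_l2fc, pp$mrna_l2fc), 0.6, tolerance = 0.05)
  expect_identical(pp, simulate_crossomics_pairs(5000, rho = 0.6, seed = 8))
})
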