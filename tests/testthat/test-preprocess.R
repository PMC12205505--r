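test_that("low-count filter applies thresholds, roster and matches brute force", {
  md <- toy_metadata(c("s1", "s2", "s3"))
  cts <- rbind(zero = c(0, 0, 0), low = c(3, 3, 3), edge = c(4, 3, 3),
               sparse = c(10, 0, 0), good = c(5, 5, 5))
  colnames(cts) <- md$sample
  cm <- count_matrix(cts, md)
  kept <- suppressMessages(filter_low_counts(cm, min_total = 10,
                                             min_samples = 2))
  expect_setequal(rownames(kept$counts), c("edge", "good"))

  # brute-force oracle on 100 random genes
  set.seed(1)
  cts2 <- matrix(rpois(400, 4), 100, 4,
                 dimnames = list(sprintf("g%03d", 1:100), paste0("s", 1:4)))
  cm2 <- count_matrix(cts2, toy_metadata(paste0("s", 1:4)))
  kept2 <- suppressMessages(filter_low_counts(cm2, 12, 3))
  oracle <- rownames(cts2)[sapply(seq_len(nrow(cts2)), function(i)
    sum(cts2[i, ]) >= 12 && sum(cts2[i, ] > 0) >= 3)]
  expect_setequal(rownames(kept2$counts), oracle)

  # roster drops non-coding genes
  roster <- kinase_roster(rownames(cts), is_protein_coding =
                            rownames(cts) != "good")
  kept3 <- suppressMessages(filter_low_counts(cm, 10, 2, roster))
  expect_setequal(rownames(kept3$counts), "edge")
})

test_that("MNAR imputation touches only missing cells and matches its model", {
  set.seed(7)
  vals <- matrix(rnorm(200 * 3, 20, 2), 200, 3,
                 dimnames = list(sprintf("g%03d", 1:200), c("a", "b", "c")))
  vals[sample(600, 90)] <- NA
  m <- intensity_matrix(vals, toy_metadata(c("a", "b", "c")))
  im <- impute_mnar(m, imputation_params(seed = 5))
  expect_false(anyNA(im$values))
  expect_identical(im$values[!is.na(vals)], vals[!is.na(vals)])
  # complete input returns identically
  full <- intensity_matrix(matrix(rnorm(20, 20, 1), 10, 2,
                                  dimnames = list(letters[1:10], c("a", "b"))),
                           toy_metadata(c("a", "b")))
  expect_identical(impute_mnar(full)$values, full$values)
  # deterministic per seed, different across seeds
  expect_identical(impute_mnar(m, imputation_params(seed = 5))$values,
                   im$values)
  expect_false(identical(impute_mnar(m, imputation_params(seed = 6))$values,
                         im$values))
  # Monte-Carlo: imputed cells follow Normal(mu - 3 sd, 0.3 sd)
  obs <- rnorm(200, 20, 2)
  big <- matrix(c(obs, rep(NA_real_, 10000)), ncol = 1,
                dimnames = list(sprintf("x%05d", 1:10200), "s1"))
  bim <- impute_mnar(intensity_matrix(big, toy_metadata("s1")),
                     imputation_params(seed = 11))
  imp <- bim$values[201:10200, 1]
  mu <- mean(obs); s <- sd(obs)
  expect_equal(mean(imp), mu - 3 * s, tolerance = 0.1)
  expect_equal(sd(imp), 0.3 * s, tolerance = 0.05)
  # all-missing sample is named in the error
  bad <- matrix(c(1, 2, NA, NA), 2, 2,
                dimnames = list(c("g1", "g2"), c("ok", "dead")))
  expect_error(impute_mnar(intensity_matrix(bad, toy_metadata(c("ok", "dead")))),
               "dead")
})

test_that("size factors equal hand values and the brute-force oracle", {
  md <- toy_metadata(c("s1", "s2"))
  same <- count_matrix(matrix(c(5, 8, 12, 5, 8, 12), 3,
                              dimnames = list(paste0("g", 1:3),
                                              md$sample)), md)
  expect_equal(unname(size_factors(same)), c(1, 1))

  dbl <- count_matrix(matrix(c(5, 8, 12, 10, 16, 24), 3,
                             dimnames = list(paste0("g", 1:3), md$sample)),
                      md)
  expect_equal(unname(size_factors(dbl)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-12)

  set.seed(3)
  for (rep in 1:5) {
    cts <- matrix(rpois(200, 50) + 1, 50, 4,
                  dimnames = list(sprintf("g%02d", 1:50), paste0("s", 1:4)))
    cm <- count_matrix(cts, toy_metadata(paste0("s", 1:4)))
    expect_equal(unname(size_factors(cm)), unname(brute_size_factors(cts)),
                 tolerance = 1e-12)
    # gene-order invariance
    perm <- sample(nrow(cts))
    cmp <- count_matrix(cts[perm, ], toy_metadata(paste0("s", 1:4)))
    expect_equal(size_factors(cmp), size_factors(cm), tolerance = 1e-12)
  }
  # no all-nonzero gene
  z <- count_matrix(matrix(c(0, 3, 3, 0), 2,
                           dimnames = list(c("g1", "g2"), md$sample)), md)
  expect_error(size_factors(z), "pseudo-reference")
})

test_that("log normalization matches arithmetic and is scale invariant", {
  md <- toy_metadata(c("s1", "s2"))
  cm <- count_matrix(matrix(c(0, 100, 0, 100), 2,
                            dimnames = list(c("g1", "g2"), md$sample)), md)
  s <- stats::setNames(c(1, 1), md$sample)
  nl <- normalize_log(cm, s, pseudocount = 1)
  expect_equal(unname(nl$values["g1", "s1"]), 0)
  expect_equal(unname(nl$values["g2", "s1"]), log2(101), tolerance = 1e-12)
  # doubling counts and size factors together changes nothing
  cm2 <- count_matrix(cm$counts * 2, md)
  expect_equal(normalize_log(cm2, s * 2, 1)$values, nl$values)
})

test_that("batch removal erases planted offsets but keeps group effects", {
  set.seed(9)
  md <- toy_metadata(paste0("s", 1:12),
                     line = rep(c("A", "B"), each = 6),
                     batch = rep(c("B1", "B2"), 6),
                     replicate = rep(1:6, 2))
  null_vals <- matrix(rnorm(50 * 12, 20, 0.5), 50, 12,
                      dimnames = list(sprintf("g%02d", 1:50), md$sample))
  vals <- null_vals
  vals[, md$batch == "B2"] <- vals[, md$batch == "B2"] + 2
  vals[, md$line == "B"] <- vals[, md$line == "B"] + 1.5
  m <- intensity_matrix(vals, md)
  out <- remove_batch(m)
  # planted batch offset removed
  bdiff <- rowMeans(out$values[, md$batch == "B2"]) -
    rowMeans(out$values[, md$batch == "B1"])
  expect_lt(max(abs(bdiff)), 1e-9)
  # planted biological effect preserved
  gdiff <- rowMeans(out$values[, md$line == "B"]) -
    rowMeans(out$values[, md$line == "A"])
  expect_equal(mean(gdiff), 1.5, tolerance = 0.1)
  # agrees with the reference implementation
  ref <- limma::removeBatchEffect(vals, batch = md$batch,
                                  design = stats::model.matrix(~md$line))
  expect_equal(out$values, ref, tolerance = 1e-8, ignore_attr = TRUE)
  # single batch: unchanged
  m1 <- intensity_matrix(null_vals, toy_metadata(paste0("s", 1:12),
                                                 line = rep(c("A", "B"),
                                                            each = 6)))
  expect_identical(remove_batch(m1)$values, null_vals)
  # confounded design rejected
  conf <- toy_metadata(paste0("s", 1:12), line = rep(c("A", "B"), each = 6),
                       batch = rep(c("B1", "B2"), each = 6))
  expect_error(remove_batch(intensity_matrix(null_vals, conf)), "confounded")
})

test_that("TMT baseline normalization zeroes the 0 h mean per line", {
  md <- toy_metadata(paste0("s", 1:8),
                     line = rep(c("P", "R"), each = 4),
                     treatment = rep(c("none", "none", "EGFRi", "EGFRi"), 2),
                     timepoint_h = rep(c(0, 0, 48, 48), 2),
                     replicate = rep(c(1, 2, 1, 2), 2))
  vals <- rbind(g1 = c(10, 12, 12, 12, 20, 20, 23, 23),
                g2 = c(5, 5, 6, 8, 7, 9, 8, 8))
  colnames(vals) <- md$sample
  out <- normalize_tmt_to_baseline(intensity_matrix(vals, md))
  for (ln in c("P", "R")) {
    base <- md$line == ln & md$timepoint_h == 0
    expect_equal(unname(rowMeans(out$values[, base])), c(0, 0),
                 tolerance = 1e-12)
  }
  # a 48 h value double the 0 h mean (linear scale) reads +1
  expect_equal(unname(out$values["g1", "s3"]), 1)  # 12 - mean(10,12) = 1
  # hand arithmetic for gene 2, line R: baseline mean 8
  expect_equal(unname(out$values["g2", md$line == "R"]),
               c(7, 9, 8, 8) - 8)
  # missing baseline errors
  md2 <- md; md2$timepoint_h[md2$line == "R"] <- 48
  expect_error(normalize_tmt_to_baseline(intensity_matrix(vals, md2)),
               "0 h")
})

test_that("reference-line normalization centers and clips", {
  md <- toy_metadata(paste0("s", 1:4), line = c("CEv3", "CEv3", "E5", "E5"))
  vals <- rbind(g1 = c(10, 12, 17.1, 17.1), g2 = c(20, 20, 16.1, 16.1))
  colnames(vals) <- md$sample
  out <- normalize_to_reference_line(intensity_matrix(vals, md), "CEv3",
                                     clip = 4)
  # reference replicates average exactly 0
  expect_equal(unname(rowMeans(out$values[, 1:2])), c(0, 0))
  # +6.1 above reference clips to 4; -3.9 stays
  expect_equal(unname(out$values["g1", "s3"]), 4)
  expect_equal(unname(out$values["g2", "s3"]), -3.9)
  expect_error(normalize_to_reference_line(intensity_matrix(vals, md), "X"),
               "reference line")
})
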