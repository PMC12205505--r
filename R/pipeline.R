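#' Run configuration for the two analysis branches
#'
#' Collects every tunable of the acquired-resistance (baseline) and acute
#' time-course branches: significance thresholds (protein q < 0.05; RNA
#' additionally |L2FC| > 1), left-censored imputation settings (shift 3,
#' scale 0.3), the 2-cluster K-means seed, and the parental/resistant line
#' layout.
#'
#' @param parental parental line id.
#' @param resistant resistant line ids.
#' @param conditions culture-condition labels.
#' @param fdr_thresh FDR threshold (strict <).
#' @param lfc_rna absolute L2FC threshold for RNA-seq calls (strict >).
#' @param lfc_protein absolute L2FC threshold for protein calls (0: q alone
#'   decides).
#' @param impute an [imputation_params()].
#' @param kmeans_k,kmeans_seed K-means cluster count and seed.
#' @param hegfr exogenous-construct symbols excluded from signatures.
#' @return a `run_config` list.
#' @export
run_config <- function(parental = "CEv3",
                       resistant = c("E4", "E5", "G1", "G5", "G8", "G12"),
                       conditions = c("FS", "SS"),
                       fdr_thresh = 0.05,
                       lfc_rna = 1,
                       lfc_protein = 0,
                       impute = imputation_params(),
                       kmeans_k = 2,
                       kmeans_seed = 1L,
                       hegfr = "hEGFR") {
  if (parental %in% resistant) stop("parental must not be a resistant line")
  if (fdr_thresh <= 0 || lfc_rna < 0 || lfc_protein < 0)
    stop("thresholds must be positive (fdr) / non-negative (lfc)")
  structure(list(parental = parental, resistant = resistant,
                 conditions = conditions, fdr_thresh = fdr_thresh,
                 lfc_rna = lfc_rna, lfc_protein = lfc_protein,
                 impute = impute, kmeans_k = kmeans_k,
                 kmeans_seed = as.integer(kmeans_seed), hegfr = hegfr),
            class = "run_config")
}

# Per-condition DE of every resistant line vs parental on an imputed LFQ
# matrix; batch enters the design when more than one batch is present.
.condition_de <- function(m, cfg) {
  imputed <- impute_mnar(m, cfg$impute)
  batch <- if (length(unique(imputed$samples$batch)) > 1)
    imputed$samples$batch else NULL
  calls <- list()
  for (ln in cfg$resistant) {
    res <- moderated_t_test(imputed, group = imputed$samples$line,
                            contrast = c(ln, cfg$parental), batch = batch)
    calls[[ln]] <- call_de(res, lfc_thresh = cfg$lfc_protein,
                           fdr_thresh = cfg$fdr_thresh)
  }
  calls
}

#' Acquired-resistance branch: BL and OL-BL signatures
#'
#' Imputes each culture condition's LFQ matrix, tests every resistant line
#' against the parental line (moderated t, batch in the design), partitions
#' DE kinases into unique/shared per condition, reconciles conditions into
#' per-line BL signatures (hEGFR and cross-condition conflicts removed,
#' logged) and builds the direction-consistent OL-BL signature.
#'
#' @param lfq_by_condition named list (FS/SS) of [intensity_matrix()]
#'   objects covering parental and resistant lines.
#' @param cfg a [run_config()].
#' @return list(bl, ol_bl, partitions, membership, de_calls, provenance).
#' @export
run_baseline_branch <- function(lfq_by_condition, cfg = run_config()) {
  stopifnot(is.list(lfq_by_condition), length(lfq_by_condition) >= 1)
  conds <- names(lfq_by_condition)
  de_calls <- lapply(lfq_by_condition, .condition_de, cfg = cfg)
  mm <- lapply(de_calls, membership_matrix)
  parts <- lapply(mm, unique_shared_partition)
  if (all(c("FS", "SS") %in% conds)) {
    bl <- reconcile_conditions(parts$FS, parts$SS, mm$FS, mm$SS,
                               hegfr = cfg$hegfr)
    ol <- overlapping_bl(mm$FS, mm$SS)
  } else {
    warning("single culture condition: degraded single-condition BL")
    cc <- conds[1]
    bl <- reconcile_conditions(parts[[cc]], parts[[cc]], mm[[cc]], mm[[cc]],
                               hegfr = cfg$hegfr)
    ol <- overlapping_bl(mm[[cc]], mm[[cc]])
  }
  list(bl = bl, ol_bl = ol, partitions = parts, membership = mm,
       de_calls = de_calls,
       provenance = sprintf("config=%s seed=%d", config_hash(cfg),
                            cfg$impute$seed))
}

# Temporal classification of one line's TMT time course.
.line_temporal <- function(m, cfg) {
  norm <- normalize_tmt_to_baseline(m)
  tps <- sort(unique(norm$samples$timepoint_h))
  if (tps[1] != 0) stop("no 0 h baseline in the time course")
  de_by_tp <- list()
  for (tt in tps[-1]) {
    keep <- norm$samples$timepoint_h %in% c(0, tt)
    sub <- subset_samples(norm, keep)
    grp <- paste0("t", sub$samples$timepoint_h)
    res <- moderated_t_test(sub, group = grp,
                            contrast = c(paste0("t", tt), "t0"))
    de_by_tp[[paste0("t", tt)]] <- call_de(res,
                                           lfc_thresh = cfg$lfc_protein,
                                           fdr_thresh = cfg$fdr_thresh)
  }
  flagged <- flag_temporal_de(de_by_tp)
  zp <- timepoint_zprofiles(norm)
  if (length(flagged) >= 2)
    zp <- kmeans_direction(zp, flagged, k = cfg$kmeans_k,
                           seed = cfg$kmeans_seed)
  list(zprofiles = zp, de_by_timepoint = de_by_tp, flagged = flagged)
}

#' Acute branch: temporal classification and the EGFRi signature
#'
#' Per line: normalizes the TMT time course to the 0 h controls, tests each
#' later timepoint against 0 h (moderated t), flags temporal DE as the
#' union over timepoints, computes z-profiles and 2-cluster K-means
#' directions; then removes cross-line direction conflicts and defines the
#' EGFRi signature as the parental-unique temporal DE kinases, split
#' up/down.
#'
#' @param tmt an [intensity_matrix()] time course covering the parental and
#'   resistant lines (or a named per-line list).
#' @param cfg a [run_config()].
#' @return list(egfri, temporal (per line), comparison vs optional `bl`),
#' @param bl optional baseline-branch output for cross-signature comparison.
#' @export
run_acute_branch <- function(tmt, cfg = run_config(), bl = NULL) {
  per_line <- if (inherits(tmt, "intensity_matrix")) {
    lns <- unique(tmt$samples$line)
    stats::setNames(lapply(lns, function(ln)
      subset_samples(tmt, tmt$samples$line == ln)), lns)
  } else tmt
  needed <- c(cfg$parental, cfg$resistant)
  missing_lines <- setdiff(needed, names(per_line))
  if (length(missing_lines) > 0)
    stop("time course missing line(s): ",
         paste(missing_lines, collapse = ", "))
  temporal <- lapply(per_line[needed], .line_temporal, cfg = cfg)
  egfri <- egfri_signature(temporal[[cfg$parental]]$zprofiles,
                           lapply(temporal[cfg$resistant],
                                  function(x) x$zprofiles))
  comparison <- NULL
  if (!is.null(bl)) {
    both <- signature_set(
      c(bl$bl$signatures, bl$ol_bl$signatures, egfri$signatures),
      c(bl$bl$provenance, bl$ol_bl$provenance, egfri$provenance),
      empty_exclusions())
    comparison <- compare_signatures(both)
  }
  list(egfri = egfri, temporal = temporal, comparison = comparison,
       provenance = sprintf("config=%s seed=%d", config_hash(cfg),
                            cfg$kmeans_seed))
}

#' Write the artifacts of a baseline or acute run
#'
#' Persists signatures (GMT), the exclusion audit log (TSV) and, when
#' present, per-line z-profile tables, each stamped with the run's
#' provenance (config hash + seed).
#'
#' @param run output of [run_baseline_branch()] or [run_acute_branch()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisible character vector of the files written.
#' @export
write_run <- function(run, dir, prefix) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  sigs <- if (!is.null(run$egfri)) run$egfri else {
    signature_set(c(run$bl$signatures, run$ol_bl$signatures),
                  c(run$bl$provenance, run$ol_bl$provenance),
                  rbind(run$bl$exclusions, run$ol_bl$exclusions))
  }
  f1 <- file.path(dir, paste0(prefix, "_signatures.gmt"))
  write_signatures(sigs, f1, provenance_comment = run$provenance)
  f2 <- file.path(dir, paste0(prefix, "_exclusions.tsv"))
  write_exclusion_log(sigs, f2)
  files <- c(f1, f2)
  if (!is.null(run$temporal)) {
    for (ln in names(run$temporal)) {
      f <- file.path(dir, paste0(prefix, "_zprofiles_", ln, ".tsv"))
      write_tsv_prov(zprofiles_table(run$temporal[[ln]]$zprofiles), f,
                     provenance = run$provenance)
      files <- c(files, f)
    }
  }
  invisible(files)
}
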