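#' Z-score trajectories over timepoints
#'
#' Per gene: the median over replicates at each timepoint, standardized
#' across timepoints ((median_t - mean) / SD, n-1 denominator), then every
#' z divided by the global SD of the full z collection so profiles are
#' scaled across the captured kinome/transcriptome. Genes with zero
#' across-timepoint SD get an all-zero profile.
#'
#' @param m an [intensity_matrix()] (or log-normalized counts) whose
#'   metadata carries `timepoint_h`; expects a single line.
#' @return a `zprofile_set`: list(z = genes x timepoints matrix,
#'   timepoints, direction, cluster, temporal_de).
#' @export
timepoint_zprofiles <- function(m) {
  stopifnot(inherits(m, "intensity_matrix"))
  tps <- sort(unique(m$samples$timepoint_h))
  if (length(tps) < 2) stop("need >= 2 distinct timepoints")
  med <- sapply(tps, function(tt) {
    idx <- m$samples$timepoint_h == tt
    if (!any(idx)) stop("timepoint with zero samples: ", tt)
    apply(m$values[, idx, drop = FALSE], 1, stats::median)
  })
  colnames(med) <- paste0("t", tps)
  mu <- rowMeans(med)
  sdv <- apply(med, 1, stats::sd)
  z <- (med - mu) / ifelse(sdv == 0, 1, sdv)
  z[sdv == 0, ] <- 0
  gs <- stats::sd(as.vector(z))
  if (is.finite(gs) && gs > 0) z <- z / gs
  structure(list(z = z, timepoints = tps,
                 direction = stats::setNames(rep("none", nrow(z)), rownames(z)),
                 cluster = stats::setNames(rep(NA_integer_, nrow(z)), rownames(z)),
                 temporal_de = stats::setNames(rep(FALSE, nrow(z)), rownames(z))),
            class = "zprofile_set")
}

#' Flag temporal differential expression vs the 0 h baseline
#'
#' A gene is temporally DE if any pairwise comparison against the 0 h
#' baseline calls it significant: the union of significant genes over the
#' supplied per-timepoint DE results.
#'
#' @param de_by_timepoint list of `de_result` objects (after [call_de()]),
#'   one per non-zero timepoint vs 0 h.
#' @return character vector of flagged genes.
#' @export
flag_temporal_de <- function(de_by_timepoint) {
  stopifnot(is.list(de_by_timepoint))
  unique(unlist(lapply(de_by_timepoint, significant_genes),
                use.names = FALSE))
}

# k-means++ seeding: spread initial centers proportionally to squared
# distance from the nearest chosen center.
.kmeanspp_centers <- function(z, k) {
  n <- nrow(z)
  centers <- z[sample.int(n, 1), , drop = FALSE]
  while (nrow(centers) < k) {
    d2 <- apply(z, 1, function(row)
      min(colSums((t(centers) - row)^2)))
    if (all(d2 == 0)) {
      centers <- rbind(centers, z[sample.int(n, 1), , drop = FALSE])
    } else {
      centers <- rbind(centers, z[sample.int(n, 1, prob = d2), , drop = FALSE])
    }
  }
  unname(centers)
}

#' Directional classification of DE genes by 2-cluster K-means
#'
#' Restricted to temporally DE genes, clusters the z trajectories into k = 2
#' groups (k-means++ seeding, 10 restarts, Euclidean distance; genes sorted
#' by name first so the result is invariant to input order). A cluster is
#' labeled "up" when its mean z at the final timepoint minus its mean z at
#' 0 h is positive, "down" when negative, and "ambiguous" on an exact tie
#' (logged). Non-DE genes keep direction "none".
#'
#' @param zp a `zprofile_set` from [timepoint_zprofiles()].
#' @param de_genes character vector of temporally DE genes (>= 2).
#' @param k number of clusters (2).
#' @param seed integer seed.
#' @param restarts number of k-means++ restarts.
#' @return the `zprofile_set` with cluster, direction and temporal_de set.
#' @export
kmeans_direction <- function(zp, de_genes, k = 2, seed = 1L, restarts = 10) {
  stopifnot(inherits(zp, "zprofile_set"))
  de_genes <- sort(intersect(unique(de_genes), rownames(zp$z)))
  if (length(de_genes) < 2) stop("need >= 2 DE genes to cluster")
  z <- zp$z[de_genes, , drop = FALSE]

  n_distinct <- nrow(unique(z))
  set.seed(substream_seed(seed, "kmeans_direction"))
  if (n_distinct < k) {
    assign_vec <- rep(1L, nrow(z))
  } else {
    best <- NULL
    for (r in seq_len(restarts)) {
      km <- tryCatch(
        stats::kmeans(z, centers = .kmeanspp_centers(z, k), iter.max = 100),
        error = function(e) NULL)
      if (!is.null(km) && (is.null(best) || km$tot.withinss < best$tot.withinss))
        best <- km
    }
    if (is.null(best)) stop("k-means failed on the DE z-profiles")
    assign_vec <- best$cluster
  }

  first_col <- 1L
  last_col <- ncol(z)
  labels <- vapply(sort(unique(assign_vec)), function(cl) {
    idx <- assign_vec == cl
    diff48 <- mean(z[idx, last_col]) - mean(z[idx, first_col])
    if (diff48 > 0) "up" else if (diff48 < 0) "down" else "ambiguous"
  }, character(1))
  if (any(labels == "ambiguous"))
    message("kmeans_direction: tie at 48h-0h mean difference; ",
            "cluster(s) labeled ambiguous")

  zp$direction[] <- "none"
  zp$direction[de_genes] <- labels[assign_vec]
  zp$cluster[] <- NA_integer_
  zp$cluster[de_genes] <- as.integer(assign_vec)
  zp$temporal_de[] <- FALSE
  zp$temporal_de[de_genes] <- TRUE
  zp
}

#' Export a zprofile set as a data frame
#'
#' @param zp a `zprofile_set`.
#' @return data.frame with gene, per-timepoint z columns, cluster,
#'   direction, temporal_de.
#' @export
zprofiles_table <- function(zp) {
  stopifnot(inherits(zp, "zprofile_set"))
  data.frame(gene = rownames(zp$z), zp$z,
             cluster = unname(zp$cluster),
             direction = unname(zp$direction),
             temporal_de = unname(zp$temporal_de),
             stringsAsFactors = FALSE, check.names = FALSE)
}
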