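#' Boolean/direction membership matrices from per-unit DE calls
#'
#' Rows are the union of all significant genes, columns the units (cell
#' lines or line x condition), with a parallel direction matrix taking
#' "up"/"down" where a gene is a member and "none" elsewhere.
#'
#' @param de_calls named list of `de_result` objects (after [call_de()]),
#'   one per unit.
#' @return list(member = logical matrix, direction = character matrix).
#' @export
membership_matrix <- function(de_calls) {
  stopifnot(is.list(de_calls), length(de_calls) > 0,
            !is.null(names(de_calls)))
  units <- names(de_calls)
  genes <- sort(unique(unlist(lapply(de_calls, significant_genes),
                              use.names = FALSE)))
  member <- matrix(FALSE, length(genes), length(units),
                   dimnames = list(genes, units))
  direction <- matrix("none", length(genes), length(units),
                      dimnames = list(genes, units))
  for (u in units) {
    res <- de_calls[[u]]
    sig <- res[res$significant, , drop = FALSE]
    member[sig$gene, u] <- TRUE
    direction[sig$gene, u] <- sig$direction
  }
  list(member = member, direction = direction)
}

#' Unique/shared partition and upset intersection counts
#'
#' A gene is unique to a unit when it is a member of exactly one unit, and
#' shared when a member of two or more. Upset counts tabulate every
#' nonempty membership pattern (all 2^n - 1 patterns for n <= max_enumerate
#' units; only observed patterns beyond that).
#'
#' @param mm output of [membership_matrix()].
#' @param max_enumerate largest unit count for exhaustive pattern
#'   enumeration.
#' @return list(unique = per-unit gene lists, shared = per-unit gene lists,
#'   upset = data.frame(pattern, count)).
#' @export
unique_shared_partition <- function(mm, max_enumerate = 8) {
  member <- mm$member
  if (ncol(member) < 2) stop("need >= 2 units to partition")
  n_member <- rowSums(member)
  units <- colnames(member)
  uniq <- lapply(units, function(u)
    rownames(member)[member[, u] & n_member == 1])
  shr <- lapply(units, function(u)
    rownames(member)[member[, u] & n_member >= 2])
  names(uniq) <- names(shr) <- units

  pattern_of <- apply(member, 1, function(row)
    paste(units[row], collapse = "&"))
  if (ncol(member) <= max_enumerate) {
    pats <- unlist(lapply(seq_along(units), function(sz)
      utils::combn(units, sz, paste, collapse = "&")))
    counts <- stats::setNames(integer(length(pats)), pats)
    obs <- table(pattern_of)
    counts[names(obs)] <- as.integer(obs)
  } else {
    obs <- sort(table(pattern_of), decreasing = TRUE)
    counts <- stats::setNames(as.integer(obs), names(obs))
  }
  list(unique = uniq, shared = shr,
       upset = data.frame(pattern = names(counts),
                          count = unname(counts),
                          stringsAsFactors = FALSE))
}

# Consistent single direction across a set of direction labels, or NA when
# they conflict.
.consensus_direction <- function(dirs) {
  dirs <- unique(dirs[dirs %in% c("up", "down")])
  if (length(dirs) == 1) dirs else NA_character_
}

#' Reconcile culture conditions into per-line baseline (BL) signatures
#'
#' Per resistant line, BL = (unique in FS) union (unique in SS), minus
#' genes unique in one condition but shared in the other
#' (cross-condition-conflict), minus the exogenous hEGFR construct. Every
#' exclusion is logged with its reason. Directions (when matrices are
#' supplied) are the consensus across conditions, NA on conflict.
#'
#' @param part_fs,part_ss outputs of [unique_shared_partition()] for the
#'   full-serum and starved-serum membership matrices (same unit universe).
#' @param mm_fs,mm_ss optional membership matrices providing directions.
#' @param hegfr symbol(s) of exogenous constructs to remove.
#' @return a [signature_set()] with one `BL_<line>` signature per line.
#' @export
reconcile_conditions <- function(part_fs, part_ss, mm_fs = NULL,
                                 mm_ss = NULL, hegfr = "hEGFR") {
  units <- names(part_fs$unique)
  if (!identical(sort(units), sort(names(part_ss$unique))))
    stop("FS and SS partitions cover different units")
  signatures <- list(); provenance <- character(0)
  excl <- list()
  note <- function(gene, sig, reason)
    excl[[length(excl) + 1]] <<- data.frame(gene = gene, signature = sig,
                                            reason = reason,
                                            stringsAsFactors = FALSE)
  for (u in units) {
    sig_name <- paste0("BL_", u)
    cand <- union(part_fs$unique[[u]], part_ss$unique[[u]])
    keep <- character(0)
    for (g in cand) {
      if (g %in% hegfr) {
        note(g, sig_name, "hEGFR")
      } else if ((g %in% part_fs$unique[[u]] && g %in% unlist(part_ss$shared)) ||
                 (g %in% part_ss$unique[[u]] && g %in% unlist(part_fs$shared))) {
        note(g, sig_name, "cross-condition-conflict")
      } else {
        keep <- c(keep, g)
      }
    }
    dirs <- vapply(keep, function(g) {
      d <- character(0)
      if (!is.null(mm_fs) && g %in% rownames(mm_fs$direction))
        d <- c(d, mm_fs$direction[g, u])
      if (!is.null(mm_ss) && g %in% rownames(mm_ss$direction))
        d <- c(d, mm_ss$direction[g, u])
      .consensus_direction(d)
    }, character(1))
    signatures[[sig_name]] <- data.frame(gene = keep,
                                         direction = unname(dirs),
                                         stringsAsFactors = FALSE)
    provenance[sig_name] <- "unique-BL"
  }
  signature_set(signatures, provenance,
                if (length(excl)) do.call(rbind, excl) else empty_exclusions())
}

#' Overlapping baseline (OL-BL) signature
#'
#' Kinases shared by at least `min_lines` resistant lines in both culture
#' conditions, restricted to those with one consistent direction across all
#' member lines and both conditions; direction conflicts are excluded and
#' logged.
#'
#' @param mm_fs,mm_ss membership matrices with directions for the two
#'   culture conditions.
#' @param min_lines minimum number of member lines per condition.
#' @return a [signature_set()] with one `OL_BL` signature.
#' @export
overlapping_bl <- function(mm_fs, mm_ss, min_lines = 2) {
  shared_fs <- rownames(mm_fs$member)[rowSums(mm_fs$member) >= min_lines]
  shared_ss <- rownames(mm_ss$member)[rowSums(mm_ss$member) >= min_lines]
  cand <- intersect(shared_fs, shared_ss)
  excl <- list(); keep <- character(0); dirs <- character(0)
  for (g in cand) {
    d <- c(mm_fs$direction[g, mm_fs$member[g, ]],
           mm_ss$direction[g, mm_ss$member[g, ]])
    cons <- .consensus_direction(d)
    if (is.na(cons)) {
      excl[[length(excl) + 1]] <- data.frame(gene = g, signature = "OL_BL",
                                             reason = "direction-ambiguous",
                                             stringsAsFactors = FALSE)
    } else {
      keep <- c(keep, g); dirs <- c(dirs, cons)
    }
  }
  signature_set(list(OL_BL = data.frame(gene = keep, direction = dirs,
                                        stringsAsFactors = FALSE)),
                c(OL_BL = "OL-BL"),
                if (length(excl)) do.call(rbind, excl) else empty_exclusions())
}

#' Acute EGFR-inhibitor (EGFRi) signature
#'
#' Two-step filter over temporal directional calls: (1) genes whose
#' direction conflicts between any two lines (up in one, down in another)
#' are removed as ambiguous; (2) the EGFRi signature is the parental line's
#' temporally DE genes that are not temporally DE in any resistant line,
#' partitioned into EGFRi-up / EGFRi-down by parental direction. Parental
#' DE genes also DE in a resistant line are logged as shared.
#'
#' @param parental_zp `zprofile_set` of the drug-sensitive parental line
#'   (after [kmeans_direction()]).
#' @param resistant_zps named list of `zprofile_set`s for the resistant
#'   lines.
#' @return a [signature_set()] with `EGFRi_up` and `EGFRi_down` signatures.
#' @export
egfri_signature <- function(parental_zp, resistant_zps) {
  stopifnot(inherits(parental_zp, "zprofile_set"), is.list(resistant_zps))
  dir_of <- function(zp) zp$direction[zp$temporal_de]
  all_dirs <- c(list(parental = dir_of(parental_zp)),
                lapply(resistant_zps, dir_of))
  genes_all <- unique(unlist(lapply(all_dirs, names), use.names = FALSE))
  excl <- list()
  note <- function(gene, reason)
    excl[[length(excl) + 1]] <<- data.frame(gene = gene, signature = "EGFRi",
                                            reason = reason,
                                            stringsAsFactors = FALSE)
  ambiguous <- character(0)
  for (g in genes_all) {
    d <- unlist(lapply(all_dirs, function(x) x[g]), use.names = FALSE)
    d <- d[!is.na(d) & d %in% c("up", "down")]
    if (length(unique(d)) > 1) {
      ambiguous <- c(ambiguous, g)
      note(g, "direction-ambiguous")
    }
  }
  resistant_de <- unique(unlist(lapply(resistant_zps, function(zp)
    names(zp$temporal_de)[zp$temporal_de]), use.names = FALSE))
  parental_de <- names(parental_zp$temporal_de)[parental_zp$temporal_de]
  parental_de <- setdiff(parental_de, ambiguous)
  not_unique <- intersect(parental_de, setdiff(resistant_de, ambiguous))
  for (g in not_unique) note(g, "shared")
  egfri <- setdiff(parental_de, resistant_de)
  dirs <- parental_zp$direction[egfri]
  up <- egfri[dirs == "up"]; down <- egfri[dirs == "down"]
  for (g in egfri[!dirs %in% c("up", "down")])
    note(g, "direction-ambiguous")
  signature_set(
    list(EGFRi_up = data.frame(gene = up, direction = rep("up", length(up)),
                               stringsAsFactors = FALSE),
         EGFRi_down = data.frame(gene = down,
                                 direction = rep("down", length(down)),
                                 stringsAsFactors = FALSE)),
    c(EGFRi_up = "EGFRi-up", EGFRi_down = "EGFRi-down"),
    if (length(excl)) do.call(rbind, excl) else empty_exclusions())
}

#' Pairwise intersections between signature sets
#'
#' @param a a [signature_set()].
#' @param b optional second [signature_set()] (defaults to `a`).
#' @return data.frame(signature_a, signature_b, overlap, genes) for every
#'   pair.
#' @export
compare_signatures <- function(a, b = a) {
  stopifnot(inherits(a, "signature_set"), inherits(b, "signature_set"))
  rows <- list()
  for (na_ in names(a$signatures)) for (nb in names(b$signatures)) {
    ga <- a$signatures[[na_]]$gene
    gb <- b$signatures[[nb]]$gene
    ov <- intersect(ga, gb)
    rows[[length(rows) + 1]] <- data.frame(
      signature_a = na_, signature_b = nb, size_a = length(ga),
      size_b = length(gb), overlap = length(ov),
      genes = paste(sort(ov), collapse = ","), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
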