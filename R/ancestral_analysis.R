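## Ancestral-allele polarization and ancestor-type allele counting. At each
## somatic site the allele carried by a strict majority of the outgroup panel
## is taken as the ancestor-type allele; a clone carrying that allele lacks
## the derived somatic mutation. Clones with high ancestor-type counts over
## the shared (common) sites branched off the propagation chain early and are
## ranked as closest to the ancestral state.

#' Polarize somatic sites against an outgroup panel
#'
#' The ancestor-type allele at a site is the strict majority allele across
#' the panel's non-missing calls. Ties, or sites with fewer than `min_calls`
#' non-missing panel calls, are flagged `ambiguous` and excluded from
#' counting.
#'
#' @param callset A [somatic_callset()].
#' @param panel An [outgroup_panel()] covering the callset's sites (missing
#'   calls allowed).
#' @param min_calls Minimum non-missing panel calls per site (default 3).
#' @return A `polarization_map` data frame: `chrom`, `pos`, `ancestor`
#'   (`"ref"`/`"alt"`/`"ambiguous"`), `n_ref`, `n_alt`.
#' @export
polarize_sites <- function(callset, panel, min_calls = 3) {
  keys_cs <- site_key(callset$sites$chrom, callset$sites$pos)
  keys_pn <- site_key(panel$sites$chrom, panel$sites$pos)
  idx <- match(keys_cs, keys_pn)
  if (all(is.na(idx)))
    stop("outgroup panel covers none of the callset's sites")
  n_ref <- integer(length(idx))
  n_alt <- integer(length(idx))
  for (i in seq_along(idx)) {
    if (is.na(idx[i])) next
    calls <- panel$calls[idx[i], ]
    n_ref[i] <- sum(calls == "ref", na.rm = TRUE)
    n_alt[i] <- sum(calls == "alt", na.rm = TRUE)
  }
  ancestor <- ifelse(is.na(idx) | (n_ref + n_alt) < min_calls | n_ref == n_alt,
                     "ambiguous", ifelse(n_ref > n_alt, "ref", "alt"))
  out <- data.frame(chrom = callset$sites$chrom, pos = callset$sites$pos,
                    ancestor = ancestor, n_ref = n_ref, n_alt = n_alt,
                    stringsAsFactors = FALSE)
  class(out) <- c("polarization_map", "data.frame")
  out
}

#' Count ancestor-type alleles per clone
#'
#' For every clone and every polarized (non-ambiguous) site, the clone's
#' allele (alt if it carries the somatic mutation, ref otherwise) is compared
#' with the ancestor-type allele; counts are kept separately over the common
#' and the unique site sets, with group means over the common-site counts
#' when a clustering is supplied.
#'
#' @param polarization A [polarize_sites()] result.
#' @param partition A [partition_by_sharing()] result on the same callset.
#' @param groups Optional [cluster_clones()] result; every clone of the
#'   partition must be labelled.
#' @return An `ancestor_count_report` list: `per_clone` (data frame `clone`,
#'   `group`, `common_count`, `common_denom`, `unique_count`,
#'   `unique_denom`), `group_means` (data frame `group`, `mean_common`,
#'   `n_clones`, or NULL).
#' @export
ancestor_counts <- function(polarization, partition, groups = NULL) {
  clones <- partition$clones
  if (!is.null(groups)) {
    absent <- setdiff(clones, names(groups$labels))
    if (length(absent))
      stop("clone(s) absent from groups: ", paste(absent, collapse = ", "))
  }
  polarized <- polarization$ancestor %in% c("ref", "alt")
  count_set <- function(idx) {
    idx <- idx[polarized[idx]]
    denom <- length(idx)
    counts <- stats::setNames(integer(length(clones)), clones)
    for (i in idx) {
      carriers <- partition$carrier_clones[[i]]
      if (polarization$ancestor[i] == "ref") {
        # ancestor-type = ref: every non-carrier matches
        counts <- counts + 1L
        counts[carriers] <- counts[carriers] - 1L
      } else {
        counts[carriers] <- counts[carriers] + 1L
      }
    }
    list(counts = counts, denom = denom)
  }
  com <- count_set(partition$common_idx)
  uni <- count_set(partition$unique_idx)
  per_clone <- data.frame(
    clone = clones,
    group = if (is.null(groups)) NA_integer_ else
      unname(groups$labels[clones]),
    common_count = unname(com$counts),
    common_denom = com$denom,
    unique_count = unname(uni$counts),
    unique_denom = uni$denom,
    stringsAsFactors = FALSE
  )
  group_means <- NULL
  if (!is.null(groups)) {
    sp <- split(per_clone$common_count, per_clone$group)
    group_means <- data.frame(
      group = as.integer(names(sp)),
      mean_common = vapply(sp, mean, numeric(1)),
      n_clones = lengths(sp),
      row.names = NULL
    )
  }
  structure(list(per_clone = per_clone, group_means = group_means),
            class = "ancestor_count_report")
}

#' @export
print.ancestor_count_report <- function(x, ...) {
  cat("ancestor_count_report:", nrow(x$per_clone), "clones;",
      "common denom", x$per_clone$common_denom[1],
      "/ unique denom", x$per_clone$unique_denom[1], "\n")
  invisible(x)
}

#' Rank clones by closeness to the ancestral state
#'
#' Orders clones by descending ancestor-type count over common sites (the
#' shared-mutation record of the propagation chain), breaking ties by
#' descending unique-site count, then by name.
#'
#' @param report An [ancestor_counts()] result.
#' @param focus Optional clone subset to rank (e.g. trees from one site).
#' @return Character vector of clone names, closest to the ancestor first.
#' @export
rank_closest_to_ancestor <- function(report, focus = NULL) {
  df <- report$per_clone
  if (!is.null(focus)) {
    if (!length(focus)) stop("focus subset is empty")
    missing <- setdiff(focus, df$clone)
    if (length(missing))
      stop("focus clone(s) not in report: ", paste(missing, collapse = ", "))
    df <- df[df$clone %in% focus, , drop = FALSE]
  }
  df$clone[order(-df$common_count, -df$unique_count, df$clone)]
}
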