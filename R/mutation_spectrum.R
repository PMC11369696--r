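## Strand-collapsed substitution classes and the shared/unique partition.
## A substitution and its reverse complement are the same mutational event
## seen from the other strand, so the 12 ordered base changes collapse to 6
## classes; C:G>T:A and A:T>G:C are the two transitions.

SUBST_CLASSES <- c("C:G>T:A", "A:T>T:A", "A:T>G:C",
                   "C:G>A:T", "C:G>G:C", "A:T>C:G")
TRANSITION_CLASSES <- c("C:G>T:A", "A:T>G:C")

#' Classify a substitution into its strand-collapsed class
#'
#' @param ref,alt Single bases in A/C/G/T (vectorised; `ref != alt`).
#' @return Data frame with columns `class` (factor over the six classes) and
#'   `is_transition`.
#' @examples
#' classify_substitution("G", "A")  # C:G>T:A, transition
#' @export
classify_substitution <- function(ref, alt) {
  bases <- c("A", "C", "G", "T")
  if (!all(ref %in% bases) || !all(alt %in% bases))
    stop("ref and alt must be single bases in A/C/G/T")
  if (any(ref == alt)) stop("ref must differ from alt")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  # collapse to the pyrimidine-free canonical representation used in the
  # class labels: report each change by its C- or A- anchored strand
  key <- paste0(ref, alt)
  map <- c(
    CT = "C:G>T:A", GA = "C:G>T:A",
    AT = "A:T>T:A", TA = "A:T>T:A",
    AG = "A:T>G:C", TC = "A:T>G:C",
    CA = "C:G>A:T", GT = "C:G>A:T",
    CG = "C:G>G:C", GC = "C:G>G:C",
    AC = "A:T>C:G", TG = "A:T>C:G"
  )
  cls <- unname(map[key])
  data.frame(
    class = factor(cls, levels = SUBST_CLASSES),
    is_transition = cls %in% TRANSITION_CLASSES,
    stringsAsFactors = FALSE
  )
}

#' Summarise the mutation spectrum of a somatic call set
#'
#' Tallies the six strand-collapsed substitution classes, their proportions
#' and the transition/transversion ratio. With zero transversions the ratio
#' is reported as `NA` (undefined), not infinity.
#'
#' @param callset A [somatic_callset()] of biallelic SNVs.
#' @return A `spectrum_report` list: `classes` (data frame of class, count,
#'   proportion, is_transition), `n`, `transitions`, `transversions`,
#'   `titv_ratio`.
#' @export
spectrum_summary <- function(callset) {
  n <- nrow(callset$sites)
  if (n == 0) {
    tab <- data.frame(class = factor(SUBST_CLASSES, levels = SUBST_CLASSES),
                      count = 0L, proportion = NA_real_,
                      is_transition = SUBST_CLASSES %in% TRANSITION_CLASSES)
    return(structure(list(classes = tab, n = 0L, transitions = 0L,
                          transversions = 0L, titv_ratio = NA_real_),
                     class = "spectrum_report"))
  }
  cl <- classify_substitution(callset$sites$ref, callset$sites$alt)
  counts <- table(cl$class)
  ti <- sum(cl$is_transition)
  tv <- n - ti
  tab <- data.frame(
    class = factor(SUBST_CLASSES, levels = SUBST_CLASSES),
    count = as.integer(counts[SUBST_CLASSES]),
    proportion = as.numeric(counts[SUBST_CLASSES]) / n,
    is_transition = SUBST_CLASSES %in% TRANSITION_CLASSES
  )
  structure(list(classes = tab, n = n, transitions = ti, transversions = tv,
                 titv_ratio = if (tv > 0) ti / tv else NA_real_),
            class = "spectrum_report")
}

#' @export
print.spectrum_report <- function(x, ...) {
  cat("mutation spectrum over", x$n, "SNVs; Ti/Tv =",
      if (is.na(x$titv_ratio)) "undefined" else round(x$titv_ratio, 2), "\n")
  df <- x$classes
  df$percent <- round(100 * df$proportion, 1)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Partition somatic sites into clone-unique and common sets
#'
#' Carrier samples are first collapsed to clones through `replicate_map`
#' (biological replicates of one tree are one clone); a site carried by
#' exactly one clone is unique, by two or more is common. Per-clone burdens
#' count a shared site once per carrier clone.
#'
#' @param callset A [somatic_callset()].
#' @param replicate_map Optional named character vector mapping sample name ->
#'   clone name; samples not named map to themselves.
#' @param all_clones Optional character vector of the full clone roster, so
#'   clones carrying no somatic site still get a (zero) burden row.
#' @return A `sharing_partition` list: `unique_idx`, `common_idx` (row indices
#'   into `callset$sites`), `carrier_clones` (per-site clone sets), `clones`,
#'   and `burden` (data frame clone/unique/common/total).
#' @export
partition_by_sharing <- function(callset, replicate_map = NULL,
                                 all_clones = NULL) {
  n <- nrow(callset$sites)
  if (n && any(lengths(callset$carriers) == 0))
    stop("somatic site with empty carrier set")
  to_clone <- function(samples) {
    if (is.null(replicate_map)) return(unique(samples))
    mapped <- ifelse(samples %in% names(replicate_map),
                     replicate_map[samples], samples)
    unique(unname(mapped))
  }
  carrier_clones <- lapply(callset$carriers, to_clone)
  n_clones <- lengths(carrier_clones)
  clones <- sort(unique(c(unlist(carrier_clones),
                          if (!is.null(replicate_map)) unname(replicate_map),
                          all_clones)))
  uniq <- which(n_clones == 1L)
  comm <- which(n_clones >= 2L)
  burden <- data.frame(clone = clones, unique = 0L, common = 0L,
                       stringsAsFactors = FALSE)
  for (i in uniq)
    burden$unique[burden$clone %in% carrier_clones[[i]]] <-
      burden$unique[burden$clone %in% carrier_clones[[i]]] + 1L
  for (i in comm)
    burden$common[burden$clone %in% carrier_clones[[i]]] <-
      burden$common[burden$clone %in% carrier_clones[[i]]] + 1L
  burden$total <- burden$unique + burden$common
  structure(list(unique_idx = uniq, common_idx = comm,
                 carrier_clones = carrier_clones, clones = clones,
                 burden = burden, sites = callset$sites),
            class = "sharing_partition")
}

#' @export
print.sharing_partition <- function(x, ...) {
  cat("sharing_partition:", length(x$unique_idx), "unique +",
      length(x$common_idx), "common sites over", length(x$clones), "clones\n")
  invisible(x)
}
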