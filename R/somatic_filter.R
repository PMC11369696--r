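## The four-stage somatic-SNV filter cascade. On a haplotype-phased reference
## a true somatic allele yields a homozygous call on its haplotype's
## chromosome; heterozygous calls indicate cross-haplotype mis-mapping, which
## is why stage 2 demands all-homozygous sites. Stage order follows the
## published narrative: biallelic SNV -> haplotype-specific homozygosity ->
## replicate consistency -> depth/quality.

#' Filter-cascade configuration
#'
#' @param max_depth Maximum mean carrier read depth (default 50); a maximum
#'   guards against collapsed-repeat pileups.
#' @param min_quality Minimum phred-scaled site quality (default 80).
#' @param replicate_pairs List of length-2 character vectors naming biological
#'   replicate sample pairs (e.g. two sequencing runs of the same tree) whose
#'   genotypes must agree.
#' @param require_polymorphic Drop sites carried by every sample (these are
#'   reference-base errors, not somatic mutations). Default `TRUE`.
#' @param depth_scope `"carrier_mean"` (default): the depth criterion applies
#'   to the mean over carrier (hom_alt) calls; `"per_sample"`: every carrier
#'   call must individually satisfy it.
#' @return A `filter_config` list.
#' @export
filter_config <- function(max_depth = 50, min_quality = 80,
                          replicate_pairs = list(),
                          require_polymorphic = TRUE,
                          depth_scope = c("carrier_mean", "per_sample")) {
  depth_scope <- match.arg(depth_scope)
  if (max_depth <= 0) stop("max_depth must be > 0")
  if (min_quality < 0) stop("min_quality must be >= 0")
  structure(list(max_depth = max_depth, min_quality = min_quality,
                 replicate_pairs = replicate_pairs,
                 require_polymorphic = require_polymorphic,
                 depth_scope = depth_scope),
            class = "filter_config")
}

#' Stage 1: keep biallelic SNVs
#'
#' Retains sites with exactly one alt allele where both ref and alt are single
#' bases. Tri-/tetra-allelic sites are rare in true data and mostly reflect
#' mapping errors in repeats; indels are out of scope.
#'
#' @param table A [variant_table()].
#' @return The filtered [variant_table()].
#' @export
filter_biallelic <- function(table) {
  keep <- n_alt_alleles(table) == 1L &
    nchar(table$sites$ref) == 1L &
    nchar(table$sites$alt) == 1L &
    table$sites$ref %in% c("A", "C", "G", "T") &
    table$sites$alt %in% c("A", "C", "G", "T")
  vt_subset(table, keep)
}

#' Stage 2: keep haplotype-specific (all-homozygous) sites
#'
#' Keeps sites where every non-missing call is hom_ref or hom_alt. Sites with
#' any heterozygous call are removed as cross-haplotype mis-mapping; sites
#' with no non-missing call carry no evidence and are removed too.
#'
#' @param table A biallelic [variant_table()].
#' @return The filtered [variant_table()].
#' @export
filter_haplotype_specific <- function(table) {
  any_het <- rowSums(table$geno == "het") > 0
  any_call <- rowSums(table$geno != "missing") > 0
  vt_subset(table, !any_het & any_call)
}

#' Stage 3: keep replicate-consistent sites
#'
#' Within every replicate pair the two genotype codes must be identical;
#' a missing call never counts as consistent (conservative).
#'
#' @param table A [variant_table()].
#' @param pairs List of length-2 character vectors of sample names.
#' @return The filtered [variant_table()].
#' @export
filter_replicate_consistent <- function(table, pairs) {
  if (!length(pairs)) return(table)
  keep <- rep(TRUE, n_sites(table))
  for (p in pairs) {
    missing <- setdiff(p, table$samples)
    if (length(missing))
      stop("replicate pair names unknown sample(s): ",
           paste(missing, collapse = ", "))
    a <- table$geno[, p[1]]
    b <- table$geno[, p[2]]
    keep <- keep & (a == b) & (a != "missing")
  }
  vt_subset(table, keep)
}

#' Stage 4: depth and quality thresholds
#'
#' Retains sites with site quality >= `min_quality` and carrier read depth
#' <= `max_depth` (mean over hom_alt calls by default; see
#' [filter_config()]'s `depth_scope`). Sites without any hom_alt call are
#' assessed on the mean over all non-missing calls.
#'
#' @param table A [variant_table()].
#' @param config A [filter_config()].
#' @return The filtered [variant_table()].
#' @export
filter_depth_quality <- function(table, config = filter_config()) {
  if (n_sites(table) == 0) return(table)
  carrier <- table$geno == "hom_alt"
  called <- table$geno != "missing"
  depth_ok <- logical(n_sites(table))
  for (i in seq_len(n_sites(table))) {
    sel <- if (any(carrier[i, ])) carrier[i, ] else called[i, ]
    if (!any(sel)) { depth_ok[i] <- FALSE; next }
    d <- table$depth[i, sel]
    depth_ok[i] <- if (config$depth_scope == "carrier_mean")
      mean(d) <= config$max_depth else all(d <= config$max_depth)
  }
  keep <- depth_ok & table$sites$qual >= config$min_quality
  vt_subset(table, keep)
}

#' Run the full somatic filter cascade
#'
#' Applies the four stages in order, then builds the somatic call set: the
#' carriers of a site are the samples with a hom_alt call. Sites with no
#' carrier (all hom_ref) are not somatic; sites carried by all samples are
#' reference-base errors and dropped when `require_polymorphic` is set.
#'
#' @param table A [variant_table()] of raw variant candidates.
#' @param config A [filter_config()].
#' @return A list with `callset` (a `somatic_callset`) and `report` (a
#'   `cascade_report` data frame of per-stage surviving site counts, with the
#'   removed site keys for each stage in `attr(, "removed")`).
#' @export
run_cascade <- function(table, config = filter_config()) {
  stages <- list(
    biallelic = function(t) filter_biallelic(t),
    haplotype_specific = function(t) filter_haplotype_specific(t),
    replicate_consistent = function(t)
      filter_replicate_consistent(t, config$replicate_pairs),
    depth_quality = function(t) filter_depth_quality(t, config)
  )
  counts <- c(raw = n_sites(table))
  removed <- list()
  cur <- table
  for (nm in names(stages)) {
    before <- vt_site_keys(cur)
    cur <- stages[[nm]](cur)
    counts[nm] <- n_sites(cur)
    removed[[nm]] <- setdiff(before, vt_site_keys(cur))
  }
  # carrier construction + polymorphism screen
  carrier <- cur$geno == "hom_alt"
  n_carr <- rowSums(carrier)
  keep <- n_carr >= 1L
  if (config$require_polymorphic) keep <- keep & n_carr < length(cur$samples)
  removed$somatic <- vt_site_keys(cur)[!keep]
  final <- vt_subset(cur, keep)
  counts["somatic"] <- n_sites(final)
  carrier <- final$geno == "hom_alt"
  carriers <- lapply(seq_len(n_sites(final)), function(i)
    final$samples[carrier[i, ]])
  mean_depth <- vapply(seq_len(n_sites(final)), function(i)
    mean(final$depth[i, carrier[i, ]]), numeric(1))
  callset <- somatic_callset(
    sites = cbind(final$sites,
                  mean_carrier_depth = if (n_sites(final)) mean_depth else numeric(0)),
    carriers = carriers
  )
  report <- data.frame(stage = names(counts), n_sites = unname(counts),
                       stringsAsFactors = FALSE)
  attr(report, "removed") <- removed
  class(report) <- c("cascade_report", "data.frame")
  list(callset = callset, report = report)
}

#' Construct a somatic call set
#'
#' @param sites Data frame with at least `chrom`, `pos`, `ref`, `alt`, `qual`
#'   (and optionally `mean_carrier_depth`).
#' @param carriers List (one element per site) of carrier sample names.
#' @return A `somatic_callset`.
#' @export
somatic_callset <- function(sites, carriers) {
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  if (length(carriers) != nrow(sites))
    stop("carriers must have one element per site")
  if (nrow(sites) && any(lengths(carriers) == 0))
    stop("every somatic site must have a non-empty carrier set")
  if (!"mean_carrier_depth" %in% names(sites))
    sites$mean_carrier_depth <- rep(NA_real_, nrow(sites))
  structure(list(sites = sites, carriers = carriers),
            class = "somatic_callset")
}

#' @export
print.somatic_callset <- function(x, ...) {
  cat("somatic_callset:", nrow(x$sites), "sites;",
      length(unique(unlist(x$carriers))), "carrier samples\n")
  invisible(x)
}
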