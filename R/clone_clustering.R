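## Clone grouping from shared somatic mutations: a binary clone x common-site
## incidence matrix, cluster-number selection from the cumulative explained
## variance (CEV) of its principal-component spectrum, and average-linkage
## agglomeration on Jaccard distances. A separate identity-by-state
## neighbour-joining tree provides the clone-identity check against an
## outgroup.

#' Build the clone x common-site incidence matrix
#'
#' Rows are clones (replicates already collapsed by the partition), columns
#' the common (carrier count >= 2) somatic sites; entries are 1 for carriers.
#' Clones carrying no common site keep an all-zero row.
#'
#' @param partition A [partition_by_sharing()] result with at least one
#'   common site.
#' @return Binary integer matrix with clone row names and `chrom:pos` column
#'   names.
#' @export
build_matrix <- function(partition) {
  if (!length(partition$common_idx))
    stop("no common sites: clustering needs sites shared by >= 2 clones; ",
         "with unique-only callsets there is no sharing signal to cluster")
  clones <- partition$clones
  idx <- partition$common_idx
  m <- matrix(0L, length(clones), length(idx),
              dimnames = list(clones,
                              site_key(partition$sites$chrom[idx],
                                       partition$sites$pos[idx])))
  for (j in seq_along(idx)) {
    m[partition$carrier_clones[[idx[j]]], j] <- 1L
  }
  m
}

#' Select the cluster number from cumulative explained variance
#'
#' Computes the principal-component spectrum of the (uncentred) binary
#' incidence matrix; the cumulative explained variance CEV_j is the fraction
#' of total variance captured by the top j components, and the selected
#' cluster number is the smallest j with CEV_j >= `threshold`. On a noise-free
#' clonal dataset the number of non-zero components equals the number of
#' distinct clonal signatures, so the selection recovers the lineage count.
#'
#' @param matrix A [build_matrix()] result (>= 2 clones).
#' @param threshold CEV threshold in (0, 1]; default 0.95.
#' @return A list: `k`, `cev` (curve over components), `eigenvalues`.
#' @export
select_cluster_number <- function(matrix, threshold = 0.95) {
  if (threshold <= 0 || threshold > 1)
    stop("threshold must be in (0, 1]")
  if (nrow(matrix) < 2) stop("need >= 2 clones")
  d <- svd(matrix)$d
  ev <- d^2
  tol <- max(ev) * 1e-12
  ev <- ev[ev > tol]
  if (!length(ev)) stop("incidence matrix has no variance")
  cev <- cumsum(ev) / sum(ev)
  k <- which(cev >= threshold - 1e-12)[1]
  list(k = as.integer(k), cev = cev, eigenvalues = ev)
}

# Jaccard distance between binary rows; two empty rows are identical
jaccard_dist <- function(m) {
  d <- suppressWarnings(vegan::vegdist(m, method = "jaccard", binary = TRUE))
  d[is.na(d)] <- 0
  d
}

#' Cluster clones into k groups by shared mutations
#'
#' Average-linkage agglomeration on Jaccard distances between the binary
#' carrier profiles, cut into `k` groups. Group labels are deterministic:
#' groups are numbered by decreasing size, ties broken by the
#' lexicographically smallest member name.
#'
#' @param matrix A [build_matrix()] result.
#' @param k Number of groups (1..n clones).
#' @return A `cluster_result` list: `labels` (named integer vector), `k`,
#'   `hclust` (the dendrogram), `distance`, `linkage`.
#' @export
cluster_clones <- function(matrix, k) {
  n <- nrow(matrix)
  if (k < 1 || k > n) stop("k must be between 1 and the number of clones")
  d <- jaccard_dist(matrix)
  hc <- stats::hclust(d, method = "average")
  raw <- stats::cutree(hc, k = k)
  # deterministic relabelling: size desc, then smallest member name
  info <- lapply(split(names(raw), raw), sort)
  ord <- order(-lengths(info), vapply(info, `[`, character(1), 1))
  labels <- stats::setNames(integer(n), names(raw))
  for (new in seq_along(ord)) labels[info[[ord[new]]]] <- new
  structure(list(labels = labels[rownames(matrix)], k = as.integer(k),
                 hclust = hc, distance = "jaccard", linkage = "average"),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("cluster_result:", length(x$labels), "clones in", x$k, "groups\n")
  print(table(x$labels))
  invisible(x)
}

#' Identity-by-state neighbour-joining tree
#'
#' Pairwise distances are mean allele-sharing dissimilarities over sites
#' where both samples are called (hom_ref/het/hom_alt scored 0/1/2, distance
#' |g1-g2|/2 averaged over sites); the tree is built by neighbour joining and
#' rooted on the outgroup. Clones of one cultivar sit at near-zero distances
#' and form a clade relative to a divergent outgroup.
#'
#' @param table A [variant_table()] with >= 3 samples.
#' @param outgroup Sample name to root on.
#' @return A rooted `phylo` tree (ape).
#' @export
identity_tree <- function(table, outgroup) {
  if (length(table$samples) < 3) stop("need >= 3 samples")
  if (!outgroup %in% table$samples)
    stop("outgroup '", outgroup, "' not among samples")
  score <- matrix(c(hom_ref = 0, het = 1, hom_alt = 2,
                    missing = NA)[table$geno],
                  nrow = n_sites(table),
                  dimnames = list(NULL, table$samples))
  if (any(colSums(!is.na(score)) == 0))
    stop("sample with all-missing genotypes")
  n <- ncol(score)
  d <- matrix(0, n, n, dimnames = list(table$samples, table$samples))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- !is.na(score[, i]) & !is.na(score[, j])
    if (!any(ok)) stop("samples ", table$samples[i], " and ",
                       table$samples[j], " share no called site")
    d[i, j] <- d[j, i] <- mean(abs(score[ok, i] - score[ok, j])) / 2
  }
  tree <- ape::nj(stats::as.dist(d))
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}
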