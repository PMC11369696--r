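## Central relation of the pipeline: per-site, per-sample genotype calls with
## read depth and site quality. Genotype codes are the four-level summary of a
## diploid GT field; on a phased reference the informative somatic signal is a
## hom_alt call on one haplotype's chromosome.

GENO_CODES <- c("hom_ref", "het", "hom_alt", "missing")

#' Construct a variant table
#'
#' @param sites Data frame with columns `chrom`, `pos` (1-based), `ref`, `alt`
#'   (comma-separated string for multi-allelic records) and `qual`
#'   (phred-scaled site quality).
#' @param geno Character matrix (sites x samples) of genotype codes among
#'   `"hom_ref"`, `"het"`, `"hom_alt"`, `"missing"`; column names are sample
#'   names.
#' @param depth Integer matrix of per-call read depths, same shape as `geno`.
#' @return An object of class `variant_table`.
#' @export
variant_table <- function(sites, geno, depth) {
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  req <- c("chrom", "pos", "ref", "alt", "qual")
  if (!all(req %in% names(sites)))
    stop("sites must have columns: ", paste(req, collapse = ", "))
  geno <- as.matrix(geno)
  depth <- as.matrix(depth)
  if (nrow(geno) != nrow(sites) || !identical(dim(geno), dim(depth)))
    stop("geno/depth dimensions inconsistent with sites")
  if (is.null(colnames(geno))) stop("geno must carry sample names as colnames")
  bad <- setdiff(unique(as.vector(geno)), GENO_CODES)
  if (length(bad)) stop("unknown genotype codes: ", paste(bad, collapse = ", "))
  if (any(depth < 0)) stop("depths must be >= 0")
  if (any(sites$qual < 0, na.rm = TRUE)) stop("site quality must be >= 0")
  alts <- strsplit(sites$alt, ",", fixed = TRUE)
  for (i in seq_len(nrow(sites))) {
    if (any(alts[[i]] == sites$ref[i]))
      stop("ref equals an alt allele at row ", i)
  }
  storage.mode(depth) <- "integer"
  colnames(depth) <- colnames(geno)
  structure(
    list(sites = sites, geno = geno, depth = depth, samples = colnames(geno)),
    class = "variant_table"
  )
}

#' @export
print.variant_table <- function(x, ...) {
  cat("variant_table:", nrow(x$sites), "sites x", length(x$samples),
      "samples\n")
  invisible(x)
}

#' Number of sites in a variant table
#' @param table A [variant_table()].
#' @return Integer site count.
#' @export
n_sites <- function(table) nrow(table$sites)

# row-subset a variant table, keeping all parallel structures aligned
vt_subset <- function(table, keep) {
  variant_table(table$sites[keep, , drop = FALSE],
                table$geno[keep, , drop = FALSE],
                table$depth[keep, , drop = FALSE])
}

# canonical site key used to join tables, truth files and panels
site_key <- function(chrom, pos) {
  if (!length(chrom)) return(character(0))
  paste0(chrom, ":", pos)
}

vt_site_keys <- function(table) site_key(table$sites$chrom, table$sites$pos)

# number of alt alleles per site
n_alt_alleles <- function(table) {
  lengths(strsplit(table$sites$alt, ",", fixed = TRUE))
}
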