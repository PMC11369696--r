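## VCF reading sits on vcfR; only the writer for the supported dialect
## (GT:DP, site QUAL) is in-house so that simulator output stays plain text.

# GT string (any of "0/1", "1|1", "./.") -> genotype code
gt_to_code <- function(gt) {
  code_one <- function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return("missing")
    alleles <- strsplit(g, "[/|]")[[1]]
    if (any(alleles == ".") || !length(alleles)) return("missing")
    if (all(alleles == "0")) return("hom_ref")
    if (length(unique(alleles)) == 1L) return("hom_alt")
    "het"
  }
  vapply(gt, code_one, character(1), USE.NAMES = FALSE)
}

#' Read a multi-sample VCF into a variant table
#'
#' Consumes a VCFv4.2 file with GT (required) and DP (optional) FORMAT fields
#' and a site QUAL column, as produced by the usual bcftools
#' mpileup/call/merge route. Multi-allelic records are read intact (all alt
#' alleles kept as a comma-separated string) so the biallelic filter stage
#' sees and counts them; genotype codes are derived from GT regardless of the
#' phasing separator.
#'
#' @param path Path to a VCF file (plain or bgzipped).
#' @param sample_subset Optional character vector of sample names to keep.
#' @return A [variant_table()].
#' @export
read_vcf <- function(path, sample_subset = NULL) {
  v <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("failed to parse VCF '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  samples <- colnames(v@gt)[-1]
  if (!is.null(sample_subset)) {
    missing <- setdiff(sample_subset, samples)
    if (length(missing))
      stop("sample(s) not in VCF: ", paste(missing, collapse = ", "),
           "; available: ", paste(samples, collapse = ", "))
    samples <- sample_subset
  }
  n <- nrow(fix)
  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  if (is.null(gt)) stop("VCF has no GT FORMAT field")
  gt <- gt[, samples, drop = FALSE]
  if (is.null(dp)) {
    dp <- matrix(0L, n, length(samples))
  } else {
    dp <- dp[, samples, drop = FALSE]
    dp[is.na(dp)] <- 0
  }
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  qual[is.na(qual)] <- 0
  geno <- matrix(gt_to_code(as.vector(gt)), nrow = n,
                 dimnames = list(NULL, samples))
  sites <- data.frame(
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"],
    alt = fix[, "ALT"],
    qual = qual,
    stringsAsFactors = FALSE
  )
  variant_table(sites, geno, matrix(as.integer(dp), n,
                                    dimnames = list(NULL, samples)))
}

#' Write a variant table as a minimal VCFv4.2 file
#'
#' Emits the dialect [read_vcf()] consumes (GT:DP, site QUAL, 1-based
#' positions); `read_vcf(write_vcf(x))` round-trips within that dialect.
#' Genotypes are written unphased: `hom_ref` as 0/0, `het` as 0/1, `hom_alt`
#' as 1/1 and `missing` as ./. (the codes do not record which alt allele a
#' multi-allelic hom_alt call carried; such records exist only to be counted
#' and rejected by the biallelic stage).
#'
#' @param table A [variant_table()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", table$samples), collapse = "\t")
  ), con)
  if (n_sites(table) == 0) return(invisible(path))
  gt_map <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1", missing = "./.")
  gt <- matrix(gt_map[table$geno], nrow = n_sites(table))
  cells <- matrix(paste0(gt, ":", table$depth), nrow = n_sites(table))
  lines <- paste(
    table$sites$chrom, table$sites$pos, ".", table$sites$ref,
    table$sites$alt, format(table$sites$qual, trim = TRUE, scientific = FALSE),
    ".", ".", "GT:DP",
    apply(cells, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(lines, con)
  invisible(path)
}
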