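#' Genome index for a haplotype-phased assembly
#'
#' Describes the chromosome set of a haplotype-resolved reference in which the
#' two parental haplotypes are carried as separate chromosome sequences (e.g.
#' the phased cherry assembly's SPA1-SPA8 and SPE1-SPE8). On such a reference a
#' heterozygous somatic allele appears as a homozygous call on one haplotype's
#' chromosome, which is what the downstream homozygosity filter exploits.
#'
#' @param chrom_names Character vector of unique chromosome identifiers.
#' @param chrom_lengths Integer vector of chromosome lengths in bp (> 0).
#' @param haplotype Character vector tagging each chromosome with its
#'   haplotype set (e.g. `"SPA"` or `"SPE"`).
#' @return An object of class `genome_index`: a data frame with columns
#'   `chrom`, `length`, `haplotype`.
#' @examples
#' gi <- genome_index(c("SPA1", "SPE1"), c(1e6, 1e6), c("SPA", "SPE"))
#' @export
genome_index <- function(chrom_names, chrom_lengths, haplotype) {
  if (anyDuplicated(chrom_names)) stop("chromosome names must be unique")
  if (length(chrom_lengths) != length(chrom_names) ||
      length(haplotype) != length(chrom_names))
    stop("chrom_names, chrom_lengths and haplotype must have equal length")
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be > 0")
  gi <- data.frame(
    chrom = as.character(chrom_names),
    length = as.numeric(chrom_lengths),
    haplotype = as.character(haplotype),
    stringsAsFactors = FALSE
  )
  class(gi) <- c("genome_index", "data.frame")
  gi
}

#' Default two-haplotype simulation genome
#'
#' A compact stand-in for a phased assembly: `n_per_hap` chromosomes per
#' haplotype set, named SPA1..SPAn and SPE1..SPEn.
#'
#' @param n_per_hap Chromosomes per haplotype set (default 8, mirroring the
#'   eight-chromosome cherry karyotype).
#' @param chrom_length Length of each chromosome in bp.
#' @return A [genome_index()].
#' @export
sim_genome <- function(n_per_hap = 8, chrom_length = 1e6) {
  names <- c(paste0("SPA", seq_len(n_per_hap)), paste0("SPE", seq_len(n_per_hap)))
  genome_index(names, rep(chrom_length, 2 * n_per_hap),
               rep(c("SPA", "SPE"), each = n_per_hap))
}

# total genome size in bp
genome_size <- function(genome) sum(genome$length)
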