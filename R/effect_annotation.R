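## Simplified coding-effect classifier: region (gene body vs intergenic),
## codon-level consequence inside CDS, splice-site flags in introns, and
## gene-deletion calls for CNV segments. "Gene body" means the full
## transcription unit, introns and UTRs included, so genic + intergenic
## always partition a call set.

EFFECT_IMPACT <- c(
  stop_gained = "high", splice_acceptor = "high", splice_donor = "high",
  gene_deletion = "high", missense = "moderate", synonymous = "low",
  intron = "modifier", non_coding_exon = "modifier", none = "modifier"
)

#' Impact level of an effect class
#'
#' Pure lookup: stop_gained / splice_acceptor / splice_donor / gene_deletion
#' are high impact, missense moderate, synonymous low, everything else
#' modifier.
#'
#' @param effect Character vector of effect classes.
#' @return Character vector of impact levels.
#' @export
effect_impact <- function(effect) {
  bad <- setdiff(effect, names(EFFECT_IMPACT))
  if (length(bad)) stop("unknown effect class: ", paste(bad, collapse = ", "))
  unname(EFFECT_IMPACT[effect])
}

#' Assign variants to gene bodies or intergenic space
#'
#' A site is genic iff its position lies within any gene's transcription unit
#' (start..end inclusive, either strand).
#'
#' @param sites Data frame with `chrom` and `pos` (1-based).
#' @param genes A [gene_model_set()].
#' @return Character vector `"genic"`/`"intergenic"` per site.
#' @export
annotate_region <- function(sites, genes) {
  if (!nrow(sites)) return(character(0))
  if (!nrow(genes$genes)) return(rep("intergenic", nrow(sites)))
  q <- GenomicRanges::GRanges(sites$chrom,
                              IRanges::IRanges(sites$pos, sites$pos))
  hits <- GenomicRanges::countOverlaps(q, gene_ranges(genes))
  ifelse(hits > 0, "genic", "intergenic")
}

# genomic position -> CDS-relative coordinate (1-based, transcript 5'->3');
# NA when the position is not in the CDS. cds rows are in transcript order.
cds_offset <- function(pos, cds, strand) {
  off <- 0L
  for (i in seq_len(nrow(cds))) {
    s <- cds$start[i]; e <- cds$end[i]
    w <- e - s + 1L
    if (pos >= s && pos <= e) {
      within <- if (strand == "-") e - pos else pos - s
      return(off + within + 1L)
    }
    off <- off + w
  }
  NA_integer_
}

# concatenated CDS sequence in transcript orientation: extract pieces in
# ascending genomic order, then reverse-complement the whole for minus strand
cds_sequence <- function(cds, strand, chrom_seq) {
  o <- order(cds$start)
  pieces <- vapply(o, function(i)
    substr(chrom_seq, cds$start[i], cds$end[i]), character(1))
  s <- paste(pieces, collapse = "")
  if (strand == "-")
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  s
}

revcomp_base <- function(b) c(A = "T", C = "G", G = "C", T = "A")[b]

#' Classify the predicted effect of an SNV
#'
#' Within CDS the affected codon is translated with and without the alt base
#' (strand-aware, standard genetic code): a gained stop is `stop_gained`, an
#' amino-acid change `missense`, a silent change `synonymous`. In introns the
#' two bases at the 5' end (transcript orientation) are `splice_donor`, the
#' two at the 3' end `splice_acceptor`, otherwise `intron`. Exonic non-CDS
#' positions are `non_coding_exon`; positions outside every gene are
#' intergenic with effect `none`.
#'
#' @param chrom,pos,ref,alt The variant (single site; `pos` 1-based).
#' @param genes A [gene_model_set()].
#' @param seqs Named character vector (or list) of chromosome sequences;
#'   needed only for CDS codon translation.
#' @return A one-row data frame: `region`, `effect`, `impact`, `gene_id`.
#' @export
classify_effect <- function(chrom, pos, ref, alt, genes, seqs = NULL) {
  out <- function(region, effect, gene_id = "") {
    data.frame(region = region, effect = effect,
               impact = effect_impact(effect), gene_id = gene_id,
               stringsAsFactors = FALSE)
  }
  g <- genes$genes
  hit <- which(g$chrom == chrom & g$start <= pos & g$end >= pos)
  if (!length(hit)) return(out("intergenic", "none"))
  gene <- g[hit[1], ]
  gid <- gene$gene_id
  strand <- gene$strand
  cds <- genes$cds[genes$cds$gene_id == gid, , drop = FALSE]
  exons <- genes$exons[genes$exons$gene_id == gid, , drop = FALSE]
  in_cds <- nrow(cds) && any(cds$start <= pos & cds$end >= pos)
  if (in_cds) {
    if (is.null(seqs) || !chrom %in% names(seqs))
      stop("CDS classification requires the sequence of chromosome ", chrom)
    chrom_seq <- as.character(seqs[[chrom]])
    cds_len <- sum(cds$end - cds$start + 1L)
    if (cds_len %% 3L != 0L)
      stop("CDS length of gene ", gid, " is not divisible by 3")
    cseq <- cds_sequence(cds, strand, chrom_seq)
    k <- cds_offset(pos, cds, strand)
    tx_alt <- if (strand == "-") revcomp_base(alt) else alt
    mut <- cseq
    substr(mut, k, k) <- unname(tx_alt)
    codon_i <- (k - 1L) %/% 3L
    from <- substr(cseq, codon_i * 3L + 1L, codon_i * 3L + 3L)
    to <- substr(mut, codon_i * 3L + 1L, codon_i * 3L + 3L)
    aa_from <- unname(Biostrings::GENETIC_CODE[from])
    aa_to <- unname(Biostrings::GENETIC_CODE[to])
    eff <- if (aa_to == "*" && aa_from != "*") "stop_gained"
      else if (aa_to != aa_from) "missense" else "synonymous"
    return(out("genic", eff, gid))
  }
  in_exon <- nrow(exons) && any(exons$start <= pos & exons$end >= pos)
  if (in_exon) return(out("genic", "non_coding_exon", gid))
  # intronic: locate the surrounding intron from the exon table
  if (nrow(exons) > 1) {
    o <- exons[order(exons$start), , drop = FALSE]
    for (i in seq_len(nrow(o) - 1L)) {
      i_start <- o$end[i] + 1L
      i_end <- o$start[i + 1L] - 1L
      if (pos >= i_start && pos <= i_end) {
        # transcript-5' end of the intron is the donor side
        donor <- if (strand == "-") pos >= i_end - 1L else pos <= i_start + 1L
        acceptor <- if (strand == "-") pos <= i_start + 1L else pos >= i_end - 1L
        eff <- if (donor) "splice_donor" else if (acceptor) "splice_acceptor"
          else "intron"
        return(out("genic", eff, gid))
      }
    }
  }
  out("genic", "intron", gid)
}

#' Genes overlapped by a CNV deletion segment
#'
#' Any gene whose transcription unit overlaps the segment by at least 1 bp is
#' reported as a high-impact `gene_deletion`.
#'
#' @param segment One-row data frame (or list) with `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @param genes A [gene_model_set()].
#' @return Data frame of `gene_id`, `region`, `effect`, `impact` (possibly
#'   zero rows).
#' @export
genes_in_deletion <- function(segment, genes) {
  g <- genes$genes
  hit <- g$chrom == segment$chrom & g$start <= segment$end &
    g$end >= segment$start
  ids <- g$gene_id[hit]
  data.frame(gene_id = ids,
             region = rep("genic", length(ids)),
             effect = rep("gene_deletion", length(ids)),
             impact = rep("high", length(ids)),
             stringsAsFactors = FALSE)
}
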