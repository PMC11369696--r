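# Fixtures are built in code: small VCF/GFF literals, toy variant tables,
# and random toy genes with sequence for the effect-classifier oracle.

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# three-record, two-sample VCF literal
toy_vcf_path <- function() {
  write_lines_tmp(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", "S2", sep = "\t"),
    paste("SPA1", "100", ".", "A", "T", "90", ".", ".", "GT:DP", "0/0:30",
          "1/1:28", sep = "\t"),
    paste("SPA1", "200", ".", "C", "G", "85", ".", ".", "GT:DP", "./.:12",
          "0|1:31", sep = "\t"),
    paste("SPE2", "150", ".", "G", "T,A", "95", ".", ".", "GT:DP", "1/1:25",
          "1/2:33", sep = "\t")
  ), ".vcf")
}

# two-exon plus-strand gene (100-200, 300-400) and a minus-strand gene
toy_gff_path <- function() {
  write_lines_tmp(c(
    "##gff-version 3",
    paste("SPA1", "test", "gene", "100", "400", ".", "+", ".", "ID=g1",
          sep = "\t"),
    paste("SPA1", "test", "mRNA", "100", "400", ".", "+", ".",
          "ID=m1;Parent=g1", sep = "\t"),
    paste("SPA1", "test", "exon", "100", "200", ".", "+", ".", "Parent=m1",
          sep = "\t"),
    paste("SPA1", "test", "exon", "300", "400", ".", "+", ".", "Parent=m1",
          sep = "\t"),
    paste("SPA1", "test", "CDS", "120", "200", ".", "+", "0", "Parent=m1",
          sep = "\t"),
    paste("SPA1", "test", "CDS", "300", "380", ".", "+", "0", "Parent=m1",
          sep = "\t"),
    paste("SPE1", "test", "gene", "500", "900", ".", "-", ".", "ID=g2",
          sep = "\t"),
    paste("SPE1", "test", "mRNA", "500", "900", ".", "-", ".",
          "ID=m2;Parent=g2", sep = "\t"),
    paste("SPE1", "test", "exon", "500", "600", ".", "-", ".", "Parent=m2",
          sep = "\t"),
    paste("SPE1", "test", "exon", "700", "900", ".", "-", ".", "Parent=m2",
          sep = "\t"),
    paste("SPE1", "test", "CDS", "500", "600", ".", "-", "0", "Parent=m2",
          sep = "\t"),
    paste("SPE1", "test", "CDS", "700", "900", ".", "-", "0", "Parent=m2",
          sep = "\t")
  ), ".gff3")
}

# quick variant table from a genotype-code matrix
vt_from_codes <- function(geno, qual = NULL, depth = NULL,
                          ref = NULL, alt = NULL, chrom = "SPA1") {
  geno <- as.matrix(geno)
  n <- nrow(geno)
  if (is.null(qual)) qual <- rep(100, n)
  if (is.null(depth)) depth <- matrix(30L, n, ncol(geno))
  if (is.null(ref)) ref <- rep("A", n)
  if (is.null(alt)) alt <- rep("T", n)
  variant_table(
    data.frame(chrom = rep(chrom, n), pos = seq_len(n) * 10L,
               ref = ref, alt = alt, qual = qual, stringsAsFactors = FALSE),
    geno, depth
  )
}

# somatic callset realizing given counts of the six substitution classes
callset_from_class_counts <- function(counts) {
  reps <- list(c("C", "T"), c("A", "T"), c("A", "G"),
               c("C", "A"), c("C", "G"), c("A", "C"))
  ref <- character(0); alt <- character(0)
  for (i in seq_along(counts)) {
    ref <- c(ref, rep(reps[[i]][1], counts[i]))
    alt <- c(alt, rep(reps[[i]][2], counts[i]))
  }
  n <- sum(counts)
  somatic_callset(
    data.frame(chrom = "SPA1", pos = seq_len(n), ref = ref, alt = alt,
               qual = 100, stringsAsFactors = FALSE),
    carriers = replicate(n, "S1", simplify = FALSE)
  )
}

# random toy gene with chromosome sequence; CDS split over 1-3 exons with
# total length divisible by 3; returns gene_model_set + seqs + cds bounds
random_toy_gene <- function(strand = sample(c("+", "-"), 1)) {
  chrom_len <- 1200L
  seq <- paste(sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE),
               collapse = "")
  n_ex <- sample(1:3, 1)
  lens <- sample(1:6, n_ex, replace = TRUE) * 3L
  while (sum(lens) %% 3L != 0L) lens <- sample(1:6, n_ex, replace = TRUE) * 3L
  starts <- integer(n_ex)
  cur <- 100L
  for (i in seq_len(n_ex)) {
    starts[i] <- cur
    cur <- cur + lens[i] + sample(20:60, 1)  # intron gap
  }
  ends <- starts + lens - 1L
  gene <- data.frame(gene_id = "gX", chrom = "chr1", strand = strand,
                     start = min(starts), end = max(ends),
                     stringsAsFactors = FALSE)
  ord <- if (strand == "-") rev(seq_len(n_ex)) else seq_len(n_ex)
  cds <- data.frame(gene_id = "gX", start = starts[ord], end = ends[ord],
                    phase = 0L, stringsAsFactors = FALSE)
  exons <- cds[, c("gene_id", "start", "end")]
  list(genes = gene_model_set(gene, exons, cds),
       seqs = c(chr1 = seq),
       cds_positions = unlist(lapply(seq_len(n_ex), function(i)
         starts[i]:ends[i])))
}

# brute-force effect oracle: translate the full CDS with and without the
# mutation and compare proteins
oracle_effect <- function(gene, pos, alt) {
  cds <- gene$genes$cds
  g <- gene$genes$genes
  seq <- gene$seqs[[g$chrom]]
  extract <- function(s) {
    pieces <- vapply(seq_len(nrow(cds)), function(i)
      substr(s, cds$start[i], cds$end[i]), character(1))
    out <- paste(pieces[order(cds$start)], collapse = "")
    if (g$strand == "-")
      out <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(out)))
    out
  }
  mut_seq <- seq
  substr(mut_seq, pos, pos) <- alt
  p0 <- as.character(Biostrings::translate(Biostrings::DNAString(extract(seq)),
                                           no.init.codon = TRUE))
  p1 <- as.character(Biostrings::translate(
    Biostrings::DNAString(extract(mut_seq)), no.init.codon = TRUE))
  if (identical(p0, p1)) return("synonymous")
  diff <- which(strsplit(p0, "")[[1]] != strsplit(p1, "")[[1]])[1]
  aa_new <- substr(p1, diff, diff)
  aa_old <- substr(p0, diff, diff)
  if (aa_new == "*" && aa_old != "*") "stop_gained" else "missense"
}

sim_truth_keys <- function(sim) {
  paste0(sim$truth$site_branch$chrom, ":", sim$truth$site_branch$pos)
}

callset_keys <- function(callset) {
  paste0(callset$sites$chrom, ":", callset$sites$pos)
}
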