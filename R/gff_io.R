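## Gene models are read from GFF3 via rtracklayer and held as plain data
## frames: one row per gene plus exon/CDS interval tables keyed by gene id.
## Only the first mRNA per gene is modelled.

#' Read gene models from a GFF3 file
#'
#' Expects gene/mRNA/exon/CDS features with 1-based inclusive coordinates.
#' Exons and CDS are attached to their gene through the mRNA Parent chain;
#' for minus-strand genes the CDS list is ordered 5'->3' in transcript
#' orientation (descending genomic start).
#'
#' @param path Path to a GFF3 file. An empty file (or one with only header
#'   lines) yields an empty model set.
#' @return An object of class `gene_model_set`: a list with data frames
#'   `genes` (gene_id, chrom, strand, start, end), `exons` and `cds`
#'   (gene_id, start, end, phase), the latter two in transcript order.
#' @export
read_gff <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (!length(body)) return(empty_gene_model_set())
  gr <- rtracklayer::import(path, format = "gff3")
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    id = if (!is.null(gr$ID)) as.character(gr$ID) else NA_character_,
    phase = if (!is.null(gr$phase)) as.integer(as.character(gr$phase)) else NA_integer_,
    stringsAsFactors = FALSE
  )
  parent <- gr$Parent
  df$parent <- if (is.null(parent)) NA_character_ else
    vapply(as.list(parent), function(p) if (length(p)) p[[1]] else NA_character_,
           character(1))
  gene_rows <- df[df$type == "gene", , drop = FALSE]
  mrna_rows <- df[df$type == "mRNA", , drop = FALSE]
  mrna_to_gene <- stats::setNames(mrna_rows$parent, mrna_rows$id)
  resolve_gene <- function(parent_id, what) {
    if (is.na(parent_id)) stop(what, " feature without Parent")
    if (parent_id %in% gene_rows$id) return(parent_id)
    g <- mrna_to_gene[parent_id]
    if (is.na(g) || !(g %in% gene_rows$id))
      stop(what, " with Parent '", parent_id, "' has no parent gene")
    unname(g)
  }
  collect <- function(type) {
    rows <- df[df$type == type, , drop = FALSE]
    if (!nrow(rows))
      return(data.frame(gene_id = character(), start = integer(),
                        end = integer(), phase = integer(),
                        stringsAsFactors = FALSE))
    gene_id <- vapply(rows$parent, resolve_gene, character(1), what = type)
    data.frame(gene_id = gene_id, start = rows$start, end = rows$end,
               phase = rows$phase, stringsAsFactors = FALSE)
  }
  exons <- collect("exon")
  cds <- collect("CDS")
  # order intervals in transcript orientation and check exon disjointness
  order_tx <- function(tab) {
    out <- lapply(split(tab, tab$gene_id), function(g) {
      strand <- gene_rows$strand[match(g$gene_id[1], gene_rows$id)]
      g[order(g$start, decreasing = identical(strand, "-")), , drop = FALSE]
    })
    do.call(rbind, c(out, list(make.row.names = FALSE)))
  }
  if (nrow(exons)) {
    for (g in split(exons, exons$gene_id)) {
      o <- g[order(g$start), , drop = FALSE]
      if (nrow(o) > 1 && any(o$start[-1] <= o$end[-nrow(o)]))
        stop("overlapping exons within gene ", g$gene_id[1])
    }
    exons <- order_tx(exons)
  }
  if (nrow(cds)) cds <- order_tx(cds)
  genes <- data.frame(
    gene_id = gene_rows$id, chrom = gene_rows$chrom,
    strand = gene_rows$strand, start = gene_rows$start, end = gene_rows$end,
    stringsAsFactors = FALSE
  )
  gene_model_set(genes, exons, cds)
}

#' Construct a gene model set
#'
#' @param genes Data frame (gene_id, chrom, strand, start, end).
#' @param exons,cds Data frames (gene_id, start, end[, phase]) in transcript
#'   orientation.
#' @return A `gene_model_set`.
#' @export
gene_model_set <- function(genes, exons, cds) {
  if (!"phase" %in% names(cds)) cds$phase <- NA_integer_
  structure(list(genes = genes, exons = exons, cds = cds),
            class = "gene_model_set")
}

empty_gene_model_set <- function() {
  gene_model_set(
    data.frame(gene_id = character(), chrom = character(),
               strand = character(), start = integer(), end = integer(),
               stringsAsFactors = FALSE),
    data.frame(gene_id = character(), start = integer(), end = integer(),
               stringsAsFactors = FALSE),
    data.frame(gene_id = character(), start = integer(), end = integer(),
               phase = integer(), stringsAsFactors = FALSE)
  )
}

#' @export
print.gene_model_set <- function(x, ...) {
  cat("gene_model_set:", nrow(x$genes), "genes,", nrow(x$exons), "exons,",
      nrow(x$cds), "CDS intervals\n")
  invisible(x)
}

# GRanges of full gene bodies (transcription start..end)
gene_ranges <- function(genes) {
  GenomicRanges::GRanges(
    seqnames = genes$genes$chrom,
    ranges = IRanges::IRanges(start = genes$genes$start, end = genes$genes$end),
    gene_id = genes$genes$gene_id
  )
}
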