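## Tab-separated report writers for the pipeline's products. Variant
## positions are written 1-based; the callset writer round-trips through
## read_callset().

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a pipeline product as a tab-separated report
#'
#' Methods exist for somatic call sets (round-trips through
#' [read_callset()]), cascade reports, spectrum reports, sharing partitions
#' (the per-clone burden table), cluster results, ancestor-count reports and
#' plain data frames (e.g. CNV segment tables).
#'
#' @param x A pipeline product.
#' @param path Output path.
#' @param ... Unused.
#' @return Invisibly, `path`.
#' @export
write_report <- function(x, path, ...) UseMethod("write_report")

#' @export
write_report.somatic_callset <- function(x, path, ...) {
  df <- x$sites
  df$carriers <- vapply(x$carriers, paste, character(1), collapse = ",")
  write_tsv(df, path)
}

#' @export
write_report.cascade_report <- function(x, path, ...) {
  write_tsv(as.data.frame(x), path)
}

#' @export
write_report.spectrum_report <- function(x, path, ...) {
  df <- x$classes
  df$percent <- round(100 * df$proportion, 1)
  write_tsv(df, path)
}

#' @export
write_report.sharing_partition <- function(x, path, ...) {
  write_tsv(x$burden, path)
}

#' @export
write_report.cluster_result <- function(x, path, ...) {
  write_tsv(data.frame(clone = names(x$labels), group = unname(x$labels)),
            path)
}

#' @export
write_report.ancestor_count_report <- function(x, path, ...) {
  write_tsv(x$per_clone, path)
}

#' @export
write_report.data.frame <- function(x, path, ...) write_tsv(x, path)

#' Read a somatic callset report back
#'
#' Inverse of `write_report()` on a `somatic_callset`.
#'
#' @param path Path written by [write_report()].
#' @return A [somatic_callset()].
#' @export
read_callset <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  df$pos <- as.integer(df$pos)
  df$qual <- as.numeric(df$qual)
  df$mean_carrier_depth <- as.numeric(df$mean_carrier_depth)
  carriers <- strsplit(df$carriers, ",", fixed = TRUE)
  df$carriers <- NULL
  somatic_callset(df, carriers)
}

#' Write CNV segments as a BED file
#'
#' BED uses 0-based half-open coordinates; the segment table's 1-based
#' inclusive intervals are converted on output.
#'
#' @param segments A [call_segments()] result.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(segments, path) {
  bed <- data.frame(chrom = segments$chrom,
                    start = segments$start - 1L,
                    end = segments$end,
                    name = segments$direction,
                    score = round(-10 * log10(pmax(segments$min_p, 1e-300))))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
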