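## Windowed copy-number deletion scan: per-window log2 ratio of
## library-size-normalised read counts (test vs reference sample) and a
## ratio-distribution p-value from the Geary-Hinkley transformation, which
## maps the ratio of two Gaussian variables (here the normal approximations
## of the Poisson window counts) onto a standard normal deviate. Maximal runs
## of consecutive significant same-direction windows become segments.

#' Construct a window-count table
#'
#' @param windows Data frame with `chrom`, `start`, `end` (1-based
#'   inclusive), `test`, `ref`; windows must tile each chromosome in order
#'   without overlap.
#' @param window_size Window width in bp.
#' @return A `window_count_table` (data frame with attributes `window_size`,
#'   `total_test`, `total_ref`).
#' @export
window_count_table <- function(windows, window_size) {
  req <- c("chrom", "start", "end", "test", "ref")
  if (!all(req %in% names(windows)))
    stop("windows must have columns: ", paste(req, collapse = ", "))
  if (any(windows$test < 0) || any(windows$ref < 0))
    stop("counts must be >= 0")
  for (g in split(windows, windows$chrom)) {
    o <- g[order(g$start), ]
    if (nrow(o) > 1 && any(o$start[-1] <= o$end[-nrow(o)]))
      stop("overlapping windows on ", g$chrom[1])
  }
  structure(as.data.frame(windows),
            class = c("window_count_table", "data.frame"),
            window_size = window_size,
            total_test = sum(windows$test),
            total_ref = sum(windows$ref))
}

#' Log2 count ratio and Geary-Hinkley p-value
#'
#' The copy-number ratio is `r = ((x + c)/Nx) / ((y + c)/Ny)` with
#' pseudo-count `c` (default 0.5) so fully deleted windows stay finite. The
#' p-value tests divergence from a 1:1 copy ratio: with `r0 = Nx/Ny` the
#' expected count ratio under the null, the Geary-Hinkley deviate is
#' `t = (y*r0 - x) / sqrt(y*r0^2 + x)` and `p = 2*(1 - pnorm(|t|))`.
#' Swapping test and reference flips every log2 ratio's sign and leaves the
#' p-values unchanged.
#'
#' @param x,y Test and reference window counts (vectorised).
#' @param nx,ny Total read counts of the test and reference samples.
#' @param pseudo Pseudo-count added to both window counts for the ratio.
#' @return Data frame with `log2_ratio` and `p`.
#' @export
log2_ratio_pvalue <- function(x, y, nx, ny, pseudo = 0.5) {
  if (any(x < 0) || any(y < 0)) stop("counts must be >= 0")
  if (nx <= 0 || ny <= 0) stop("totals must be > 0")
  r <- ((x + pseudo) / nx) / ((y + pseudo) / ny)
  r0 <- nx / ny
  denom <- sqrt(y * r0^2 + x)
  t <- ifelse(denom > 0, (y * r0 - x) / denom, 0)
  p <- pmin(1, pmax(0, 2 * stats::pnorm(-abs(t))))
  data.frame(log2_ratio = log2(r), p = p)
}

#' Call CNV segments from a window-count table
#'
#' Computes per-window log2 ratio and Geary-Hinkley p, marks windows with
#' `p <= alpha` and `|log2 ratio| >= log2_cut`, and emits every maximal run
#' of at least `min_windows` consecutive marked windows of one direction as
#' a segment. Runs never cross chromosome boundaries. Raw per-window
#' p-values are used by default (the run-length requirement does the
#' multiplicity control); `adjust = "BH"` switches to
#' Benjamini-Hochberg-adjusted p-values.
#'
#' @param table A [window_count_table()].
#' @param alpha Per-window significance level (default 1e-3).
#' @param min_windows Minimum run length (default 3).
#' @param log2_cut Minimum absolute log2 ratio (default 0.5).
#' @param pseudo Pseudo-count for the ratio.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Data frame of segments: `chrom`, `start`, `end` (1-based
#'   inclusive), `n_windows`, `mean_log2`, `min_p`, `direction`
#'   (`"deletion"`/`"insertion"`), sorted and non-overlapping.
#' @export
call_segments <- function(table, alpha = 1e-3, min_windows = 3,
                          log2_cut = 0.5, pseudo = 0.5,
                          adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (min_windows < 1) stop("min_windows must be >= 1")
  nx <- attr(table, "total_test")
  ny <- attr(table, "total_ref")
  stats <- log2_ratio_pvalue(table$test, table$ref, nx, ny, pseudo)
  p <- if (adjust == "BH") stats::p.adjust(stats$p, "BH") else stats$p
  sig <- p <= alpha & abs(stats$log2_ratio) >= log2_cut &
    is.finite(stats$log2_ratio)
  state <- ifelse(sig, sign(stats$log2_ratio), 0)
  segs <- list()
  for (chrom in unique(table$chrom)) {
    sel <- which(table$chrom == chrom)
    sel <- sel[order(table$start[sel])]
    r <- rle(state[sel])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in seq_along(r$values)) {
      if (r$values[i] == 0 || r$lengths[i] < min_windows) next
      idx <- sel[starts[i]:ends[i]]
      segs[[length(segs) + 1L]] <- data.frame(
        chrom = chrom,
        start = min(table$start[idx]),
        end = max(table$end[idx]),
        n_windows = length(idx),
        mean_log2 = mean(stats$log2_ratio[idx]),
        min_p = min(p[idx]),
        direction = if (r$values[i] < 0) "deletion" else "insertion",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(segs))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_windows = integer(),
                      mean_log2 = numeric(), min_p = numeric(),
                      direction = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, segs)
  out[order(out$chrom, out$start), , drop = FALSE]
}
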