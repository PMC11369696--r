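#!/usr/bin/env Rscript
# Scan the per-clone window-count tables for copy-number deletions with the
# Geary-Hinkley ratio test (alpha 1e-3, >= 3 consecutive windows, |log2|
# >= 0.5), intersect the segments with gene models, and compare against the
# planted truth intervals.

library(clonetrace)

run <- "results/run"
truth_cnv <- read.delim(file.path(run, "truth_cnvs.tsv"))
genes <- sim_gene_models(sim_genome(), seed = 1)

all_segs <- list()
for (f in list.files(run, pattern = "^windows_.*\\.tsv$")) {
  clone <- sub("^windows_(.*)\\.tsv$", "\\1", f)
  w <- window_count_table(read.delim(file.path(run, f)), 1000)
  segs <- call_segments(w, alpha = 1e-3, min_windows = 3, log2_cut = 0.5)
  if (nrow(segs)) segs$clone <- clone
  all_segs[[clone]] <- segs
}
segs <- do.call(rbind, all_segs)
rownames(segs) <- NULL
write_report(segs, file.path(run, "cnv_segments.tsv"))
write_bed(segs, file.path(run, "cnv_segments.bed"))

cat(nrow(segs), "CNV segments in", length(unique(segs$clone)), "clones:\n")
print(segs[, c("clone", "chrom", "start", "end", "mean_log2", "direction")])

hits <- do.call(rbind, lapply(seq_len(nrow(segs)), function(i) {
  g <- genes_in_deletion(segs[i, ], genes)
  if (nrow(g)) cbind(clone = segs$clone[i], chrom = segs$chrom[i], g) else NULL
}))
if (!is.null(hits)) {
  write_report(hits, file.path(run, "cnv_gene_hits.tsv"))
  cat(nrow(hits), "genes overlapped by deletions\n")
} else cat("no genes overlapped by deletions\n")

for (j in seq_len(nrow(truth_cnv))) {
  s <- segs[segs$clone == truth_cnv$clone[j] &
              segs$chrom == truth_cnv$chrom[j] &
              segs$start < truth_cnv$end[j] & segs$end > truth_cnv$start[j], ]
  cat(sprintf("planted %s:%d-%d (%s): %s\n", truth_cnv$chrom[j],
              truth_cnv$start[j], truth_cnv$end[j], truth_cnv$clone[j],
              if (nrow(s) == 1) "recovered" else "MISSED"))
}
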