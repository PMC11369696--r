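#!/usr/bin/env Rscript
# Characterize the filtered somatic SNVs: strand-collapsed substitution
# spectrum with Ti/Tv, the unique/common sharing partition with per-clone
# burdens, and the gene-body vs intergenic split against simulated gene
# models.

library(clonetrace)

run <- "results/run"
cs <- read_callset(file.path(run, "callset.tsv"))
sample_map <- read.delim(file.path(run, "sample_map.tsv"))
replicate_map <- with(subset(sample_map, sample != clone),
                      setNames(clone, sample))

sp <- spectrum_summary(cs)
write_report(sp, file.path(run, "spectrum.tsv"))
print(sp)

part <- partition_by_sharing(cs, replicate_map,
                             all_clones = unique(sample_map$clone))
write_report(part, file.path(run, "burden.tsv"))
cat(sprintf("%d unique and %d common somatic SNVs across %d clones\n",
            length(part$unique_idx), length(part$common_idx),
            length(part$clones)))
top <- head(part$burden[order(-part$burden$total), ], 3)
cat("highest burdens:", paste(top$clone, top$total, collapse = ", "), "\n")

genes <- sim_gene_models(sim_genome(), seed = 1)
region <- annotate_region(cs$sites, genes)
write_report(data.frame(chrom = cs$sites$chrom, pos = cs$sites$pos,
                        region = region),
             file.path(run, "regions.tsv"))
cat(sprintf("%d variants (%.1f%%) in gene bodies, %d (%.1f%%) intergenic\n",
            sum(region == "genic"), 100 * mean(region == "genic"),
            sum(region == "intergenic"), 100 * mean(region == "intergenic")))
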