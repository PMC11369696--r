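#!/usr/bin/env Rscript
# Build the study-scale synthetic dataset: 46 clones from eight founder
# lineages (group sizes 19/7/4/2/3/1/1/9), one replicate pair, 34x depth,
# a 10-line outgroup panel, five 10-25 kb deletions in four carriers, and
# labelled artifact sites for every filter stage. Outputs under results/run.

library(clonetrace)

out <- "results/run"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- simulation_config(seed = 1)
sim <- simulate_propagation(cfg)
aug <- inject_artifacts(sim)

write_vcf(aug$table, file.path(out, "variants.vcf"))
write_vcf(sim$table, file.path(out, "true_variants.vcf"))
writeLines(truth_newick(sim$truth), file.path(out, "truth_tree.nwk"))
write_report(sim$truth$site_branch, file.path(out, "truth_sites.tsv"))
write_report(aug$sidecar, file.path(out, "artifact_sidecar.tsv"))
write_report(sim$truth$cnvs, file.path(out, "truth_cnvs.tsv"))
for (cl in names(sim$windows))
  write_report(as.data.frame(sim$windows[[cl]]),
               file.path(out, paste0("windows_", cl, ".tsv")))
writeLines(c(paste("sample", "clone", sep = "\t"),
             paste(aug$table$samples,
                   ifelse(aug$table$samples %in% names(sim$truth$replicate_map),
                          sim$truth$replicate_map[aug$table$samples],
                          aug$table$samples), sep = "\t")),
           file.path(out, "sample_map.tsv"))

cat("simulated", nrow(sim$truth$site_branch), "true somatic SNVs on",
    nrow(sim$truth$edges), "branches;", nrow(aug$sidecar),
    "artifact sites;", nrow(sim$truth$cnvs), "planted deletions\n")
cat("wrote", out, "\n")
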