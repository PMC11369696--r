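#!/usr/bin/env Rscript
# Group the clones from their shared somatic mutations: binary incidence
# matrix over common sites, cluster-number selection from the cumulative
# explained variance at threshold 0.95, average-linkage/Jaccard dendrogram,
# plus the identity-by-state NJ check against a synthetic outgroup.

library(clonetrace)

run <- "results/run"
cs <- read_callset(file.path(run, "callset.tsv"))
sample_map <- read.delim(file.path(run, "sample_map.tsv"))
replicate_map <- with(subset(sample_map, sample != clone),
                      setNames(clone, sample))

part <- partition_by_sharing(cs, replicate_map,
                             all_clones = unique(sample_map$clone))
m <- build_matrix(part)
sel <- select_cluster_number(m, threshold = 0.95)
groups <- cluster_clones(m, sel$k)
write_report(groups, file.path(run, "groups.tsv"))
write_report(data.frame(component = seq_along(sel$cev), cev = sel$cev),
             file.path(run, "cev_curve.tsv"))

cat(sprintf("CEV reaches 0.95 at %d components; %d clones in %d groups\n",
            sel$k, nrow(m), groups$k))
print(table(groups$labels))

# identity check: clones should collapse to one clade against an outgroup
vt <- read_vcf(file.path(run, "true_variants.vcf"))
set.seed(1)
og <- ifelse(vt$geno[, 1] == "hom_alt", "hom_ref",
             ifelse(runif(n_sites(vt)) < 0.5, "hom_alt", "hom_ref"))
vt2 <- variant_table(vt$sites, cbind(vt$geno, OUT = og),
                     cbind(vt$depth, OUT = rep(30L, n_sites(vt))))
tree <- identity_tree(vt2, "OUT")
ape::write.tree(tree, file.path(run, "identity_tree.nwk"))
clones <- setdiff(colnames(vt$geno), names(replicate_map))
cat("clones monophyletic against outgroup:",
    ape::is.monophyletic(tree, c(clones, names(replicate_map))), "\n")
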