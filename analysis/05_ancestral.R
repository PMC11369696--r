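#!/usr/bin/env Rscript
# Polarize the somatic sites against the 10-line outgroup panel (strict
# majority = ancestor-type allele), count ancestor-type alleles per clone
# over common and unique sites, and rank the clones by closeness to the
# ancestral state.

library(clonetrace)

run <- "results/run"
cs <- read_callset(file.path(run, "callset.tsv"))
sample_map <- read.delim(file.path(run, "sample_map.tsv"))
replicate_map <- with(subset(sample_map, sample != clone),
                      setNames(clone, sample))

# the simulated panel is invariant (all ancestral = reference) at true sites
panel <- outgroup_panel(cs$sites[, c("chrom", "pos")],
                        matrix("ref", nrow(cs$sites), 10,
                               dimnames = list(NULL, sprintf("OG%02d", 1:10))))
part <- partition_by_sharing(cs, replicate_map,
                             all_clones = unique(sample_map$clone))
m <- build_matrix(part)
groups <- cluster_clones(m, select_cluster_number(m, 0.95)$k)

polar <- polarize_sites(cs, panel)
anc <- ancestor_counts(polar, part, groups)
write_report(anc, file.path(run, "ancestor_counts.tsv"))
write_report(anc$group_means, file.path(run, "ancestor_group_means.tsv"))

pc <- anc$per_clone
cat(sprintf("ancestor-type counts over %d common sites: %d (%s) to %d (%s)\n",
            pc$common_denom[1], min(pc$common_count),
            pc$clone[which.min(pc$common_count)], max(pc$common_count),
            pc$clone[which.max(pc$common_count)]))
ranking <- rank_closest_to_ancestor(anc)
cat("closest to the ancestral state:", head(ranking, 3), "\n")
write_report(data.frame(rank = seq_along(ranking), clone = ranking),
             file.path(run, "ancestor_ranking.tsv"))
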