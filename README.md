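# clonetrace

Somatic-mutation-based lineage tracing for clonally propagated plants.

Vegetatively propagated cultivars — grafted fruit and flowering trees,
cutting-propagated crops — are genetically near-identical, so conventional
markers cannot tell one clone's history from another's. Somatic mutations
can: a mutation that arises in the meristem of one tree is inherited by
every clone later propagated from that branch and is essentially never
reversed. The set of mutations *shared* between clones therefore records
the propagation chain, and the clone carrying the fewest shared derived
alleles sits closest to the common ancestor. `clonetrace` implements this
inference for whole-genome resequencing data of clone panels called against
a **haplotype-phased reference** (two haplotype chromosome sets, e.g.
SPA1–SPA8 / SPE1–SPE8), where a true heterozygous somatic allele appears as
a *homozygous* call on one haplotype's chromosome.

The package provides, per module:

- **Somatic filter cascade** (`run_cascade`): biallelic SNVs → sites with
  only haplotype-specific (all-homozygous) calls → replicate-consistent
  genotypes → read depth ≤ 50 and site quality ≥ 80, then carrier-set
  construction with a polymorphism screen. Every stage count is reported.
- **Mutation spectrum** (`spectrum_summary`, `partition_by_sharing`): the
  six strand-collapsed substitution classes, Ti/Tv ratio, and the partition
  into clone-unique (carrier count = 1) and common (≥ 2) sites with
  per-clone burdens.
- **Effect annotation** (`annotate_region`, `classify_effect`,
  `genes_in_deletion`): gene-body vs intergenic assignment, codon-level
  consequences (stop gained / missense / synonymous), splice-site flags,
  and gene-deletion calls for CNV segments.
- **Clone clustering** (`build_matrix`, `select_cluster_number`,
  `cluster_clones`, `identity_tree`): binary clone × common-site incidence
  matrix; the cluster number is the smallest component count whose
  cumulative explained variance (CEV) reaches a threshold (default 0.95);
  groups come from average-linkage clustering on Jaccard distances; an
  identity-by-state neighbour-joining tree provides the clone-identity
  check against an outgroup.
- **Ancestral analysis** (`polarize_sites`, `ancestor_counts`,
  `rank_closest_to_ancestor`): the ancestor-type allele at each site is the
  strict majority allele of a 10-line outgroup panel; clones are ranked by
  their ancestor-type allele count over the common sites.
- **CNV deletion scan** (`log2_ratio_pvalue`, `call_segments`): windowed
  log2 ratio of library-normalised read counts with a Geary–Hinkley
  ratio-test p-value (the ratio of the two approximately Gaussian Poisson
  counts mapped to a standard normal deviate); maximal runs of significant
  same-direction windows become segments.
- **Synthetic data generator** (`simulation_config`,
  `simulate_propagation`, `inject_artifacts`): clonal-propagation datasets
  with a known propagation tree, branch-assigned mutations, an outgroup
  panel, planted 10–25 kb deletions, and labelled artifact sites targeting
  each cascade stage — so the whole pipeline is testable against ground
  truth.

## Worked example

A bundled toy panel (6 clones, one sequenced twice as replicates
`C01_A`/`C01_B`) runs through the cascade and the sharing analysis:

```r
library(clonetrace)
vcf <- system.file("extdata", "example_clones.vcf", package = "clonetrace")
vt  <- read_vcf(vcf)
res <- run_cascade(vt, filter_config(replicate_pairs = list(c("C01_A", "C01_B"))))
res$report
#>                  stage n_sites
#> 1                  raw      34
#> 2            biallelic      34
#> 3   haplotype_specific      34
#> 4 replicate_consistent      34
#> 5        depth_quality      34
#> 6              somatic      34

spectrum_summary(res$callset)
#> mutation spectrum over 34 SNVs; Ti/Tv = 1.12
#>    class count proportion is_transition percent
#>  C:G>T:A    12 0.35294118          TRUE    35.3
#>  A:T>T:A     6 0.17647059         FALSE    17.6
#>  ...

part <- partition_by_sharing(res$callset,
                             replicate_map = c(C01_A = "C01", C01_B = "C01"))
part$burden
#>   clone unique common total
#> 1   C01      1     13    14
#> 2   C02      1     13    14
#> 3   C03      3      6     9
#> ...
```

This clean toy panel loses nothing in the cascade (all 34 candidate sites
are genuine somatic SNVs); on realistic input each stage removes its target
artifact class — tri-allelic records, cross-haplotype het calls,
replicate-discordant sites, collapsed-repeat pileups and low-quality calls.
`unique` counts mutations private to one clone (arisen after its
propagation), `common` counts mutations shared through the propagation
chain; the two replicate runs of tree C01 are collapsed before counting.

The numbered scripts under `analysis/` run the full study-scale workflow —
simulate a 46-clone panel, filter, characterize, cluster, polarize, scan
for deletions — writing all tables under `results/run/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_filter_cascade.R
# ... through analysis/06_cnv_scan.R
```

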