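---
title: "Tracing clonal propagation lineages from somatic mutations"
author: "clonetrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing clonal propagation lineages from somatic mutations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonetrace)
```

## The model

A vegetatively propagated cultivar is a set of genetically near-identical
individuals descended from one ancestral tree through a chain of grafting
or cutting events. Somatic mutations accumulate along that chain and are,
for practical purposes, irreversible: a mutation present in the meristem
from which a clone was taken is carried by that clone and by every clone
propagated from it afterwards. The observable consequence is a perfect
containment structure — each mutation's carrier set is exactly the leaf
set of one branch of the (unobserved) propagation tree. Mutations on
terminal branches are private to one clone ("unique"); mutations on
internal branches are shared by two or more ("common"). The common
mutations carry all the lineage signal: clustering clones by shared
mutations recovers propagation groups, and counting how many *ancestral*
(pre-mutation) alleles a clone retains at the common sites orders clones
by their distance from the ancestor.

Genotypes come from short-read calls against a *haplotype-phased*
reference in which the two parental haplotypes are separate chromosome
sequences (here tagged SPA and SPE). This matters for filtering: a true
somatic allele, heterozygous at the cell level, produces a *homozygous*
alternate call on its own haplotype's chromosome, because only reads from
that haplotype map there. A *heterozygous* call on a phased reference
instead indicates reads from both haplotypes piling up at one place —
cross-haplotype mis-mapping — and is treated as an artifact.

## The filter cascade

Raw merged multi-sample calls are reduced to high-confidence somatic SNVs
in four ordered stages:

1. **Biallelic SNVs.** Sites with one single-base alternate allele.
   Tri-/tetra-allelic sites overwhelmingly reflect mapping errors in
   repeats; indels are out of scope.
2. **Haplotype-specific homozygosity.** Every non-missing call must be
   homozygous (reference or alternate), per the phased-reference argument
   above. Sites with no non-missing call carry no evidence and are also
   dropped.
3. **Replicate consistency.** Within each biological replicate pair (two
   sequencing runs of the same tree) the genotype codes must be identical.
   A missing call is never "consistent" — this is deliberately
   conservative, since a replicate pair exists precisely to confirm calls.
4. **Depth and quality.** Site quality ≥ 80 (phred-scaled site QUAL) and
   carrier read depth ≤ 50. The depth criterion is a *maximum*: excessive
   depth marks collapsed repeats, where paralogous reads stack up and
   produce confident-looking false homozygous calls. It is evaluated on
   the mean over carrier (hom-alt) calls by default; a per-sample switch
   (`depth_scope = "per_sample"`) is available, as the choice between the
   two is not forced by anything in the data model.

After the stages, carriers are the samples with hom-alt calls. Sites with
no carrier are non-somatic; sites carried by *every* sample are
reference-base errors rather than somatic mutations and are dropped by
default (`require_polymorphic = TRUE`) — a mutation shared by all clones
is indistinguishable from an error in the reference base itself.

Whether the original quality criterion meant site QUAL or per-genotype GQ
is not decidable from the call annotations modelled here; site QUAL is
used because it is what a bcftools-style caller always provides. The
homozygosity reading of "haplotype-specific" in stage 2 is likewise this
package's stated reconstruction.

## Mutation spectrum

The 12 ordered base substitutions collapse to six strand-symmetric
classes (a change and its reverse complement are one mutational event);
C:G→T:A and A:T→G:C are the transitions. The transition/transversion
ratio is reported as `NA` when there are no transversions — an undefined
ratio, not an infinite one. Proportions are printed at one decimal
percent; full precision is kept internally.

## Clustering and cluster-number selection

Clones are clustered on the binary clone × common-site incidence matrix
(replicate runs collapsed to one clone first). Two genuinely open design
choices were fixed as follows:

- **Distance and linkage.** Jaccard distance on the binary carrier
  profiles with average linkage. Jaccard ignores shared absences, which is
  right for sparse presence/absence data (two clones are similar because
  they share mutations, not because they both lack them); average linkage
  is the common choice for genotype dendrograms. Both are recorded in the
  result object; two all-zero profiles get distance 0 (they are
  identical, not undefined).
- **Cluster number from cumulative explained variance (CEV).** The
  selected number of groups is the smallest `j` whose top-`j`
  principal-component variance fraction reaches the threshold (default
  0.95). The spectrum is computed on the **uncentred** incidence matrix.
  This is intentional: on noise-free clonal data with `d` distinct
  lineage signatures the uncentred spectrum has exactly `d` non-zero
  components, so the selected count equals the number of signatures,
  which is the quantity the dendrogram is then cut into. Centring removes
  one component (the mean), making the component count `d − 1` and
  breaking that correspondence in exactly the clean cases where the
  answer is known. For noisy, full-rank data the two differ little.
  Deterministic group labels: groups are numbered by decreasing size,
  ties broken by smallest member name.

The identity-by-state neighbour-joining tree (`identity_tree`) is a
separate sanity check that a clone panel really is one cultivar: clones
sit at near-zero pairwise distances and form a single clade when rooted
on a divergent outgroup. Distances are mean absolute differences of
0/1/2-coded genotypes over co-called sites.

## Ancestral polarization and ranking

At each somatic site, the allele carried by a **strict majority** of the
outgroup panel's non-missing calls is the ancestor-type allele. Ties are
`ambiguous` and excluded; so are sites with fewer than `min_calls = 3`
non-missing panel calls, to guard against polarizing on one or two lines.
The study system this models had an invariant panel (all ten outgroup
lines carried the same allele everywhere), so the tie rule never fired
there; it still needs a definition, and exclusion is the conservative
one.

A clone's ancestor-type count over the common sites equals (polarized
common sites) − (shared derived mutations on its propagation path), so
ranking by descending common-site count puts the clone with the lightest
shared mutational load — the earliest offshoot — first. Ties break by
descending unique-site count, then name. Unique-site counts are reported
as a secondary quantity (informally, a proxy for time since the clone's
own propagation) but never drive the primary ranking.

## CNV deletion scan

Per chromosome, fixed windows (default 1 kb) carry read counts for a test
and a reference clone. The copy-number ratio per window is
`r = ((x + ½)/Nx) / ((y + ½)/Ny)`; the pseudo-count keeps fully deleted
windows finite (a full deletion on a phased haplotype leaves counts near
zero). Significance comes from the Geary–Hinkley transformation: treating
the Poisson counts as Gaussian with variance equal to their mean, the
deviate `t = (y·r₀ − x) / sqrt(y·r₀² + x)` with `r₀ = Nx/Ny` is standard
normal under the 1:1 null, giving a two-sided p-value. At the default
window expectation (~226 reads at 34× with 150 bp reads) the Gaussian
approximation is comfortable, and the empirical type-I error at α = 0.05
lands within a couple of points of nominal (the test suite checks
[0.03, 0.07] over 2 × 10⁴ null windows).

Segments are maximal runs of ≥ `min_windows` (default 3) consecutive
windows with `p ≤ α` (default 10⁻³) and `|log2 ratio| ≥ 0.5`, same
direction, never crossing a chromosome boundary. No multiple-testing
correction is applied per window by default — the run-length requirement
is the multiplicity control, which is the classic windowed-scan design; a
Benjamini–Hochberg option exists behind `adjust = "BH"`. Swapping test
and reference flips every log2 sign and preserves p-values exactly.

Which clone serves as the reference is configurable; in the study system
this models, the published account names the reference inconsistently
between text and figure, so nothing is hard-coded.

## The synthetic data generator

`simulate_propagation` emulates the statistical structure of a clone
resequencing study, with defaults set to the modelled system: 46 clones
in eight founder lineages of sizes 19/7/4/2/3/1/1/9, nested random
binary propagation within each lineage, one clone sequenced as two
replicate runs, mean depth 34×, a 10-line invariant outgroup panel, and
five planted deletions of 25/10/15/10/25 kb across four carrier clones.
Per-branch mutation counts are Poisson; the default terminal and internal
means put roughly nine unique mutations on record for every shared one,
matching the heavily terminal-weighted sharing seen in clonal surveys.
Substitutions are drawn from the six strand-collapsed classes with a
C:G→T:A-dominated weight vector typical of plant somatic spectra, and
site positions are uniform over both haplotype chromosome sets.

Two generator choices are deliberate idealizations:

- True-site depths are Poisson(34) *truncated at 50* and true-site
  qualities are `80 + gamma`, i.e. genuine somatic sites always sit inside
  the cascade's accepted region, while `inject_artifacts` plants sites
  that violate exactly one criterion each (tri-allelic records, het
  calls, replicate-discordant pairs, depth pileups, low quality). This
  makes cascade precision and recall well-defined quantities with exact
  sidecar truth. Real data has overlapping distributions; passing the
  truth-recovery tests therefore demonstrates that the *logic* of each
  stage is right, not that these thresholds are optimal on real reads.
- Artifact classes are specified as exact counts, not rates, for the same
  reason: the bookkeeping against the sidecar is then exact.

The generator does not model read-level noise, mapping, trinucleotide
context, back-mutation, recombination, or selection.

## Problem sizes and numerical choices

The test suite and the acceptance script run the generator at the study
scale (46 clones, ~700 true sites, 450 artifacts; 2 × 10⁴ null CNV
windows; 10⁶ Monte-Carlo replicates for the ratio-test oracle), which
completes in well under a minute per analysis on one core. Lineage
recovery is exercised with balanced founder sizes (6,6,6,6,6,6,5,5) and
star-shaped subtrees so that every founder branch is internal and each
lineage leaves a distinct signature — with singleton lineages a founder
branch is terminal, its mutations are private, and no clustering method
could tell two signature-less singletons apart; the balanced design is
the cleanest configuration in which the selection rule's answer is
provably the founder count. Eigenvalues below `1e-12` of the largest are
treated as zero in the CEV; the CEV curve ends at 1 within `1e-9`.
Degenerate inputs (empty tables, all-missing sites, zero-transversion
spectra, empty callsets) return empty results or `NA`, not errors, except
where an invariant is genuinely violated (empty carrier sets, CDS length
not divisible by three).

## Limitations

- The effect classifier is a simplified consequence caller: one
  transcript per gene, SNVs only, no UTR subclasses, no start/stop-loss
  special cases beyond stop-gain; deletions are annotated only as whole
  gene overlaps.
- The homozygosity reconstruction of haplotype-specific filtering assumes
  a fully phased, assembly-complete reference; collapsed or missing
  haplotype sequence would reintroduce het artifacts the cascade then
  removes at stage 2, costing recall on real data.
- The CEV rule conflates component count and cluster count by design; it
  is one defensible reconstruction of cluster-number selection on
  genotype matrices, and both the threshold and the clustering metric are
  configurable rather than claimed optimal.
- Ancestor ranking orders clones; it does not date divergences, and the
  package makes no claims about calendar ages of clones.
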