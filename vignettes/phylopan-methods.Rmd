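---
title: "Methods: species delimitation and pangenome dynamics with phylopan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: species delimitation and pangenome dynamics with phylopan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`phylopan` packages the comparative-genomics workflow behind
whole-genome bacterial species delimitation: intergenomic distances,
hierarchical clustering scored by the adjusted Rand index, a
neighbour-joining phylogeny, pangenome rarefaction, Faith's phylogenetic
diversity with a randomisation null, multi-gene character scoring and
genomic-island synteny. This vignette is the package's own account of
those methods: the models and their assumptions, the parameters that
matter, the numerical choices, and what the synthetic ground truth does
and does not establish.

## Intergenomic distances and dDDH

Genome-BLAST distance approaches summarise the locally alignable
fraction of two genomes into one distance. `phylopan` implements a
deliberately simplified kernel rather than reproducing any particular
alignment server bit-for-bit:

1. exact `k`-mer seeds (`k = 12` bp by default; values below 8 are
   rejected) define candidate diagonals;
2. along each diagonal an ungapped X-drop scan (match +1, mismatch −3,
   drop 12) emits maximal locally similar segments, trimmed to start and
   end on a match and discarded below `min_len` (50 bp default);
3. segments are made non-overlapping on the query greedily by descending
   identities, each trimmed match re-scored on its retained interval.

Two distance formulas are available: `identity`,
`d = 1 − Σident/Σlen` over matched segments (per-site divergence inside
homologous regions; `d = 1` with no matches), and `coverage`,
`d = 1 − 2Σlen/(LA + LB)` (unmatched genome fraction). Both are clamped
to [0, 1]. Matrices are computed once per unordered pair on the
canonically ordered pair, so symmetry is exact by construction; only
symmetry, range and a zero diagonal are asserted — these distances are
not guaranteed metric, and no triangle inequality is claimed.
Matching is forward-strand and per replicon; the synthetic generator
keeps each gene cassette's strand consistent across genomes, which is
the regime this kernel is intended for. For published distance tables
the TSV/PHYLIP loaders are the fidelity path; the kernel is for
self-contained, desk-scale analyses.

Distance converts to digital DNA–DNA hybridization through a logistic
curve in log-distance, `dDDH(d) = 100/(1 + exp(a + b log d))`, with
`dDDH(0) = 100` taken as the limiting value and evaluated exactly at
`d = 0`. The two coefficients are fitted exactly through the
species-boundary anchor (0.036 ↔ 70%) and a configurable far anchor.
The far anchor's default, (0.25, 25), is an artifact choice shaping the
tail of the curve — published sources pin only the 70% anchor — and both
anchors are exposed in `ddh_calibration()`. The curve is strictly
decreasing whenever the anchors are consistent (`b > 0` is enforced),
and the analytic inverse `distance_from_ddh()` round-trips to numerical
precision.

Query filtering (`filter_by_query()`) keeps genomes at distance ≤ the
threshold, *inclusive* — retaining genomes "at" the boundary is the
safer reading of threshold-based subgroup selection — with the default
0.135 matching the subgroup-versus-neighbour boundary of the motivating
system. All threshold comparisons in the package (query filter,
dendrogram cuts, the ≥50% character rule) are inclusive for the same
reason.

## Species delimitation

The reference partition at species rank is defined as single-linkage
components at `T_ref = 0.036` (edges join genomes at `d ≤ T_ref`): the
only threshold firmly tied to species rank is dDDH 70%, and connected
components are its natural partition. Because the construction of the
reference is a genuinely open choice, `delimit_species()` accepts a
user-supplied reference partition instead (e.g. taxonomic server calls).

The scan evaluates agglomerative clusterings for `F = 0, 0.5, 1`
(single, average/UPGMA, complete linkage — `stats::hclust` supplies the
clustering engine) over thresholds from 0 to the maximum observed
distance in steps of 0.0005, scoring each cut against the reference with
the adjusted Rand index. Cut semantics are inclusive: merges at height
exactly `T` are applied (implemented as a cut at `T + 1e-12` to absorb
floating-point noise in merge heights). The best record maximises ARI
with ties resolved to the smallest `T`, then the smallest `F`, making
the scan fully deterministic. Two invariants are enforced by tests:
`k(T)` is non-increasing in `T` for fixed linkage, and
`k_single ≤ k_average ≤ k_complete` at every threshold.

The ARI uses the contingency-table form
`(Σᵢⱼ C(nᵢⱼ,2) − E)/(M − E)` with
`E = Σᵢ C(aᵢ,2) Σⱼ C(bⱼ,2)/C(n,2)` and
`M = (Σᵢ C(aᵢ,2) + Σⱼ C(bⱼ,2))/2`. In the degenerate case `M = E`
(both partitions all-singletons or both one cluster) the index is
defined as 1 when the partitions agree up to relabelling and 0
otherwise, so that "identical partitions score 1" holds everywhere
while "all-singletons versus one-cluster" scores 0. The test suite
verifies the implementation exhaustively against an independent
pair-counting evaluation on all 203 set partitions of 6 items.

Neighbour joining is authored in-package because deterministic
tie-breaking matters for reproducibility: among pairs minimising the
Q-criterion within 1e-12, the lexicographically smallest label pair is
joined, where an internal node inherits the smallest tip label beneath
it. Negative branch-length estimates (possible on non-additive input)
are clamped to zero with a warning. On additive matrices the algorithm
recovers the generating tree exactly (verified on 50 random 8-taxon
trees against a path-length oracle); on arbitrary matrices it matches
the reference NJ implementation's topology.

## Pangenome

Orthologous groups are reciprocal-best-hit components: an ungapped
k-mer-anchored kernel scores protein pairs (identity over the shorter
sequence; coverage = shorter/longer length, guarding against
truncations), edges require identity ≥ 0.5 and coverage ≥ 0.5 by
default plus reciprocal-best status between the two genomes, and OGs
are connected components with unmatched proteins as singletons. This
replaces a full OrthoFinder+MCL stack: absolute OG counts on real data
will differ, but every property the package asserts (pool bookkeeping,
rarefaction behaviour, single-copy-core extraction) is preserved, and
on synthetic data — where gene families are well separated — the
grouping is exact. An OrthoFinder-style `Orthogroups.GeneCount.tsv`
loader provides the fidelity path. The 0.5/0.5 defaults are exposed
because no universal thresholds exist for this step.

Rarefaction draws uniformly random genome orderings (100 replicates by
default, seeded); at prefix size `g` the core is the OG set present in
all first `g` genomes, the pangenome the union, and the new-gene count
what genome `g` adds. Per-position means and standard deviations
summarise the curves, matching the mean-line/sd-shadow presentation
convention for gene-accumulation plots. Within every replicate
`pan(g) = pan(g−1) + new(g)`, pan is non-decreasing and core
non-increasing; `core(N)` and `pan(N)` are permutation-invariant. The
small-table oracle (three genomes with OG sets {1,2,3}, {1,2,4}, {1,5})
is checked against full enumeration of all six orderings.

## Diversity and characters

Faith's PD is the branch-length sum of the minimal spanning subtree of
a tip set. `include_root = TRUE` by default — the path from the spanned
clade to the root counts, matching the default of the classic
community-phylogenetics implementation — and the flag is exposed
because conventions differ. The SES null shuffles taxon labels
uniformly across all tips (the `taxa.labels` model): each of the 999
default randomisations relabels the whole tree once and evaluates every
cluster on it. `SES = (obs − mean)/sd`; a zero-variance null (e.g. a
cluster containing every tip) reports SES 0 with an explicit
`degenerate` flag rather than an error. A one-sided quantile
`p_lower = (#{null ≤ obs} + 1)/(R + 1)` accompanies each SES.

Characters are OG-id sets. A genome's score for a character is the
percentage of the character's OGs present (copy number beyond presence
is ignored), and presence is called at ≥ 50%, boundary inclusive — a
genome carrying exactly half the cluster's genes is called positive.
OG ids missing from the table count as absent everywhere, and an
optional per-character exclusion list operationalises the removal of
non-specific wider groups, for which no algorithmic criterion exists.

## Island synteny

A query cluster is an ordered list of proteins from a source region.
A genome gene matches a query gene at ≥ 70% ungapped identity computed
over the full query CDS length, so a gene truncated to half length can
reach at most 50% and never matches. A locus requires at least half the
query genes matching as a colinear run: same replicon, at most
`max_gene_gap = 5` intervening genes, one strand, query order preserved
forward or reversed (fixing the locus orientation). The ≥50%/gap-5
colinearity rule is an artifact decision — the source convention pins
only the per-CDS identity threshold and the flank window — and both
knobs are exposed. Flank extraction returns up to 70 kb (default) per
side, truncated at replicon ends, reverse-complemented and swapped for
minus-orientation loci so flanks always read in the query's
orientation. Whole-cluster nucleotide identity reuses the fragment
kernel (`100·Σident/Σlen`, 0 with no fragments; symmetric, 100
diagonal), and the cluster protein tree concatenates matched proteins
in query gene order (gap blocks for absent genes), computes p-distances
over mutually non-gap positions (distance 1 when two loci share no
scored position) and applies the package's NJ — a distance surrogate
for a maximum-likelihood cluster tree, adequate for topology-level
statements only.

## The synthetic generator

The generator is the package's ground-truth instrument, not a model of
molecular evolution. It emulates the statistical skeleton that the
delimitation workflow assumes:

* **Species structure.** Genomes fall into `n_species` planted species.
  Planted distances are drawn directly: within-species uniform on
  [0.005, 0.03], between-species uniform on [0.08, 0.14] by default, so
  the partition is recoverable by construction at the 0.036 boundary
  (`is_species_separable()` checks the flag). Defaults mirror the
  motivating subgroup at desk scale: 12 species of unequal sizes
  (8, 6, 5, 5, 4, 4, 3, 3, 2, 2, 2, 2 genomes — 46 in total, the
  largest species dominant as in real collections).
* **Sequences.** Each shared gene cassette (gene + spacer) descends
  from a root ancestor: one mutation pass per species
  (`mutation_rate_between = 0.06` substitutions/site) and one per
  genome (`mutation_rate_within = 0.01`). Pairwise divergence is then
  ≈ 2× the rate, placing sequence-derived identity distances inside
  the planted bands (≈ 0.02 within, ≈ 0.115 between). Distances are
  *also* planted directly so clustering tests do not depend on the
  estimator's fidelity; both channels are exposed.
* **Gene content.** Three pools: a core pool (30 OGs) in every genome,
  a species pool (8 OGs) per species, and a fixed number of
  strain-private genes per genome (2), giving Heaps-like new-gene
  behaviour at exactly the configured private rate. Genes are forced
  ORFs (ATG + non-stop codons, length a multiple of 3, 300 bp default)
  so FASTA, GFF3 and proteome stay mutually consistent; substitutions
  may create in-frame stops, which translation retains as `*`.
* **The island.** `island_gene_count` genes (8, after the eight-gene
  toxin cluster of the motivating system), contiguous and
  strand-consistent, with conserved flanks (2 kb at desk scale standing
  in for the 70 kb real-data window), carried by 9 of the 12 default
  species. Island genes and flanks diverge between species at
  `island_mutation_scale = 0.25` times the background rate, modelling a
  recently acquired, strongly conserved genomic island — across real
  island-bearing strains the cluster retains high nucleotide identity
  and full-length protein homology, and a background-rate island would
  contradict that observed conservation.
* **Determinism.** One integer seed fixes every draw; equal
  configurations produce byte-identical collections, and all stage
  seeds in the pipeline derive from the master seed.

What passing tests on this generator establish: the estimators and the
delimitation logic are correct on inputs satisfying their assumptions
(separated species, well-separated gene families, strand-consistent
homology, no rearrangement within cassettes). What they do not
establish: robustness to indels, codon bias, horizontal transfer
between species, paralogy, assembly fragmentation or contamination —
none of which the generator simulates. Real-data absolute values (OG
counts, distance scales) will differ from any simplified kernel; the
loader interfaces exist precisely so published matrices and OG tables
can replace the in-package kernels.

## Numerical choices and problem sizes

Floating-point ties in the scan and in NJ are resolved within 1e-12;
dendrogram cuts add 1e-12 to the threshold to keep equality merges
inclusive; distance matrices are validated symmetric within 1e-12 with
zero diagonal; the TSV writer rounds at 1e-6 and the reader
re-symmetrises. Degenerate inputs are defined, not errors: empty match
sets give distance 1, zero-variance SES nulls give flagged 0, degenerate
ARI cases are scored by identity-up-to-relabelling.

The test suite runs on deliberately small problem sizes — collections of
6–46 genomes, 8-taxon trees for the NJ oracle, 6-item partitions for the
exhaustive ARI check, 300 bp genes — chosen so the full suite and the
end-to-end pipeline complete in minutes while still exercising every
code path at the sizes where exhaustive and closed-form oracles are
available.

## Limitations

The fragment kernel is forward-strand, ungapped and seed-exact; it is
not a replacement for a full aligner on diverged or rearranged real
genomes. The RBH orthology has no MCL refinement and will split or lump
differently from graph-clustering pipelines on real proteomes. The NJ
surrogate carries no bootstrap support and replaces maximum-likelihood
trees only at the topology level. The dDDH far-anchor default is an
artifact choice; users matching a specific published calibration should
supply their own anchors.
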