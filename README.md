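# phylopan

Species delimitation and pangenome dynamics for bacterial genome
collections.

`phylopan` re-implements, as a tested and reusable R pipeline, the
comparative-genomics workflow used to resolve species inside a bacterial
phylogenomic subgroup (the motivating system is the *Pseudomonas
protegens* subgroup) and to characterise the resulting species clusters:

* **Intergenomic distances.** A GBDP-style fragment-match kernel
  (exact-seed, ungapped X-drop extension, greedy non-overlap trimming)
  turns genome pairs into distances via coverage- or identity-based
  formulas, with conversion between distance *d* and digital DNA–DNA
  hybridization, `dDDH(d) = 100 / (1 + exp(a + b log d))`, calibrated so
  that `dDDH(0.036) = 70%` — the conventional same-species boundary. A
  loader for externally computed distance matrices (TSV or PHYLIP) is the
  fidelity path for published distance tables.
* **Species delimitation.** Hierarchical clustering across the three
  linkages `F = 0 / 0.5 / 1` (single / average / complete) over a
  threshold grid `T = 0 … max(d)` in steps of 0.0005, scored against the
  dDDH-70% reference partition by the adjusted Rand index
  `ARI = (Σᵢⱼ C(nᵢⱼ,2) − E) / (M − E)`; plus Saitou–Nei neighbour
  joining with deterministic tie-breaking for the phylogenomic tree.
* **Pangenome.** Reciprocal-best-hit orthologous groups from proteomes
  (or an imported OrthoFinder-style count table), and rarefaction of the
  core-genome, pangenome and new-gene curves over random genome
  orderings (default 100 replicates), with single-copy-core extraction.
* **Diversity and characters.** Faith's phylogenetic diversity per
  species cluster with a 999-shuffle tip-label null
  (`SES = (PDobs − mean(PDnull)) / sd(PDnull)`), and presence scoring of
  multi-gene characters (biosynthetic/toxin clusters) under the
  inclusive ≥ 50% rule.
* **Island synteny.** Location of a multi-gene toxin-island analogue by
  full-length 70% amino-acid identity and colinearity, flank extraction
  (default 70 kb window), pairwise whole-cluster nucleotide identity and
  a concatenated-protein NJ tree.
* **Synthetic truth.** A seeded generator plants species structure
  (within-species distances below 0.036, between-species above), a
  three-pool gene model (core / species / strain-private) and a
  contiguous island with conserved flanks, so every stage can be tested
  against known ground truth.

## Worked example

```r
library(phylopan)

col <- simulate_collection(simulation_config(seed = 1))
col
#> <synthetic_collection> 46 genomes in 12 planted species; 226 OGs; island in 35 genome(s)

scan <- delimit_species(col$planted_distances)
glance(scan)
#> # A tibble: 1 × 7
#>       F      T     k   ari n_genomes   step T_ref
#>   <dbl>  <dbl> <int> <dbl>     <int>  <dbl> <dbl>
#> 1     0 0.0285    12     1        46 0.0005 0.036
```

The scan recovers exactly the 12 planted species (`k = 12`) in perfect
agreement with the dDDH-70% reference partition (`ARI = 1`), with the
earliest (smallest-`T`) maximum reached by single linkage. Rarefaction
and per-cluster diversity follow the same grammar:

```r
rarefy(col$planted_og_table, replicates = 100, seed = 1)
#> <rarefaction> 46 genomes, 100 replicates; core(N)=30, pan(N)=226

tree <- neighbour_joining(col$planted_distances)
head(ses_pd(tree, scan$best_partition, randomisations = 999, seed = 1), 3)
#> # A tibble: 3 × 8
#>   cluster n_tips pd_obs null_mean null_sd   ses p_lower degenerate
#>   <chr>    <int>  <dbl>     <dbl>   <dbl> <dbl>   <dbl> <lgl>
#> 1 1            8 0.0961     0.344  0.0425 -5.83   0.001 FALSE
#> 2 10           2 0.0657     0.107  0.0131 -3.18   0.053 FALSE
#> 3 11           2 0.0664     0.107  0.0135 -2.99   0.062 FALSE
```

The core genome settles at the planted core-pool size (30 OGs), the
pangenome reaches the full planted OG pool (226), and every species
cluster has a strongly negative SES — its members span far less branch
length than random tip sets of the same size, as expected for planted
clades. `score_characters()` with the island spec calls the island
present in exactly the 35 genomes of island-bearing species, and

```r
ddh_from_distance(0.036)
#> [1] 70
```

confirms the calibration anchor. Each result type has `tidy()`,
`glance()` and `autoplot()` methods; `run_pipeline(pipeline_config())`
chains all stages and writes TSV/newick outputs plus a summary report.

## Documentation

The methods vignette (`vignettes/phylopan-methods.Rmd`) describes the
models, the generator's assumptions, parameter defaults and units,
numerical choices and known limitations.
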