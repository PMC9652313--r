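# crossneuro

Cross-species analysis of GABAergic (inhibitory) neuron cell types from
single-nucleus RNA-seq counts: cell-type conservation scoring between
species, supervised neighbor-voting AUROC for gene sets, pseudocell
co-expression modules with disease-risk-gene enrichment, and regulon
activity grouping — validated end to end on synthetic multi-species data
with planted ground truth.

## Who this is for

Comparative single-cell transcriptomics: you have count matrices from two
or more species with cell annotations (species, batch, subtype, condition),
a one-to-one ortholog table, and gene sets (risk genes, regulons), and you
want quantitative answers to "which subtypes are conserved?", "which gene
sets identify a cell type across batches?", "which co-expression modules
carry disease risk genes?" and "which regulatory programs are shared across
species?".

## The statistics at the core

* **Conservation score.** After homolog mapping, per-subtype subsampling
  (n = 100), reciprocal-PCA anchor integration and joint clustering into
  k ≥ 31 clusters, the conservation of a query subtype A against a
  reference subtype B is

  `overlap(A, B) = Σ_c min(p_A(c), p_B(c))  =  1 − TV(p_A, p_B)`,

  the summed minimum of their cluster-proportion vectors, i.e. one minus
  the total-variation distance; it ranges from 0 (disjoint) to 1
  (identical cluster usage).
* **Neighbor-voting AUROC** (supervised MetaNeighbor protocol): Spearman
  similarity on a gene-set submatrix, rank-standardised to (0, 1]; cells of
  a held-out batch are scored by degree-normalised votes from the other
  batches and the AUROC is the Mann–Whitney U statistic scaled to [0, 1];
  20 cells per cluster, 10 iterations, mean ± sd.
* **Topological overlap modules**: 10-cell pseudocells per
  subtype × condition × batch stratum, MAD ≥ 0.1 gene filter, adjacency
  `a_ij = |cor(i,j)|^6`, TOM
  `ω_ij = (Σ_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 − a_ij)`,
  average-linkage clustering of `1 − ω`, minimum module size 10, eigengene
  merge at r ≥ 0.75, kME reassignment.
* **Risk enrichment**: upper-tail hypergeometric probability
  `P(X ≥ k)` for `X ~ Hypergeom(N = 20000, M, n)`, log-space tail sum;
  tiers `*` (0.01–0.05), `**` (0.001–0.01), `***` (≤ 0.001).
* **Regulon activity**: AUCell-style area under the target-recovery curve
  in the top 5% of each cell's expression ranking; two-component Gaussian
  mixture binarisation; activation fractions per species × subtype;
  k-means grouping with k = 8.

The package also contains the data layer (Matrix Market bundles with TSV
sidecars, GMT gene sets, one-to-one homology tables) and a
negative-binomial simulator that plants conserved and species-private
subtypes, batch effects, modules, regulons and a disease condition, so
every claim the pipeline makes can be checked against known truth.

## Worked example

```r
library(crossneuro)

# simulate the default two-species study and score conservation:
# 4 conserved GABAergic subclasses + the mouse-private Meis2 type,
# 200 cells per subtype, 2 batches per species
res <- experiment_conservation(seed = 1)
round(res$overlap, 2)
#>       PVALB  SST LAMP5  VIP
#> PVALB  0.96 0.00  0.01 0.00
#> SST    0.01 0.91  0.01 0.01
#> LAMP5  0.01 0.00  0.92 0.00
#> VIP    0.01 0.00  0.01 0.86
#> Meis2  0.04 0.01  0.02 0.01
```

Rows are mouse subtypes, columns human subtypes. The four conserved
subclasses pair with their homonymous human subtype at overlap 0.86–0.96
(they occupy the joint clusters in matching proportions), while the
mouse-private Meis2 type overlaps no human subtype above 0.04 — the
integration keeps a population with no cross-species counterpart separate
instead of forcing it onto the nearest human cluster.

```r
mn <- experiment_metaneighbor(seed = 1)
c(marker = mn$marker$mean, random = mn$random$mean)
#>   marker   random
#> 0.978    0.482
```

The inhibitory-program gene set (GAD markers plus subtype marker blocks)
lets inhibitory cells find each other across batches almost perfectly
(AUROC 0.978 ± 0.027 over 10 iterations), while a size-matched random set
performs at chance.

The numbered scripts under `analysis/` run the full study —
`01_simulate.R` … `06_validation.R` — writing MTX bundles, conservation and
correlation matrices, AUROC tables, module/enrichment/DEG tables, regulon
profiles and a cross-seed validation summary under `results/`.

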