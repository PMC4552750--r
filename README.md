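# regpart

Regularity partitions for functional brain-connectivity networks.

## What this is for

fMRI task experiments yield a BOLD time series per voxel. A common way to
study cortical organization is to build a graph from these series — voxels
as vertices, an edge wherever the Pearson correlation between two voxels is
among the strongest 10% of all pairs — and then to ask how the edges of that
graph are organized.

`regpart` answers that question through pseudo-randomness. A bipartite pair
of vertex sets (X, Y) is **ε-regular** when every pair of subsets A ⊂ X,
B ⊂ Y with |A| > ε|X|, |B| > ε|Y| satisfies

```
|d(X,Y) − d(A,B)| < ε,   d(X,Y) = e(X,Y) / (|X||Y|)
```

i.e. the pair spreads its edges the way a random bipartite graph would, at
every admissible scale. The package implements a practical Szemerédi-type
partitioning algorithm that splits a graph's vertex set into equal-size
clusters (plus a small "junk" holding set P0) such that almost all cluster
pairs are ε-regular, using verified certificates of irregularity to drive
iterative refinement. On top of the partition it computes:

* **triangle lower bounds** for cluster triples,
  (1−2ε)(α−ε)(β−ε)(γ−ε)|X||Y||Z|, sampled over random triples;
* the **partition index** ind(P) = k⁻² Σ_{i≠j} d(V_i,V_j)², the expected
  between-cluster edge mass;
* Newman–Girvan **modularity** MOD(P) = Σ_i [l_i/L − (d_i/2L)²];
* the **modified co-affinity matrix** — the probability that two vertices
  share a cluster across the family of low-modularity partitions produced
  during refinement — with reverse Cuthill–McKee reordering to expose
  block-diagonal organization;
* a **reduced-graph pipeline**: one node per cluster with density weights,
  normalized-cut spectral clustering of the reduced graph, label map-back,
  junk redistribution, and Hungarian-matched accuracy against ground-truth
  labels, compared head-to-head with Ncut applied directly to the full
  graph.

Synthetic generators (stochastic block models, random bipartite graphs,
ROI-structured voxel time series with analytically known correlations) make
every stage testable with known ground truth. Audience: anyone analyzing
connectivity-style graphs who wants pseudo-randomness structure rather than
(or alongside) community structure — the method is graph-generic even
though its motivation is neuroimaging.

## Worked example

```r
library(regpart)

## planted 4-block graph, 400 vertices, p_in = 0.5, p_out = 0.05
sbm <- generateSBM(400, 4, pIn = 0.5, pOut = 0.05, seed = 1)
numEdges(sbm$graph)
#> [1] 12948

hist <- regularityPartition(sbm$graph,
                            regularityParams(eps = 0.1, l = 4, h = 5),
                            seed = 1)
hist
#> PartitionHistory: 1 round(s), halt = regular; final: 4 clusters of size 100

partitionMetrics(sbm$graph, hist, reps = 10, seed = 1)
#>   round n_clusters cluster_size junk_size triangle_bound_min
#> 1     1          4          100         0                  0
#>   triangle_bound_mean triangle_bound_max  index modularity irregular_pairs
#> 1                   0                  0 0.0019     0.5201               0
```

The sequential initial partition lines up with the planted blocks, the
cross-block pairs (density ≈ 0.05) are declared 0.1-regular, and the run
halts in one round with zero irregular pairs. The triangle bound is 0
because every cross-cluster density is below ε — the clamped bound is
vacuous, as it should be for a graph whose triangles live inside blocks.
The index (0.0019 ≈ mean squared cross density) and the modularity of the
block partition (0.52) summarize the same structure from two angles.

```r
cp <- comparePipelines(sbm$graph, sbm$labels,
                       regularityParams(eps = 0.1, l = 4, h = 5),
                       nClusters = 4, seed = 1)
c(reduced = cp$reducedNcutAccuracy, direct = cp$normalNcutAccuracy)
#> reduced  direct
#>       1       1
```

Both the reduced pipeline (Ncut on 4 cluster-nodes) and direct Ncut on all
400 vertices recover the planted blocks perfectly: the reduction preserved
the information at a fraction of the eigen-decomposition cost.

Starting from time series instead of a graph:

```r
am <- generateRoiTimeSeries(120, 4, 200, rhoWithin = 0.6, seed = 2)
g  <- thresholdAdjacency(pearsonCorrelationMatrix(am), keepFraction = 0.10)
attr(g, "threshold"); numEdges(g)
#> [1] 0.616637
#> [1] 714
```

714 = floor(0.10 × 120·119/2) edges survive, above an adaptive correlation
threshold of 0.617.

A thin command-line wrapper over the same functions lives in
`inst/scripts/regpart.R` (subcommands `simulate`, `connectivity`,
`partition`, `metrics`, `coaffinity`, `reduce-cluster`, `evaluate`).

See `vignettes/regularity-partitioning.Rmd` for the model, the certificate
search design, parameter semantics and known limitations.

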