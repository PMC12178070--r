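# scprior

Prior-informed batch integration and cell-type label harmonization for
multi-batch single-cell expression data.

## What problem this solves

Meta-analyses of public single-cell RNA-seq data face two entangled
obstacles: every dataset carries its own batch effect, and every dataset
names its cell types in its own dialect ("T cell", "T lymphocyte",
"CD4+ T", the occasional outright mislabel). Standard integration methods
throw the annotations away and align on expression alone. `scprior` instead
treats annotations as *soft prior knowledge*: the textual similarity of
cell-type names — a label-by-label matrix `M` of text-embedding cosines,
floored at 0.05 — modulates the expression-based computations without ever
overriding them.

Three pieces implement the idea:

- **Prior-weighted panorama integration.** Batches share a truncated-SVD
  embedding; mutual nearest neighbors are searched under weighted distances
  `d'_ij = d_ij / M_IJ`, and each matched pair's displacement gains a
  group-cohesion correction
  `Bias'_ij = Bias_ij + M_IJ (v_i − v_I − v_j + v_J)`
  built from the type centroids `v_I`, `v_J`, so cells of consistently
  annotated types keep their relative position inside the target cluster.
- **Uncertainty-modulated harmonization.** Cells are softly assigned to
  another dataset's types through `S = exp(−D / mean D)`; each cell's
  normalized entropy `α = H(p)/log K` gates how much the label prior blends
  in: `S'_iJ = β[(1−α_i) S_iJ + α_i M_IJ] + (1−β) S_iJ` (β = 0.1). Majority
  rules on the resulting assignment fractions classify type pairs as
  one-to-one / split / merge / novel and union them into alignment groups.
- **The two-step pipeline.** Harmonize first, rebuild `M` on the harmonized
  labels (grouped aliases now share similarity 1), then integrate with the
  rebuilt prior. Consensus cluster labels come from fuzzy majority voting
  (near-synonymous labels pool their votes). A corruption-experiment
  harness replays fuzzy / unbiased / biased mis-annotation designs and
  scores robustness on the corrupted cells only.

Around the core sit a deterministic offline label-embedding provider
(character n-gram hashing — fully reproducible, no network), an
ontology-Jaccard annotation-accuracy module (OBO reader, reflexive
ancestor sets), a mock-annotator processing pipeline (QC → preprocess →
cluster-to-target-k → annotate → re-annotate, fully logged), integration
metrics (KMeans ARI, silhouette, iLISI, kBET-style acceptance; overall =
0.4·batch + 0.6·bio), and a negative-binomial multi-batch simulator that
makes everything testable offline.

## Worked example

Three simulated batches share six pancreas-style cell types under a
moderate batch effect; the second batch annotates every type with a plural
alias.

```r
library(scprior)

cfg <- sim_config(n_batches = 3, cells_per_batch = 400, n_genes = 150,
                  batch_effect_sd = 0.5, seed = 42)
batches <- generate_batches(cfg)
batches[[2]]$label_given <- paste0(batches[[2]]$label_given, "s")

res <- two_step_integrate(batches, knn = 20, seed = 1)
print(res$harmonization)
#> harmonization: 6 groups over 18 (dataset, type) nodes
#>   [1] acinar cell = acinar cells
#>   [2] alpha cell = alpha cells
#>   [3] beta cell = beta cells
#>   [4] delta cell = delta cells
#>   [5] ductal cell = ductal cells
#>   [6] endothelial cell = endothelial cells
```

Every alias lands in the group of its original type, so the rebuilt prior
gives the pair similarity 1 and the integration treats them as one
population. Benchmarking the embedding before and after:

```r
truth <- unlist(lapply(batches, `[[`, "label_true"))
batch <- unlist(lapply(batches, `[[`, "batch"))
pre   <- do.call(rbind, lapply(res$reduced, `[[`, "coords"))
benchmark_embedding(pre, truth, batch, seed = 1)
#> metrics_report: kmeans_ari=0.268 silhouette=0.513 ilisi=0.504 kbet=0.045 | batch=0.275 bio=0.390 overall=0.344
benchmark_embedding(res$embedding$coords, truth, batch, seed = 1)
#> metrics_report: kmeans_ari=0.877 silhouette=0.514 ilisi=0.965 kbet=0.940 | batch=0.953 bio=0.696 overall=0.798
```

Batch mixing (iLISI 0.50 → 0.97, kBET 0.05 → 0.94) and type recovery
(KMeans ARI 0.27 → 0.88) both improve; the overall score rises from 0.34
to 0.80.

A thin command-line wrapper exposes the same operations
(`exec/scprior simulate | process | integrate | harmonize | two-step |
vote | corrupt | experiment | benchmark`); dataset directories are
MatrixMarket triples (`matrix.mtx`, `genes.tsv`, `metadata.tsv`).

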