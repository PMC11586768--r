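# parties

Partition-level integration of multi-omics data with diffusion-enhanced
similarities — an R package for disease subtyping.

## What it is for

Given several omics data types measured on the same samples (expression,
methylation, somatic mutation counts, …), the goal is a single clustering of
the samples into molecular subtypes. Two obstacles are built into this
problem: sample-similarity matrices computed from thousands of mostly
uninformative features are noisy, and different data types can carry
*different* cluster structures that common-structure integration methods
average away. This package is for analysts who want an integration that
first denoises each data type's similarity and then combines
**partition-level** information — what each data type says about how samples
group — rather than the raw similarities themselves.

## The method

Per data type *s* (features standardized to mean 0, SD 1):

1. **Adaptive Gaussian kernel.**
   K\_s(i,j) = exp(−‖x\_i−x\_j‖² / (2 ε(i,j)²)) with ε(i,j) = μ\_i + μ\_j,
   where μ\_i is the mean distance from sample *i* to its k nearest
   neighbours (default k = n/4).
2. **One-hop diffusion.** With the row-stochastic kNN transition matrix
   P\_s, the enhanced kernel is K\_enh = (K Pᵀ + P K)/2 — each similarity is
   averaged over neighbourhoods, reducing noise.
3. **Partition-level integration.** Minimize over simplex-constrained local
   similarities Z\_s, orthonormal per-type bases F\_s (n × C\_s) and an
   orthonormal consensus basis Y (n × C):

   Σ\_s { ⟨D\_enh, Z\_s⟩ + β‖Z\_s‖² + γ( tr(F\_sᵀ(I−Z\_s)F\_s) +
   w\_s‖YYᵀ − F\_sF\_sᵀ‖² ) },

   with weights w\_s ∝ 1/(2‖YYᵀ − F\_sF\_sᵀ‖) re-learned each iteration, so
   concordant data types count more. Final labels: k-means on the rows of Y.

Cluster numbers C\_s are selected by the eigengap criterion on a
kNN-localized similarity; the package also ships the simulation designs used
to benchmark the method, NMI evaluation utilities, TSV/CSV matrix I/O and a
command-line interface.

## Worked example

Three simulated data types that deliberately disagree: type 1 separates
clusters {1,2} from {3,4}, type 2 additionally splits 1 from 2, type 3
additionally splits 3 from 4. No single data type can recover all four
clusters; the integration can.

```r
library(parties)

sim <- simulate_preset("setting3", replicate = 1, seed = 11)
fit <- parties(sim$data, consensus_clusters = 4)
fit
#> Partition-level integration fit
#>   samples: 200  data types: 3  consensus clusters: 4
#>   per-type clusters: 2, 2, 2
#>   weights: data1=0.333, data2=0.333, data3=0.333
#>   converged after 3 iterations (subspace change 6.46e-09)
#>   cluster sizes: 50, 50, 50, 50

nmi(fit$labels, sim$labels)
#> [1] 1
```

The eigengap criterion assigns each data type two clusters — each type
really does carry only a two-way split — yet the consensus basis combines
the three different splits into the correct four subtypes (NMI = 1 against
the truth). `tidy(fit)` returns the per-sample assignments,
`glance(fit)` one row of convergence diagnostics, `weight_table(fit)` the
learned data-type weights, and `autoplot(fit)` the loss trace.

For real data:

```r
mats <- list(
  expr = read_feature_matrix("expr.tsv"),
  meth = read_feature_matrix("meth.tsv"),
  mut  = read_feature_matrix("mut.tsv")
)
fit <- parties(harmonize_samples(mats), consensus_clusters = "auto")
tidy(fit)
```

or from a shell:

```sh
Rscript inst/cli/parties.R fit \
  --data expr=expr.tsv --data meth=meth.tsv --data mut=mut.tsv \
  --clusters auto --seed 1 --out results/
```

which writes `labels.tsv`, `eigengap.json`, `loss_trace.csv`,
`weights.json` and a JSON run manifest. `simulate` and `benchmark`
subcommands generate preset data and tidy NMI comparison tables.

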