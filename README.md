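# granulaR

Temporal diversity and co-occurrence network analysis for parallel
bioreactor microbiomes.

## The problem

Wastewater-treatment microbiomes are tracked by monthly 16S rRNA
amplicon sequencing of parallel reactors — for example two aerobic
granular sludge (AGS) reactors and a conventional activated sludge
(CAS) line treating the same municipal wastewater. Answering the
ecological questions such a design poses requires a chain of
specialised statistics, each easy to get subtly wrong:

* **Alpha diversity** as Hill numbers
  `qD = (Σ p_i^q)^(1/(1−q))` (q = 0 richness, q = 1 exponential
  Shannon), on rarefied counts.
* **Beta diversity** as Hill-framework dissimilarity: `β = γ/α ∈ [1,2]`
  normalised to `[0,1]` via local (Sørensen-type, `1 − C_q2`) or
  regional (Jaccard-type, `1 − U_q2`) overlap, with PCoA ordination.
* **Succession**: rate of change (dissimilarity per day between
  consecutive samples), moving-window time-gap dissimilarity curves
  whose mid-period peak reveals seasonal periodicity, and same-day
  cross-reactor comparisons.
* **Consensus co-occurrence networks**: SparCC-type compositional
  correlations (log-ratio variation matrix `t_ij = Var ln(f_i/f_j)`,
  basis variances from `[(D−2)I + J] ω² = t·1`, Dirichlet resampling,
  iterative strong-pair exclusion, 1000-permutation p-values) crossed
  with Spearman correlations under Benjamini–Hochberg FDR 0.05; an edge
  requires ρ > 0.5 and significance in **both** methods, positive only.
  Modules by Clauset–Newman–Moore greedy modularity
  (`Q = Σ_c [e_c/m − (d_c/2m)²]`), with "major" modules holding ≥ 10
  ASVs and ≥ 2% relative abundance in some sample.
* **Functional guilds** (AOB, NOB, PAO, GAO): abundance trajectories,
  temperature correlations, date-paired reactor tests (t or exact
  signed-rank), and guild-by-module cross-tabulation — the footprint of
  functional redundancy.

`granulaR` packages this chain behind Bioconductor-style S4 classes
(`AmpliconExperiment` extends `SummarizedExperiment`), together with a
seeded synthetic generator of parallel-reactor time series with planted
seasonal/trend modules, twin and divergent reactors, and guild-labelled
genera — so every estimator is testable against ground truth.

## Worked example

```r
library(granulaR)

ae <- simulateReactorSeries(reactorSimConfig(seed = 42))
rare <- rarefyCounts(ae, seed = 43)
filt <- prevalenceFilter(rare)
meta <- sampleMetadata(filt)

d <- dissimilarityMatrix(filt, q = 1)
#> HillDissimilarity: 57 samples, q = 1, variant = local
sameDayDissimilarity(d, meta, "AGS1", "AGS2")
#>         mean         sd  n
#> 1 0.08511347 0.01160954 19
sameDayDissimilarity(d, meta, "AGS1", "CAS")
#>       mean         sd  n
#> 1 0.377402 0.03784718 19
```

The two granular twins differ by only ~0.085 (q = 1 dissimilarity) on
any given day, while granular vs floc communities sit at ~0.38 — the
reactor configuration, not time, is the dominant axis of variation.

```r
sel <- meta$sample[meta$reactor == "CAS"]
curve <- timeGapCurve(dissimilarityMatrix(relativeAbundance(filt)[, sel],
                                          q = 1), meta, "CAS")
peakGap(curve)
#> [1] 222.1
```

Mean dissimilarity between CAS samples peaks at a time gap of ~222
days — near half the annual period, the signature of seasonal
periodicity.

```r
sub <- prevalenceFilter(filt[, sel])
obs <- sparccCorrelations(sub, sparccParams(seed = 44))
obs <- permutationPvalues(sub, obs, n_perm = 1000, seed = 45)
spear <- spearmanCorrelations(relativeAbundance(sub))
net <- detectModules(consensusEdges(obs, spear))
net
#> ConsensusNetwork: 276 nodes, 4606 edges, 4 modules, Q = 0.526
mm <- majorModules(net, relativeAbundance(sub))
mm[mm$major, ]
#>   module n_asvs max_abundance major
#> 1      1     45     0.3038935  TRUE
#> 2      2     64     0.6468658  TRUE
#> 3      3     31     0.5717601  TRUE
#> 4      4    136     0.8901609  TRUE
```

276 of the filtered ASVs form a consensus network of 4,606 positive
edges that decomposes into 4 major modules (modularity Q = 0.53);
`attr(mm, "trajectories")` holds each module's per-sample summed
abundance, and `guildModuleCrosstab()` shows how guild members spread
across modules. `runPipeline(pipelineConfig(...))` chains all stages
and writes every table as TSV plus a `manifest.json`.

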