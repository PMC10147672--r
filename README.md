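# founderscape

Population-genetic analysis of founder populations through
identity-by-descent (IBD) segment sharing, modelled on the study design used
for isolated settler populations such as Newfoundland & Labrador: coastal
communities founded a dozen generations ago by settlers from two diverged
source populations, with religious denomination tracking settler origin.

Real cohorts of this kind are access-restricted, so the package ships a
forward-in-time founder-colony simulator that emits every input the analysis
consumes — phased VCF, IBD/HBD segment tables, a genetic map, sample
metadata with grandparental birthplaces — together with complete ground
truth (pedigree, founder-haplotype mosaics, true ancestry fractions). Every
analysis stage is therefore testable against known truth.

## What it computes

* **IBD network structure.** Individuals are nodes, edge weights are total
  shared IBD in cM; edges above 142 cM are excluded as familial. Community
  detection is three rounds of hierarchical Louvain clustering
  (`build_graph()`, `hierarchical_cluster()`).
* **NNLS ancestry profiles.** Each target's band-limited (3–15 cM) sharing
  profile `x` over source individuals is modelled as a non-negative mixture
  of the sources' own profiles: `beta = argmin_{b >= 0} ||x - t(Y) b||^2`,
  normalised to sum to one, then aggregated to source clusters and regions
  (`estimate_ancestry()`, plus an unsupervised cluster-mixture variant).
* **Founder-effect statistics.** Within-cluster IBD summaries, runs of
  homozygosity with length bins `[4,8) [8,12) [12,20) [20,300)` cM,
  `F_ROH` (genome fraction in ROH > 1.5 Mb), 6-SD outlier exclusion and
  consanguinity flags (> 50 cM of genome in ROH > 20 cM each).
* **Drift statistics.** Patterson's
  `D = sum((pW-pX)(pY-pZ)) / sum((pW+pX-2 pW pX)(pY+pZ-2 pY pZ))` with a
  5 cM block jackknife, in the source-affinity arrangement
  `D(outgroup, cluster; source1, source2)` and the colony-drift arrangement
  `D(outgroup, cluster; source, random colony)`; Hudson's ratio-of-averages
  FST.
* **Geography and denomination.** Plain Euclidean grandparental distances in
  degrees, the mean-distance <= 0.5 cohort filter, cluster x denomination
  chi-squared tests with simulated p-values, and the IBD-versus-distance
  same-denomination test.

## Worked example

```r
library(founderscape)

cfg <- sim_config(seed = 1)          # 4 demes, founded 12 generations ago
sim <- simulate_founder_colony(cfg)  # ~560 samples, truth included
sim
#> synthetic founder-colony dataset
#>   ...
#>   561 present-day samples (391 colony, 120 reference, 50 outgroup)
#>   true IBD segments >= 1.000002 cM: 1019588 | HBD: 2609 | sites: 8000

grp     <- setNames(sim$samples$group, sim$samples$id)
colony  <- sim$samples$id[sim$samples$role == "colony"]
refs    <- sim$samples$id[sim$samples$role == "reference"]

fit <- estimate_ancestry(sim$ibd, colony, refs,
                         source_clusters = grp[refs],
                         target_clusters = grp[colony])
fit
#> IBD-NNLS ancestry fit: 391 targets x 120 sources (band 3-15 cM)
#>   target-cluster mean source-cluster proportions:
#>              S1    S2
#> Avalon    0.843 0.157
#> Burin     0.584 0.416
#> NotreDame 0.102 0.898
#> Trinity   0.269 0.731
```

The demes were founded with true S1 (Irish-like) fractions 0.9 / 0.7 / 0.1 /
0.3; the fitted cluster means recover the mixture proportions and their rank
order from IBD sharing alone. `run_pipeline()` executes the whole chain
(simulate → network → ancestry → stats → drift → geo) into an output
directory with a checksummed, seed-reproducible manifest.

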