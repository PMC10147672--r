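---
title: "Methods: IBD networks, NNLS ancestry and founder-effect statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: IBD networks, NNLS ancestry and founder-effect statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its models and the design choices
behind them. It states no empirical numbers beyond what the test suite and
`scripts/acceptance.R` themselves compute.

## The scientific setting

The package targets founder populations of the Newfoundland-and-Labrador
kind: a colony founded roughly a dozen generations ago by settlers from two
diverged source populations, subdivided into coastal communities ("demes" or
bays) that mate largely within themselves, with religious denomination
correlated with settler origin at the community level. Three signatures
organise the analysis: elevated IBD sharing and runs of homozygosity
(founder effect), community structure in the IBD-sharing network, and
allele-frequency drift away from the sources.

## The synthetic founder colony

`simulate_founder_colony()` is first-class, tested code, not a fixture. It
emulates:

* **Two source populations** drifting from a common ancestral frequency pool
  under the Balding–Nichols model (`Beta(p(1-F)/F, (1-p)(1-F)/F)`,
  default divergence `F = 0.02` per source; an outgroup at `F = 0.15`).
  Each source is a finite random-mating pedigree (150 diploids per
  generation, 20 generations) rather than an infinite pool, so present-day
  reference panels genuinely share IBD with the colony through the founding
  bottleneck. Reference individuals are the final source generation and are
  never ancestral to post-founding colonists.
* **Recombination** as Poisson crossovers (mean `length_cM/100` per
  chromosome, positions uniform on the cM axis) with no interference and no
  obligate chiasma — the simplest model consistent with cM semantics. The
  default map is four 100 cM chromosomes at a constant 1 Mb/cM, which keeps
  bp–cM conversions trivially invertible; real maps are accepted at the IO
  boundary.
* **Colonial founding and growth.** Four demes with founder S1 fractions
  0.9/0.7/0.3/0.1, founded 12 generations before present. Founder counts are
  not stated by the source material; 40 diploid founders per deme was fixed
  a priori as a plausible outport scale, and the growth rate defaults to
  `(400/160)^(1/12)` so the colony reaches ≈ 400 individuals today.
  Mating is monogamous within deme (selfing impossible, sib mating
  permitted — sib matings generate the long-ROH consanguinity signal);
  each individual migrates to another deme's mating pool with probability
  0.01 per generation. A deme left without a mating pair is a hard error
  naming the deme and generation, not a silent recovery: tiny-founder
  configurations are expected to die out under many seeds, and sweep
  analyses select seeds under which all configurations survive.
* **Denomination and geography.** Denomination is a noisy function of deme
  (fidelity 0.9), not of individual ancestry — religion proxies ancestry at
  community level only. Grandparental birthplaces are the grandparent's
  natal-deme centroid plus Gaussian jitter (0.05°).

Ground truth is exact: every haplotype is a mosaic of founder-haplotype
labels tiling the map, so true IBD is interval intersection of labels
(`extract_true_ibd()`, with a brute-force grid scan as its test oracle),
true ancestry is the cM fraction carried on S1-labelled founder haplotypes,
and genotypes follow deterministically from founder alleles
(identity-by-descent implies identity-in-state; there is no mutation,
genotyping-error or phase-error model, since segment detection is outside
the package's scope). All randomness flows from one seed through fixed
sub-streams (`derive_seed()`), so every artefact is byte-reproducible.

What passing tests on this generator do **not** show: robustness to segment
detection error, phasing switch error, array ascertainment, or realistic
human recombination-map heterogeneity. The generator validates the
statistical machinery, not the upstream detection tools.

## Segment preprocessing

Segment tables use a refinedIBD-style 9-column dialect; bp coordinates are
interpolated linearly between genetic-map anchors, and positions outside the
map are errors, not clamps. Fragments of a putatively larger segment
separated by at most 0.6 cM are merged transitively before analysis (the
merged length spans the union). The pipeline applies merging before both
the 142 cM network filter and the 3–15 cM ancestry band; length-band
filters are strictly exclusive at both edges, and boundary behaviour
(exactly 3 cM excluded, exactly 142 cM kept) is pinned by tests.

## IBD network and hierarchical Louvain

Nodes are individuals; an edge weight is the pair's total shared cM (all
haplotype combinations, segments > 1 cM). Totals strictly above 142 cM are
excluded as familial rather than population signal. Louvain modularity
maximisation (resolution 1.0, exposed as an argument) is run three times
hierarchically: each community with ≥ 10 members is re-clustered on its
induced subgraph; smaller communities pass through unchanged. Louvain is
visitation-order dependent, so node order is pinned (sorted ids, then a
seeded shuffle) and identical input plus seed reproduces the hierarchy
exactly. Clusters are named by hierarchy path and size rank (`"2.1"` is the
largest child of the second-largest level-1 community), since geographic
naming is a manual, presentation-level step.

A caution observed in simulation and worth stating as a design limitation:
when a deme is already isolated as its own level-1 community, the level-2
re-clustering of that community resolves genuine *family* substructure
(modularity has no stopping rule short of its optimum), so "demes" are not
guaranteed to be the level-2 stratum of the hierarchy. On a ~400 cM
simulated genome the fixed 142 cM familial threshold also sits much closer
to typical within-deme totals than it does on a ~3,500 cM human autosomal
map. The acceptance script therefore reports deme-recovery ARI at both
levels 1 and 2.

## NNLS ancestry model

For targets `i` and sources `j`, `X[i, j]` is the proportion of target i's
band-limited (3–15 cM, strict) IBD total shared with source j; rows are
normalised by their pre-normalisation sums, which are retained. `Y` is the
same construction among sources with its diagonal (self-sharing) set to
zero and rows renormalised — self-copying is meaningless for an
individual's IBD totals. Each target is fitted independently by
non-negative least squares (`beta = argmin_{b>=0} ||x - t(Y) b||`, solver
tolerance 1e-10, no joint regularisation), and `beta` is normalised to sum
to one. Targets with no qualifying sharing are excluded *and reported*;
an all-zero fit is reported as unresolvable rather than normalised.

Sources are individuals, as the profile definition requires; coefficients
are aggregated to source clusters and then regions after solving, and
per-individual profiles are averaged within target clusters (solving on
cluster-mean profiles is available, but per-individual averaging is the
default because it weights every target equally and keeps exclusions
explicit). The "> 5%" major-contributors view is a reporting filter only,
never applied before aggregation.

The unsupervised variant treats each cluster's member-mean profile over the
other clusters as the response. Here, unlike the individual-level `Y`, a
design cluster keeps its own within-cluster sharing column: sharing among
distinct members of one cluster is real signal, and zeroing it makes the
design singular whenever two reference clusters share no IBD with each
other (which is exact for independently simulated sources).

## Founder-effect statistics

Within-cluster IBD summaries average, per individual, the total cM and
segment count shared with each same-cluster partner in the 3–15 cM band;
pairs that share nothing count as zeros (excluding them would bias isolated
clusters upward), and cluster-level means carry mean ± 1.96 SE intervals
(the interval method is a package choice; the source material shows CIs
without stating one). ROH totals use segments > 1 cM; binned totals use
half-open bins `[4,8) [8,12) [12,20) [20,300)` cM (the upper edge follows
the figure-level definition over a conflicting in-text "[20,200]"; it is an
argument). `F_ROH` is the bp fraction of the genome — the sum of map
spans — covered by ROH longer than 1.5 Mb, keeping the conventional
physical threshold alongside genetic-length bins. Outlier exclusion flags
individuals more than 6 leave-one-out SDs above their cluster's mean total
ROH in a single pass; leave-one-out is required for the rule to behave in
small clusters, where an extreme individual would otherwise inflate the SD
enough to mask itself. Consanguinity is flagged when ROH segments longer
than 20 cM sum to more than 50 cM.

The IBD-versus-distance test ranks cluster pairs by median cross-pair IBD
and median grandparental distance and takes the same-denomination indicator
coefficient from a rank regression, with a one-sided permutation null over
cluster-level denomination labels. With few clusters the permutation space
is coarse (three distinct assignments for two-of-each among four clusters),
so small p-values require a clustering fine enough to give several
same/different-denomination pairs.

## Drift statistics

Patterson's D uses the frequency form
`D = Σ(pW−pX)(pY−pZ) / Σ(pW+pX−2pWpX)(pY+pZ−2pYpZ)` over sites shared by
all four groups, with delete-one block jackknife SEs over contiguous 5 cM
blocks (the block length is a package choice; external tools do not state
theirs). The sign convention is pinned to the formula — `D < 0` means
excess X–Y sharing — and every result carries interpretation text, because
prose and figure captions in this literature routinely disagree about
which sign means which. Sample frequencies are unweighted allele counts.

The colony-drift arrangement `D(outgroup, X; source, random-colony)` draws
500 non-member colony individuals without replacement (seeded; all of them
with a warning when fewer exist). One property deserves emphasis: its
expectation for *any* colony subset X contains the variance of colony-wide
drift, so in a strongly bottlenecked colony even a randomly drawn
pseudo-cluster sits at a large positive baseline. The informative signal is
a cluster's elevation above that shared baseline, not |z| against zero; the
tests assert exactly this (disjoint pseudo-clusters share a common
baseline).

Hudson's FST is the unbiased ratio-of-averages estimator; single-site
estimates may be negative, and the estimator is consistent for the
Balding–Nichols divergence used in simulation (checked at F = 0.01).

## Geography and composition

Grandparental distance is the plain Euclidean distance on decimal degrees —
deliberately not great-circle, because the 0.5° cohort filter is defined on
raw coordinate differences; the degree unit overstates east–west distance
at high latitude, a documented limitation. The mean over all unordered
pairs of located grandparents (up to six; the all-pairs reading of "mean
distance between all grandparents") must be ≤ 0.5, inclusive; samples with
fewer than two located grandparents are unevaluable rather than excluded.
The denomination-by-cluster test is Pearson's chi-squared with a
fixed-margin simulated p-value, `p = (1 + #{sim ≥ obs})/(n_sim + 1)` (never
zero), appropriate for sparse tables; per-cell Pearson residuals and their
share of the statistic identify which cells drive an association.

## Numerical and reproducibility choices

Interval arithmetic uses half-open cM intervals internally with 1e-9
tolerances at junctions; segment tables are canonicalised (lexicographic
carrier pairs, deterministic sort) so write–read–write cycles are
byte-identical. The pairwise mosaic-intersection engine is compiled code,
since it is the package's one hot loop. `run_pipeline()` records seeds,
parameters and md5 checksums of every artefact in a manifest; reruns with
identical configuration are byte-identical.

Problem sizes used by the test suite and acceptance script — a ~560-sample
default colony, five-seed sweeps for recovery checks, three-seed sweeps
over founder counts {20, 40, 80}, 200 null-D replicates, 500 null
contingency tables — were chosen as the smallest designs that make the
checks statistically meaningful at desk scale.

## Known limitations

* No segment detection or phasing: true segments stand in for detected
  ones, and accepted real tables are trusted as given.
* No mutation or genotyping error; drift tests on simulated data are
  slightly cleaner than they would be on array data.
* No Indigenous-ancestry component, historical-Ne reconstruction,
  co-ancestry painting, or migration-surface estimation; a > 4 cM
  within-cluster export hook serves external Ne tools.
* Louvain level semantics are emergent, not forced (nothing pins "sources
  versus colony" to level 1), and the familial edge threshold is an
  absolute cM value whose meaning scales with genome length.
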