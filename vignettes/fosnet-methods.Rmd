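---
title: "Methods: c-Fos functional connectomics with fosnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: c-Fos functional connectomics with fosnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fosnet)
```

## The analysis in one paragraph

Counts of c-Fos-positive cells are a post-hoc proxy for recent neuronal
activity: an animal is trained, perfused ~90 min later, and cells expressing
the immediate-early gene product are counted per brain region. Across the
animals of one experimental condition, regions whose counts rise and fall
together are inferred to be functionally coupled. `fosnet` turns an
animal-by-region count table into (i) per-region activation statistics
against a homecage baseline, (ii) per-condition inter-regional Pearson
correlation matrices, (iii) functional networks whose edges are the
significant positive correlations at a chosen p threshold, and (iv)
graph-theoretic characterizations of those networks — communities and
community roles, four centrality measures, hub sets, and a group-label
permutation test for centrality differences between two conditions.

## Data model and normalization

The node universe is a 49-region rat atlas grouped into nine anatomical
groups (prefrontal PFC, medial prefrontal mPFC, retrosplenial RSC, thalamic
TAL, amygdalar AMY, dorsal/ventral hippocampal DH/VH, subicular SUB and
parahippocampal PHC). The default mapping ships with the package and is
fully user-overridable through the atlas CSV; the assignment of AC, M2 and
ECT between neighbouring groups is the least certain part of the mapping and
worth checking against one's own parcellation. The default condition design
has six groups — homecage baseline HC (n = 12), contextual fear conditioning
CFC (n = 11), conditioning with a 5-s context-shock interval CFC-5s
(n = 11), context-only CT (n = 11), context-with-interval CT-5s (n = 12) and
immediate-shock US (n = 11).

Counts are normalized per region to percent of the baseline-condition mean
(`normalize_to_baseline()`), so the baseline group's mean is exactly 100.
Pearson correlations are invariant to this per-region linear rescaling, so
normalization affects only the activation analysis, never the networks.
Missing entries (lost tissue) stay `NA` and correlations use
pairwise-complete observations with the per-pair n recorded.

## Activation analysis

Per region, an omnibus Welch ANOVA (`oneway.test`, unequal variances)
compares conditions; pairwise Welch t contrasts are computed only when the
omnibus p passes the gate (default alpha = 0.05, mirroring a
protected-contrast workflow). A permutation F alternative is provided; a
Benjamini-Hochberg flag across regions is available but off by default,
matching the common practice of reporting unadjusted per-region p-values in
this literature. We deliberately use Welch tests rather than generalized
linear models with data-driven family selection: the decision logic layered
on the contrasts — not the test family — is the scientifically interesting
part, and Welch tests are transparent, dependency-free and robust to the
variance heterogeneity typical of count-derived percentages. Effect sizes
are standardized mean differences (pooled-SD denominator), comparable in
spirit but not in value to model-based standardized coefficients.

`classify_engagement()` encodes the three-clause decision rule as boolean
logic over the contrasts: *target-specific* (the focal condition exceeds
every other condition), *both-conditionings* (focal and partner conditioning
do not differ, each exceeds the shock-only or baseline group, and either
each exceeds its own context control or the context controls are
indistinguishable from shock-only and baseline), *contextual* (the four
context-exposed groups are indistinguishable and each exceeds shock-only or
baseline), then *other*/*none*.

## Correlation, edge comparison and group connectivity

Correlations use all animals of one condition; two-sided p-values come from
the exact t transform `t = r sqrt(n-2) / sqrt(1-r^2)` with `df = n - 2`. At
n = 11 the critical r is 0.602 (p < 0.05) and 0.735 (p < 0.01); these two
values fully determine which edges the thresholded networks contain.

Single-edge differences between conditions are compared after the Fisher Z
transform `z = atanh(r)`. Two conventions are computed and labeled: the raw
difference `z1 - z2` flagged at `|.| >= 2`, and the standardized difference
`(z1 - z2) / sqrt(1/(n1-3) + 1/(n2-3))` flagged at 1.96. The standardized
form is the default because its critical value corresponds to an actual
two-sided alpha of 0.05; the raw form is retained because published
worked values in this literature often follow it. For the printed pair
(r = 0.981 vs 0.345, n = 11) the raw difference is 1.964 — just under the
literal cutoff of 2 — while the standardized statistic is 3.93; the package
reports both rather than guessing a convention.

Anatomical-group connectivity averages raw coefficients within a group
(internal), between a group and all other regions (external) and between
group pairs; two conditions are compared per scope by a Welch t test on
Fisher-transformed coefficients (default) or by a coefficient permutation
test. These coefficient sets are not independent samples (each region
contributes to many pairs), so the p-values are descriptive screening
devices, not exact tests — the same caveat applies to any analysis that
treats correlation coefficients as observations.

## Networks and graph measures

An edge joins two regions when r > 0 and p < threshold; all atlas regions
stay in the node set, isolates flagged, and significant negative
correlations are counted as a diagnostic but never become edges (in the
motivating data there were none). Density is reported both over connected
nodes (the convention that reproduces published 46-node values) and over all
nodes. Shortest-path measures are unweighted — path length is the minimum
number of edges — while the weighted degree sums correlation coefficients.
Global efficiency is the mean nodal efficiency with unreachable pairs
contributing zero; average path length is over reachable pairs only;
the "connected up to k edges" phrasing of network diameter is exposed as the
maximum eccentricity among connected nodes, an interpretation we label as
such. Between- and within-threshold comparisons of node-level measures use
Welch t and two-sample Kolmogorov-Smirnov tests. By construction, edges at
p < 0.01 are a subset of edges at p < 0.05, so degree, weighted degree and
density can only decrease at the stricter threshold — the within-condition
direction of that comparison is a structural invariant, and the test suite
asserts it on every synthetic run.

## Communities, roles, centralities, hubs

Communities maximize modularity. The default optimizer is multilevel
(Louvain) on Fisher-Z edge weights with a fixed seed; leading-eigenvector is
offered since the choice of heuristic is not canonical, and
`exhaustive_small` enumerates all partitions of graphs with at most 10 nodes
as an exact oracle. On small random graphs the Louvain heuristic attains the
enumerated optimum in roughly 95% of cases, which is why the exact mode, not
the heuristic, anchors the oracle tests.

The within-community degree z-score uses unweighted within-community degree
and the population SD of the node's community, with z = 0 when the SD is
zero (including singletons). The participation coefficient defaults to the
Guimera squared-share form `1 - sum_s (k_is/k_i)^2`; the literal
one-minus-own-share ratio is kept as `simple_ratio` because the two
appear interchangeably in methods descriptions. Provincial hubs require
WC >= 1.5 and PC <= 0.3; connector hubs PC >= 0.8 and WC <= 1.5; nodes
matching neither exclusive rule are "neither".

Centralities: weighted degree (sum of r by default; a Fisher-Z weighting is
available because some published weighted-degree magnitudes exceed the
maximum possible sum of 48 correlation coefficients, suggesting transformed
weights), eigenvector centrality (principal eigenvector of the weighted
adjacency per connected component, scaled to max 1 within the component),
betweenness (unnormalized, unweighted paths) and closeness (reachable-node
count over summed distances; isolates score 0). Hubs are nodes in the top
`floor(N * 0.25)` of at least 3 of the 4 measures; ties at the cutoff expand
the list with a reported count, and stable hubs are the intersection of hub
sets across thresholds.

## Permutation comparison of centralities

To compare a region's centrality between two conditions, animal labels are
shuffled without replacement (group sizes preserved), the entire
correlation-threshold-centrality pipeline is recomputed per resample, and
the one-sided exceedance frequency `count(resampled > observed) / n_perm` is
reported. This strict-exceedance p can be exactly 0; because published minimum
p-values of 0.001 at 1000 resamples suggest a floored convention, the
`(count + 1) / (n_perm + 1)` form is always reported alongside. Differences
significant at every threshold are flagged stable. The strict-exceedance
convention is well calibrated when the centrality differences are
continuous; in very sparse networks, mass of exactly-zero differences makes
it anti-conservative, which is why calibration checks use dense null
networks comparable to the empirical ones (density 0.4-0.8).

## The synthetic cohort generator

Real per-animal counts are not publicly deposited, so the generator is a
first-class module: it emulates the statistical structure the analysis
assumes and makes every downstream stage testable. Counts are lognormal
(strictly positive, right-skewed, as cell counts are); region j of condition
c is `exp(mu_cj + sigma_j z_j)` with latent `z ~ N(0, C_c)`, where `C_c` is
a background correlation `rho0` plus condition-specific within-block values,
verified positive semi-definite (eigenvalue tolerance 1e-10) before
sampling. Mean/SD targets are matched on the observed scale; activation
shifts multiply mean and SD together (constant CV), so they do not perturb
the correlation structure. Correlation targets apply on the latent scale;
the observed-scale Pearson r is mildly attenuated (about 0.014 at rho = 0.2,
CV = 0.3), which is visible in large-n checks but negligible relative to
sampling noise at n = 11. A truncated-normal family (animal-level rejection
sampling) is available for symmetric noise.

`reference_cohort_spec()` fixes the study conditions the package emulates:
the six-group design above; base means spread deterministically over a
realistic 40-220 cells range with CV 0.3; the eleven focal regions (PL, IL,
BLAp, LAv, MEAa, vCA1, vSUB, PER, POR, DIENT, VIENT) at 3.0x in CFC-5s
versus 1.4x in the other trained arms — about 2.6 SD on the log scale,
matching the large contrasts typical of IEG counts (standardized effects of
1-2 in this literature); six fear-conditioning regions (AC, BLAa, CEA, M2,
vDG, RSDp) at 2.2x in both conditionings; amygdala-block coupling 0.75 in
CFC-5s versus 0.35 in CFC over a 0.25 background. `planted_truth()` returns
the machine-readable ground truth for recovery scoring.

What the generator does *not* emulate: spatial autocorrelation between
neighbouring regions beyond the declared blocks, batch effects across
immunohistochemistry runs, counting error correlated within sections, or
heavy-tailed outlier animals. Passing recovery tests therefore show that the
pipeline detects the planted structure under idealized noise, not that the
original biological inferences are correct.

## Numerical choices and degenerate inputs

* Correlation p-values: exact t transform, df = n - 2; `|r| = 1` maps to
  p = 0; zero-variance regions are marked undefined (NA) with a warning,
  never silently zeroed, and are excluded from scope means with a count.
* Network z-weights clamp r at `1 - 1e-12` before `atanh` so a numerically
  perfect correlation cannot produce an infinite weight; the user-facing
  `fisher_z()` refuses `|r| >= 1` outright.
* Hub ranking breaks ties by value then lexicographic region code; ties at
  the quartile cutoff expand the flagged list rather than dropping an
  arbitrary subset.
* Degenerate activation rows (zero variance in every group) are flagged
  `undefined` and excluded from gating, not dropped.
* Empty graphs: all-singleton partition with Q = 0; isolated nodes score 0
  in every centrality and both community-role measures.
* All stochastic steps (generator, Louvain, permutation tests) take explicit
  integer seeds and restore the caller's RNG state.

## Problem sizes used in the checks

The test suite and the acceptance script size their simulations to run on a
single CPU in minutes while keeping Monte-Carlo standard errors well inside
the asserted bands: 5000 replicates for the edge-difference calibration
(SE about 0.003), 80 null cohorts x 49 regions for the activation
calibration (SE about 0.004 before inter-region correlation), 100 null
datasets x 200 resamples for the permutation calibration, 100 seeds per
recovery scenario, 200 random graphs (4-12 nodes) for oracle equivalence and
20 graphs (5-8 nodes) for the exhaustive-modularity cross-check.

## Known limitations

* Correlation networks at n = 11 are noisy; single-edge inferences
  (including the Fisher-Z worked example) have wide sampling bands, and the
  published raw-vs-standardized discrepancy cannot be resolved from printed
  values alone.
* The group-connectivity and node-level network comparisons treat dependent
  quantities (shared-animal correlations, shared-edge node measures) as
  samples; their p-values are screening tools.
* The strict-exceedance permutation p is anti-conservative when differences have
  point mass (sparse networks); prefer the corrected form there.
* Louvain is a heuristic: with a fixed seed it is reproducible, but it is
  not guaranteed to attain the modularity optimum on every graph.
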