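---
title: "Structural covariance network analysis with scnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural covariance network analysis with scnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scnet)
```

## The model

A structural covariance network is a *group-level* construct: its nodes
are anatomical regions (by convention the 116 regions of the AAL
parcellation) and its edges are Pearson correlations of regional
grey-matter volumes computed *across the subjects of one group*. There
is one network per group, not one per subject — which is why group
comparison requires permutation of subjects and full recomputation of
the networks, not an edge-wise test.

The pipeline is:

1. **Residualize** each region's volumes on nuisance covariates (age
   and sex by default) by ordinary least squares with an intercept, and
   correlate the residuals. For a single covariate set applied to all
   regions this is equivalent to partial correlation given the
   covariates.
2. **Threshold** the correlation matrix into binary undirected graphs
   over a grid of densities $d$, keeping the
   $k = \mathrm{round}(d\,N(N-1)/2)$ most strongly *positive*
   correlations as edges. Negative correlations are never edges:
   grey-matter covariance edges are conventionally restricted to
   positive coupling, and "strongest connections" thresholding is only
   meaningful on one sign. Ties at the cutoff are broken by
   lexicographic (row, column) order so that runs are bit-reproducible.
3. **Measure** each graph: mean clustering coefficient $C$
   (segregation), characteristic path length $L$ (integration), the
   small-world index
   $\sigma = (C/C_{rand})/(L/L_{rand})$ against degree-preserving
   random reference graphs, nodal betweenness centrality, and hubs
   (betweenness at least two standard deviations above the regional
   mean).
4. **Compare** groups by subject-relabeling permutation: the observed
   per-density metric difference is summarized by its trapezoidal area
   under the curve (AUC) across densities, the entire pipeline is
   recomputed on each of `n_perm` relabelings, and the two-tailed
   p-value is the add-one permutation percentile
   $p = (\#\{|T^{perm}| \ge |T^{obs}|\} + 1)/(n_{perm} + 1)$.
   Regional betweenness p-values are Benjamini–Hochberg corrected
   across regions; the three global metrics are not pooled with the
   regional family.

## Density grid and connectivity

The density grid runs from $d_{\min}$, the smallest grid density at
which **every** compared network forms a single connected component, up
to $d_{\max} = 0.5$; grey-matter covariance networks are conventionally
not analyzed above half density, where they become nearly random. The
grid step defaults to 0.01 and is recorded in every output so AUC
values are interpretable. $d_{\min}$ is determined per comparison pair
from the observed networks and reused in every permutation replicate; a
replicate whose graph disconnects at some density is flagged, and its
path length is computed on the largest connected component so that the
permutation distribution stays defined without infinite distances.
Recomputing $d_{\min}$ within each replicate is available via
`recompute_d_min = TRUE`.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `grid_step` | 0.01 | density grid resolution |
| `d_max` | 0.5 | upper density bound |
| `n_perm` | 1000 | permutation replicates |
| `n_random` | 20 | random reference graphs per density (for $\sigma$) |
| `n_swaps_per_edge` | 10 | attempted double-edge swaps per edge |
| `alpha` | 0.05 | significance level of the FDR-corrected maps |

The random references are produced by Maslov–Sneppen double-edge
swaps, which preserve every node's degree exactly. Swaps are applied in
adaptively sized batches; after each batch connectivity is checked and
the batch rolled back if it broke, so every reference graph of a
connected input is itself connected. The hub threshold uses the
population (n-denominator) standard deviation; the sample-SD variant is
available via `identify_hubs(sd_type = "sample")`. Betweenness is
normalized by $(N-1)(N-2)/2$; the hub rule is invariant to that scale.

## The synthetic cohort generator

No volume tables are distributed with grey-matter covariance studies of
this design, so `synthetic_spec()` / `generate_cohort()` simulate
cohorts with the statistical structure the analysis assumes: regional
volumes are multivariate normal around 1.0 (arbitrary units) with a
block-structured population correlation matrix (`rho_in = 0.3` within
blocks of 10 regions, `rho_out = 0.05` between blocks), linear age and
sex effects on the means, residual SD `noise_sd = 0.1`, and an optional
hub region correlating with all others. Cohort sizes default to 20
subjects per group — the scale of a typical first-episode longitudinal
sample — and longitudinal specs add a follow-up measurement whose
residual component correlates at `rho_t = 0.8` within subject
(test–retest correlation is not identified by any published value of
this design; 0.8 is typical of segmented grey-matter volumes).
Volumes are truncated at zero with a warning, which never triggers at
the default noise level.

Every group's implied population correlation matrix is checked for
positive semi-definiteness at construction, and a violation is an
error naming the offending parameterization — never a silent
nearest-PSD repair, because a repaired matrix would no longer match the
parameters the test asserts against.

Two constructions deserve comment:

* **Group differences** are implanted by shifting all population
  correlations involving one *peripheral* region by `delta_rho` in
  group 2. A peripheral region is one with only background covariance
  (a singleton block): shifting a region *inside* an equicorrelated
  block by +0.3 is never positive semi-definite (the block would need
  $\rho_{in} \ge (\rho_{in} + 0.3)^2$, which has no real solution), so
  the peripheral construction is the natural one for a localized
  covariance difference of that size.
* **What the generator does not emulate**: spatial autocorrelation of
  real parcellations, non-Gaussian volume distributions, scanner or
  site effects, and subject motion. Passing tests therefore demonstrate
  that the *inference machinery* is correct and calibrated under the
  model the method assumes — not that any particular empirical finding
  generalizes.

## Numerical conventions

* Residual means after covariate removal are zero to $10^{-10}$;
  residualization is idempotent.
* Edge ranking uses a stable sort, so equal correlations resolve to
  the lexicographically first (row, col) pair on every platform.
* Nodes of degree < 2 contribute clustering 0; the empty graph has
  $C = 0$.
* $\sigma$ accepts $C = 0$ (returning 0) but requires positive
  $L$, $C_{rand}$, $L_{rand}$.
* All randomness (cohort generation, permutation, rewiring) flows from
  explicit seeds; a run's metadata JSON records every convention needed
  for exact replay, and repeated runs are byte-identical.

## Problem sizes used in the test suite

The packaged tests exercise the machinery at sizes chosen to probe the
statistics rather than the full 116-region cohort: oracle equivalence
on 100 random graphs of up to 12 nodes against brute-force
(enumeration, Floyd–Warshall, shortest-path counting) oracles;
calibration of the global clustering AUC test on 200 null cohorts of
40 regions and 30 subjects per group at 200 permutations (empirical
type-I error within [0.02, 0.08] at nominal 0.05); and recovery of a
`delta_rho = 0.3` perturbation with 300 subjects per group, where the
implanted region must rank in the top 5 by |betweenness AUC
difference| and reach raw p < 0.05 in at least 80% of 50 repeats.
These sizes are the package's reference experiments; the same code
runs unchanged at 116 regions and 1000 permutations.

## A worked example

```{r example, eval = FALSE}
spec <- synthetic_spec(n_regions = 40, n_subjects_per_group = 30,
                       seed = 1)
cohort <- generate_cohort(spec)

cmp <- compare_metrics(cohort[cohort$group == "control", ],
                       cohort[cohort$group == "patient", ],
                       metrics = c("clustering", "path_length",
                                   "betweenness"),
                       n_perm = 200, seed = 1)
print(cmp)

net <- correlation_network(residualize(cohort[cohort$group == "control", ]))
A <- binarize_at_density(net, cmp$d_min)
identify_hubs(betweenness_centrality(A))
```

## Known limitations

* Weighted-network and negative-edge variants are out of scope; only
  binary positive-correlation graphs are analyzed.
* The paired permutation scheme swaps timepoint labels within subject;
  an unpaired fallback is available by calling `compare_metrics()`
  with `paired = FALSE`, but the published design of such studies does
  not state its exact paired scheme, so the within-subject swap is a
  design choice of this package.
* The small-world index per permutation replicate is expensive
  ($n_{random}$ rewired graphs per density per replicate); sigma is
  therefore excluded from the default comparison metric set and can be
  requested explicitly where the computational budget allows.
* Repeated-measures ANOVA is implemented for the two-timepoint,
  two-group design only, where sphericity holds trivially.
```
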