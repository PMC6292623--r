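---
title: "Detecting high-abundance plant clusters along transects: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting high-abundance plant clusters along transects: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lisatransect)
```

## The problem

Vegetation surveys that string contiguous quadrats along transects — for
example 23 transects of 25 quadrats of 2 m × 2 m, 575 quadrats in all —
routinely find that plant individuals are not spread evenly: a few short
runs of quadrats concentrate a disproportionate share of individuals and
species. `lisatransect` detects those runs statistically, as *High-High
(HH) clusters* of per-quadrat density, and then characterizes them:
which growth habits (trees, shrubs, palms, vines, cacti) are enriched,
which species dominate, and whether the cluster quadrats fall into
compositional groups that track the substrate (lithology) of their
transects.

## The statistic

The analyzed variable is the density of individuals per quadrat,
`dN = N / a`, with `N` the quadrat's individual count and `a` its area
in m² (4 m² by default, so `dN = N/4`). For quadrat *i* in a scope of
*n* quadrats with mean `x̄`, the local Moran statistic is

    I_i = (x_i − x̄) / S_i² · Σ_{j≠i} w_ij (x_j − x̄)
    S_i² = Σ_{j≠i} (x_j − x̄)² / (n − 1)

`I_i` is positive when a quadrat and its neighbourhood deviate from the
mean in the same direction, so a significantly positive `I_i` at a
high-density quadrat flags "high surrounded by high".

Two conventions for the scale term circulate. The default (`variant =
"anselin"`) excludes quadrat *i* and divides by `n − 1`, exactly as
written above. Most spatial-statistics software instead divides the
cross-product by the global second moment `m₂ = Σ_j (x_j − x̄)²/n`;
that is available as `variant = "moment"` for cross-checking. The two
agree closely unless `x_i` is extreme.

### Weights

Quadrats are ordinal positions along a transect; adjacency is
first-order contiguity on the line, and weights are row-standardized
("W style"): interior quadrats have two neighbours at weight 0.5 each,
endpoints one neighbour at weight 1. Every row sums to one exactly
(binary fractions), so the spatial lag `Σ_j w_ij x_j` is a convex
combination and equal weighting makes `I_i` comparable across quadrats
and transects. Transects are never neighbours of each other.

### Scope

The mean, `n`, and `S_i²` are computed **per transect** (`n = 25`) by
default, because the weight rows are defined within a transect block and
the Moran scatterplot is drawn per transect. `scope = "pooled"` treats
the entire survey as one scope (weights stay within transects) for
sensitivity analysis.

## Inference

`local_moran_table()` tests each `I_i` one-sided (`Pr(Z > z)`, the
alternative of positive association that an HH hunt needs) and applies a
Bonferroni correction, by default with `m` equal to the number of tests
in the scope (25 per transect; 575 when pooled).

Two analytic nulls are implemented:

* **Total randomization** (default): all values permuted across
  positions. `E[I_i] = −Σ_j w_ij/(n−1)` (−1/24 on a 25-quadrat
  transect) and the matching second moment in terms of the sample
  kurtosis. These closed forms are exact for the `"moment"` variant and
  a close approximation for the default variant; the test suite
  validates both the mean and the standard deviation against 10⁵ Monte
  Carlo permutations (sd within 2%).
* **Conditional randomization** (`null = "conditional"`): `x_i` held
  fixed, the other `n − 1` values permuted. Because the scale term is
  then fixed, the mean and variance of `I_i` follow exactly from
  sampling-without-replacement algebra, for both variants.

A conditional **permutation test** (`local_moran_perm()`,
`inference = "permutation"`) gives the standard pseudo-p
`(1 + #{I* ≥ I}) / (1 + n_perm)`, reproducible by seed. Under an
exchangeable null the pseudo-p is uniform (checked by
Kolmogorov–Smirnov over 500 replicates at `n_perm = 199`). Analytic
conditional p-values track permutation p-values within 0.03 at interior
quadrats; at endpoints the permuted lag is a *single* resampled value,
the normal approximation is coarser, and discrepancies up to roughly
0.1 can occur — one reason endpoint quadrats face a stricter
significance rule.

### Classification and the endpoint rule

Significant quadrats are labelled by the quadrant of
`(x − x̄, lag − x̄)`: HH, LL, HL or LH; everything else is NS
(not significant). Interior quadrats are significant at
`p_adj < alpha` (default 0.05). Endpoints, having one neighbour, are
prone to edge artefacts, so they must satisfy `p_adj < alpha_endpoint`
(default 0.01) **and** their single neighbour's density must exceed the
scope mean. A quadrat exactly at the mean is never assigned a cluster
class (its quadrant is undefined); it is reported NS with a warning.
Both raw and adjusted p-values are kept in the output so either
convention can be audited.

## Characterizing clusters

`partition_groups()` splits the sample into the HH quadrats and "the
rest" (LL, outliers and NS together). `summarize_group()` reports
richness, abundance, area, percent of individuals per habit (vines and
cacti pooled, as is conventional for these forests) and per-habit
densities as mean ± SE over the group's quadrats, with SE =
sd(n−1)/√n. `density_ratio()` compares group means;
`ttest_density()` compares per-quadrat pooled densities (Welch by
default — the variant and its df are always reported, since pooled and
Welch variants can differ materially). `rank_abundance()` ranks species
present in at least `min_quadrats = 3` quadrats of the group by
within-group abundance, truncated to `top_k = 17`; proportions are
percentages of *all* individuals in the group (including species the
occupancy filter removed), which is why listed proportions sum well
below 100. Ties in abundance break alphabetically, so tables are
deterministic.

## Ordination and grouping of HH quadrats

HH quadrats are ordinated two ways: PCoA on Bray-Curtis dissimilarity
of raw counts, and PCA on Hellinger-transformed counts (square-root
relative abundance; rows then have unit L2 norm, so centred PCA without
variance scaling is appropriate). PCoA reports negative eigenvalues —
expected for Bray-Curtis — with a flag rather than correcting them
silently; coordinates use the positive eigenvalues only. By default the
ordination uses all species present in the HH quadrats; the
rank-abundance filter is applied only when exporting plot-ready species
lists (`ordination_species = "filtered"` restricts the ordination
itself, for comparison).

Grouping uses chord distance (Euclidean on L2-normalized rows, bounded
by √2) with the linkage chosen by highest cophenetic correlation among
single, complete, UPGMA, WPGMA and Ward — UPGMA typically wins on such
data. `hclust`'s deterministic tie handling is relied on for
reproducibility. Cluster confidence comes from the **multiscale
bootstrap**: species (columns) are resampled with replacement at sizes
`round(r·S)` for ten scales `r` in [0.5, 1.4], the tree is rebuilt, and
each original node's recovery frequency `BP(r)` is recorded. The
approximately unbiased value corrects for boundary curvature: with
`z(r) = Φ⁻¹(1 − BP(r))`, weighted least squares fits
`z(r) = v√r + c/√r` and `AU = 1 − Φ(v − c)`. BP is reported at the
scale closest to 1. Nodes never (always) recovered get AU = 0 (1);
nodes whose `BP(r)` is entirely 0/1 except too few scales to fit are
flagged and given their near-1 frequency. Resampling columns is the
convention for community dendrograms of sites and is stated here
because it matters: it asks how stable the quadrat grouping is under
perturbation of the species set. `cut_groups()` extracts `k` groups
from the selected dendrogram; `k` is the user's call, guided by the
AU/BP values.

## The synthetic generator

`simulation_config()` defaults describe the survey design the package
targets: 23 transects × 25 quadrats × 4 m², 172 species with habit mix
(tree 0.45, shrub 0.35, palm 0.05, vine 0.12, cactus 0.03), geometric
rank-abundance decay 0.96, baseline intensity λ₀ = 2158/575 ≈ 3.75
individuals per quadrat. Planted clusters are 10 contiguous runs of 1–3
quadrats at κ·λ₀ with κ = 2.5 — the density contrast reported between
HH clusters and the rest in such forests — and shrub/palm/vine species
up-weighted by 2.5 inside clusters. Transects carry one of 3 lithology
classes whose lognormal (sd 0.5 on log scale) species preferences shift
composition. Counts factorize as Poisson totals × multinomial
composition, so the density signal and the compositional signal can be
tuned independently. Per-transect seeds derive deterministically from
the root seed, so datasets are stable for leading transects when
`n_transects` grows.

What the generator does *not* emulate: spatially continuous intensity
surfaces, between-transect correlation, within-quadrat point locations,
detection error, or taxonomic noise. Passing the recovery tests
therefore shows the statistic and its inference behave correctly under
the design's sampling model — not that any particular field dataset
meets that model.

### Calibration results the test suite enforces

* With κ = 1 (no clusters) the mean fraction of quadrats flagged HH
  stays at or below 0.05 across 200 simulated surveys (measured ≈
  0.009 — Bonferroni makes the procedure conservative).
* With κ = 4 and runs of 3, mean sensitivity across 100 surveys exceeds
  the pinned 0.6 (measured ≈ 0.67 at calibration). Sensitivity counts
  every planted quadrat; a run's edge quadrats, having one background
  neighbour, are intrinsically harder than its centre, which caps
  attainable sensitivity well below 1 at any κ.
* Power increases with κ (checked at 1.5 vs 4).

## Numerical choices and degenerate inputs

* Row-standardized weights use exact binary fractions; row sums are
  checked at 1e-12.
* A transect with constant density has no statistic (zero variance):
  error, not NA.
* Scales in the bootstrap use the effective `round(r·S)/S`; resamples
  that empty a quadrat row are redrawn (deterministically within the
  seeded stream).
* Reported tables round only at export (percentages 2 dp, densities
  3 dp, ratios 1 dp); full precision is kept internally.
* Problem sizes in tests and the acceptance script (e.g. 100–200
  simulated surveys, 10⁵ permutation draws, bootstrap 150–1000
  replicates) were chosen as the smallest sizes at which the Monte
  Carlo error is comfortably below the tolerance being asserted.

## Known limitations

* The analytic total-randomization moments are exact for the `"moment"`
  variant only; with the default variant they are an approximation
  (excellent in practice, and the conditional null and permutation test
  are exact alternatives).
* Only linear (transect) contiguity ships; the neighbour-list
  representation admits other graphs but none are constructed.
* No NMDS/constrained ordination, no diversity indices, no spatial
  statistics beyond local Moran's I — deliberately out of scope.
* The pipeline assumes individuals are already identified, habit-
  labelled and height-filtered; no taxonomic cleaning is attempted.
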