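---
title: "The flow-hierarchy of urban trip networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The flow-hierarchy of urban trip networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Cities differ in how their mobility is organized. In some, activity is
concentrated in a nested sequence of hotspots — a dominant core ringed by
successively less active zones — and most trips connect places of similar
activity. In others, high-activity cells are scattered across the urban
area and trips mix all activity strata. flowhier quantifies where a city
sits on this spectrum from nothing but an origin–destination (OD) trip
table on spatial cells.

The pipeline has four stages, each exposed as a pipeable function:

1. **Outflows** (`cell_outflows()`): the total outgoing trips of every
   cell. Intra-cell trips are excluded throughout.
2. **Hotspot levels** (`assign_levels()`): a nonparametric, iterated
   thresholding of the outflow distribution (the Loubar construction).
3. **Level-flow matrix** (`level_flow_matrix()`): the `L × L` matrix `T`
   whose entry `T[i, j]` is the share of all trips going from level-`i`
   cells to level-`j` cells.
4. **Flow-hierarchy** (`flow_hierarchy()`): the tri-diagonal trace of `T`,

   $$\Phi \;=\; \sum_{i=1}^{L-1}\big(T_{ii} + T_{i,i+1} + T_{i+1,i}\big) + T_{LL},$$

   the share of trips exchanged between same- or adjacent-level hotspots.
   `city_phi()` runs all four stages and both null models at once.

`Φ = 1` means all interaction stays within the band (tree-like,
maximally hierarchical); uniform mixing over level pairs gives
`(3L − 2)/L²`.

## The Loubar construction

The Lorenz curve of the outflows plots, in ascending order, the
cumulative fraction of cells against the cumulative fraction of total
outflow. Because the curve is piecewise linear, its derivative at
`(1, 1)` is the final segment's slope `s = n · max(F) / ΣF`; the tangent
there meets the x-axis at `x* = 1 − 1/s`, and the cells in sorted
positions beyond `x*` are the hotspots of the current level. They are
removed, the threshold is recomputed on the remaining cells, and the
procedure repeats until the remaining distribution is flat
(`s ≤ 1 + 10⁻⁹`), fewer than `min_cells` cells remain, or no
positive-outflow cell is left.

Decisions the construction needs that no textbook fixes:

- **Ties at the cut.** Cells whose outflow strictly exceeds the boundary
  value enter first; remaining slots are filled among boundary-valued
  cells in input order. Deterministic and order-stable.
- **Zero-outflow cells** are assigned to the final level `L`: they are
  part of the city but demonstrably not hotspots at any depth. The count
  folded in this way is kept in the result's attributes.
- **Termination.** We iterate to exhaustion by default (`min_cells = 1`):
  deep hierarchies (a dozen or more levels in very large metros) are
  meaningful, and truncated analyses can be reproduced by raising
  `min_cells`.
- **`L = 1`.** A perfectly flat city has a single level and the band is
  the whole 1×1 matrix, so `Φ = 1` by convention. The metric is about the
  *organization* of differences; with no differences, there is nothing
  off-band.

## Null models

Two reference points separate "heterogeneous flows" from "spatially
organized flows":

- **Uniform null** `uniform_null_phi(L) = (3L − 2)/L²`: all level pairs
  equally likely. At `L = 14` this is ≈ 0.20.
- **Rewired null** (`rewired_null()`): keeps the empirical level
  marginals but makes origin and destination levels independent,
  $$T^h_{ij} = \Big(\sum_k T_{ik}\Big)\,\frac{\sum_m T_{mj}}{\sum_{mk} T_{mk}}.$$
  Row and column sums are preserved exactly (a property the test suite
  asserts to 10⁻¹²). The implementation accepts raw count matrices too —
  the grand total cancels. `Φ − Φ_h` is the part of the hierarchy
  attributable to *spatial correlation between hotspots* rather than to
  the heavy-tailed level-flow distribution alone.

Validation treats a matrix as normalized when its entries sum to 1
within a relative 10⁻⁸; band sums are clamped at 1 to absorb
floating-point overshoot.

## Trip-distribution models

`gravity_flows()`, `radiation_flows()` and `pwo_flows()` generate OD
flows from cell masses and per-origin out-trip totals; `model_phi()`
chains them into the Φ pipeline. All three are production-constrained
(`Σ_j T_ij = O_i` exactly, asserted to 10⁻¹⁰ relative): out-trips are an
input, only the destination split is modeled. Masses default to cell
populations and fall back to the out-trips when populations are absent.

- **Gravity**: `T_ij ∝ m_j^β f(d_ij)` with exponential `exp(−d/λ)` or
  power `d^−γ` deterrence; `β` interpolates linear (1) to quadratic (2)
  mass dependence.
- **Radiation** (parameter-free):
  `p_ij ∝ m_i m_j / ((m_i + s_ij)(m_i + m_j + s_ij))` with `s_ij` the
  mass strictly inside the origin-centered circle of radius `d_ij`,
  excluding origin and destination. Distance ties stay outside the
  circle. The finite-size correction is absorbed by the per-origin
  renormalization that the production constraint requires anyway.
- **Population-weighted opportunities**:
  `T_ij ∝ m_j (1/S_ji − 1/M)` with `S_ji` the mass within the
  destination-centered circle of radius `d_ji`. The circle-inclusion
  convention in the literature is ambiguous; ours is *strict* inequality
  on distance, which automatically includes the destination (distance 0)
  and excludes the origin (on the boundary). Note that symmetric cell
  layouts do **not** generally produce symmetric splits: on a unit square
  with equal masses the diagonal destination's circle contains the two
  side cells, so it receives strictly less — only exchangeable
  destinations split equally.

Distances are Euclidean on the planar km coordinates (inputs must be
pre-projected; no geographic machinery is included). Distinct cells at
identical coordinates get a 10⁻⁹ km distance floor with a warning.

## The synthetic city generator

`generate_city()` exists so every stage is testable without any data
download. It emulates a gridded metro:

- cells on a `grid_side × grid_side` grid with 1 km spacing, comparable
  to the ≈1.3 km² cells used when aggregating real trip data;
- population = `base_population ×` (sum of Gaussian kernels around the
  activity centers + a small uniform floor), with **rank-size center
  amplitudes** (`k^−center_weight_decay`): a primary center always pinned
  at the grid center, subcenters scattered uniformly in a disc of radius
  `center_spread` around it;
- out-trips proportional to population; flows from a configurable trip
  model; optional mean-preserving log-normal noise on flows
  (`noise_cv`) and on the population surface (`population_cv`).

Defaults (chosen for realism, with the mechanism below in mind, and then
frozen): `grid_side = 30` (a ~30 km metro), `kernel_width = 2` km (tight
employment cores), gravity flows with exponential deterrence at
`λ = 2` km (trips short relative to the urban extent, as in real
intra-city mobility), `trips_per_capita = 0.5`, `noise_cv = 0.3`,
`population_cv = 0` (the smooth analytic kernel), `base_population =
1000`. Everything is reproducible from `seed`; runs differing only in
`center_spread` share all random draws (common random numbers), so
paired comparisons isolate the geometry.

**Why this regime.** The compact-vs-scattered contrast that
`hierarchy_response_curve()` measures only emerges when the city is much
larger than both the density kernel and the trip scale. In a small,
smooth monocentric city the entire periphery sends its trips to the core
— a flow across three or more levels — which *depresses* Φ for the
compact layout; and scattering *equal-amplitude* centers lowers the
global peak outflow, which flattens the Lorenz tangent, balloons the
level-1 set, and *inflates* Φ mechanically. Rank-size subcenter weights
keep the outflow distribution heavy-tailed while the geometry changes,
and pinning the primary center removes edge-truncation artifacts. In the
chosen regime, scattering subcenters to half the grid size reliably
lowers mean Φ (the canonical polycentric experiment uses `n_centers = 4`,
`center_weight_decay = 0.5`, i.e. subcenters at 71/58/50% of the core
amplitude, in line with employment subcenters in real metros).

**What the generator does not emulate.** Real street networks,
anisotropic geography (coasts, rivers), land-use zoning, temporal
structure, and the deep hierarchies (`L ≈ 14`) of the largest real
metros — the generator plateaus around `L = 5–7`. Passing tests on
generator output therefore demonstrate internal consistency and the
qualitative mechanisms, not agreement with any particular real city.

## A known, deliberate red flag: the mass-exponent sweep

On this generator, the gravity flow-hierarchy is *decreasing* in the
mass exponent (≈0.94 → 0.86 → 0.77 across β = 1, 1.5, 2 at the
defaults), and the corresponding acceptance check expecting a
non-decreasing trend fails. We believe this is structural, not a bug:
the synthetic city *is* a linear-mass gravity process, and hotspot
levels are fixed by the given outflows, so raising β only re-aims
destination choice toward the top-mass core. That drains peripheral
origins (levels 3 and up) across two-or-more-level gaps, and band mass
falls monotonically — in the limit β → ∞ the matrix collapses onto the
top-level column. The published observation that stronger mass
nonlinearity improves model estimates concerns real cities, where
linear-mass models *underestimate* the empirical hierarchy; for a city
whose ground truth is β = 1, agreement is maximal at β = 1 by
construction and no parameterization of this generator can reproduce a
rising trend. The ordering that does transfer — radiation above linear
gravity, over- versus under-concentration — holds in every seed and is
asserted in the tests.

## Indicator statistics

`correlate()` reports three explained variances between Φ and a per-city
indicator: squared Pearson correlation, squared Spearman rank
correlation, and `1 − RSS/TSS` of a LOESS fit of the indicator on Φ.
LOESS defaults are locally linear (`degree = 1`), tricube weights, span
0.75 — standard values, exposed as arguments and echoed in the output
since different spans change `R²_L`. The LOESS explained variance can be
negative for pathological fits; the raw value is kept and a clipped copy
is provided for reporting. Significance stars (one/two/three for
p < 0.05/0.01/0.001) are based on the Pearson p-value; the Spearman
p-value is reported alongside, and a seeded permutation option replaces
the t-approximation for small samples. Analysis is complete-case per
indicator with the dropped count reported. Fits are unweighted; a
population-weighted variant can be had by pre-filtering the table.

`multivariate_gain()` fits three OLS models with intercepts — Φ only,
covariates only, covariates + Φ — and reports the R² gain from adding
Φ. Nesting guarantees a non-negative gain; rank-deficient designs error
out naming the offending columns rather than silently aliasing.

`rank_cities()` orders cities by decreasing Φ (ties broken by city id,
deterministically) and appends per-group mean/sd of both Φ and rank.

## Spatial scale

`coarse_grain()` re-bins cells onto a square grid (half-open bins
anchored at the origin; boundary cells go to the higher bin) and drops
newly intra-bin flows, consistent with the exclusion of intra-cell
trips. Re-running `city_phi()` at bin sizes 2 and 3 km over a diverse
20-city synthetic ensemble leaves the Φ *ranking* largely intact
(pairwise Spearman above 0.8 in the test suite, a threshold of our own
choosing): the value drifts with scale, the ordering is stable —
provided the ensemble spans a wide Φ range, as real city sets do.

## Problem sizes and budgets

The test suite and acceptance script use 30×30-cell cities (900 cells,
~8·10⁵ directed flows), 10–20 seeds per stochastic claim, and
oracle-comparison sweeps of 200–1000 random instances; a full run of
everything takes a few minutes on one core. These sizes were chosen so
that each stochastic property is measured with enough replicates to be
stable across seed choices while keeping the feedback loop short.

## Limitations

- Planar coordinates only; callers must project geographic data first.
- The generator's hierarchies are shallower than those of the largest
  real metros, and none of its parameters were tuned to reproduce any
  specific city's Φ.
- Empirically reported city values (e.g. Φ ranges of 0.77–0.95) derive
  from proprietary mobility data and are not reproducible here; they are
  context, not test surfaces.
- The PWO circle convention and the stars-from-Pearson choice are
  documented decisions where the literature or source material is
  ambiguous.
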