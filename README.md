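# flowhier

Quantify the hierarchical organization of urban mobility from
origin–destination trip networks.

Cities range from strongly *hierarchical* — activity concentrated in
nested hotspot levels, trips flowing mostly between places of similar
activity — to *flat*, with high-activity cells scattered and trips mixing
all strata. flowhier measures where a city falls on that spectrum with a
single nonparametric metric, the **flow-hierarchy Φ**, built in three
steps from an OD table on spatial cells:

1. **Hotspot levels.** Cell outflows are thresholded by the derivative of
   their Lorenz curve at (1, 1) (the Loubar construction); selected cells
   form level 1, are removed, and the threshold is recomputed to yield
   level 2, and so on, giving every cell a level ℓ = 1…L.
2. **Level-flow matrix.** `T[i, j]` = share of all inter-cell trips going
   from level-*i* cells to level-*j* cells (entries sum to 1).
3. **Metric.** The tri-diagonal trace

   Φ = Σᵢ (Tᵢᵢ + Tᵢ,ᵢ₊₁ + Tᵢ₊₁,ᵢ) + T_LL,

   the share of trips between same- or adjacent-level hotspots: 1 for
   tree-like cities, (3L − 2)/L² under uniform mixing.

Two null models calibrate the metric: the closed-form **uniform null**
Φᵤ = (3L − 2)/L², and the **rewired null** Φₕ, the metric of the
outer-product matrix with the empirical level marginals — what the
heterogeneous flow distribution alone would produce, with all spatial
correlation between hotspots removed.

The package also provides production-constrained **trip-distribution
models** (gravity with tunable mass exponent, radiation,
population-weighted opportunities) for estimating Φ from outflows alone,
**indicator statistics** (Pearson/Spearman/LOESS explained variances,
significance stars, nested-OLS variance gain) linking Φ to per-city
indicators, a seeded **synthetic city generator** for controlled
experiments, and a `flowhier` **command-line interface**
(`inst/exec/flowhier`).

## Worked example

```r
library(flowhier)

# a compact monocentric city: 30 x 30 km grid, 1 km cells, gravity flows
net <- generate_city(city_config(seed = 1))
net
#> <trip_network> 900 cells, 809100 directed flows, total flow 21491.6
#>   total population 43132.7

res <- city_phi(net)
res
#> <hierarchy_result> phi = 0.9370  (L = 5, uniform null 0.5200, rewired null 0.6455)

tidy(res)
#> # A tibble: 5 × 4
#>   level n_cells outflow_share threshold
#>   <int>   <int>         <dbl>     <dbl>
#> 1     1      44      0.498       110.
#> 2     2     109      0.154        11.1
#> 3     3     678      0.318         9.57
#> 4     4      68      0.0298        9.02
#> 5     5       1      0.000419      9.00
```

Read: 93.7% of all trips connect cells of the same or adjacent hotspot
level. A city with this level structure but *independent* level pairings
would score only 0.65 (`phi_rewired`), so most of the excess hierarchy
comes from the spatial arrangement of the hotspots, not from the
heavy-tailed outflow distribution — the 44 level-1 cells alone emit half
of all trips. Scattering activity centers lowers Φ:

```r
rc <- hierarchy_response_curve(
  city_config(n_centers = 4, center_weight_decay = 0.5, seed = 101),
  spread_values = c(0, 15), seeds_per_point = 10
)
rc
#> # A tibble: 2 × 4
#>   spread mean_phi  sd_phi n_seeds
#>    <dbl>    <dbl>   <dbl>   <int>
#> 1      0    0.910 0.00926      10
#> 2     15    0.899 0.0100       10
```

From a shell, the same pipeline runs on CSV files (edge list
`origin,destination,weight`; cell table `id,x,y[,population]`, planar km
coordinates):

```sh
inst/exec/flowhier phi \
  --edges inst/extdata/toy_edges.csv \
  --cells inst/extdata/toy_cells.csv \
  --out phi.json
```

Every run writes a `<out>.manifest.json` (parameters, input digests,
package version, seed) sufficient to reproduce it.

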