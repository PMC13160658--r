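# cloudsens

Cloud-model quantification of the climate-change sensitivity of the
upper limit of montane deciduous broad-leaved forests (ULMDB) — the
elevational boundary where the deciduous belt gives way, usually to
conifers. The package is for montane biogeographers and ecologists who
have (or simulate) tables of boundary location points with impact
factors, and want per-mountain temperature / precipitation /
comprehensive sensitivity indices with dominance classification,
regional aggregation and NDVI-based validation.

## The method in brief

For each ULMDB *site*, boundary elevation is regressed on five impact
factors (aspect class, terrain relief, mountaintop effect, January mean
temperature, annual precipitation):

    y = a₁x₁ + … + a₅x₅ + b + ε

Standardized-coefficient magnitudes, normalized to sum to one, give the
site's factor-weight vector. Within each mountain, the backward cloud
generator digests every factor's site weights into three digital
features — expectation *Ex*, entropy *En*, hyperentropy *He*:

    Ex = x̄,   En = √(π/2) · mean|xᵢ − x̄|,   He = √|S² − En²|

For a climate factor in a mountain holding `Nᵢ` of the study's `N`
points, the single-factor sensitivity index is

    SI = Ex/(En + He) × Nᵢ/N × 100

TSI (temperature) and PSI (precipitation) sum to the comprehensive
index CSI; the contribution rate `Pᵢ = SIᵢ/CSI` classifies a mountain
as temperature- or precipitation-dominated when it strictly exceeds
50 %. A forward cloud generator produces droplet diagrams, DEM helpers
compute the terrain factors, and per-point NDVI trend slopes provide a
Spearman-correlation validation of the indices.

## Worked example

The package ships a synthetic-study generator with known ground truth,
so the full pipeline runs without any download. Six mountains, 25 sites
each (the last two arid/semi-arid, precipitation-dominant by
construction):

```r
library(cloudsens)
study <- generate_study(default_study_config(
  n_mountains = 6, n_sites = 150, n_points = 3000, n_arid = 2), seed = 1)
fit <- ulmdb_sensitivity(
  study$points, ndvi = study$ndvi,
  mountain_meta = study$truth[, c("mountain_id", "region", "moisture")])
summary(fit)
```

```
Cloud-model climate-sensitivity fit
  6 mountains, 150 fitted sites (0 excluded), N = 3000 points
  dominance: precipitation 2, temperature 4 

Per-mountain sensitivity indices (x100):
 mountain_id     tsi     psi     csi p_temp p_precip     dominance n_points
         M01  88.214  77.310 165.524 53.29%   46.71%   temperature      500
         M02 104.725  58.912 163.637 64.00%   36.00%   temperature      500
         M03 110.932  61.419 172.351 64.36%   35.64%   temperature      500
         M04 132.218  95.233 227.451 58.13%   41.87%   temperature      500
         M05  75.602 118.568 194.170 38.94%   61.06% precipitation      500
         M06  78.899 111.259 190.158 41.49%   58.51% precipitation      500
```

Every mountain's dominance class matches the generator's truth: the
four humid mountains come out temperature-dominated, the two arid ones
precipitation-dominated. TSI/PSI are the scaled `Ex/(En+He) × Nᵢ/N`
values; `p_temp`/`p_precip` are contribution rates.

The cloud estimator itself is a first-class object:

```r
backward_cloud(c(1860, 1950, 2110, 2040, 1880))
#> Normal cloud digest 
#>   Ex = 1968  En = 107.284  He = 15.4852   (n = 5)
simulate(cloud(1968, 107, 15), nsim = 1000, seed = 1)  # forward droplets
```

A published 28-mountain reference table is bundled for the index
arithmetic path:

```r
rec <- sensitivity_from_indices(nh_mountain_indices())
regional_summary(rec, "region")[, c("region", "n_mountains", "mean_csi")]
#>      region n_mountains mean_csi
#> 1    europe          11   7.7300
#> 2 east_asia          11   9.9090
#> 3     other           6   6.7778
```

East Asian mountains show the highest mean comprehensive sensitivity,
and 16 of the 23 humid mountains (≈70 %) are temperature-dominated
versus 4 of 5 arid mountains precipitation-dominated — the dry/wet
contrast the indices are designed to expose.

`run_pipeline()` chains simulate/ingest → weights → clouds → indices →
validation and writes the sensitivity CSV, regional-summary JSON,
validation table, config snapshot and a markdown report to a directory.

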