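# sistr — discriminating chronic heavy-metal stress in rice from LAI time series

Chronic heavy-metal contamination of paddy soil depresses rice growth — but
so do pests, disease and nutrient deficiency, and a single-season
vegetation-index map cannot tell them apart. `sistr` separates them using
the *temporal and spatial signature* of chronic contamination: it lasts the
whole season, it repeats almost identically in consecutive years (the
source sits in the soil), and it is spatially clustered. The package is for
agricultural remote-sensing practitioners screening paddy landscapes for
likely contamination from two years of multi-date LAI (or NDVI-derived
LAI) rasters.

## The method

Per rice pixel *i*, from two years of 20-step LAI series (5-day sampling,
DOY 160–255):

1. **Stress level** — DTW distance to an unstressed reference simulation
   for the year: `S_i = dtw(LAI_sample, LAI_i)`; min–max normalised per
   year over the rice pixels and averaged over the two years. The
   reference comes from a reduced daily crop model (Beer's-law light
   interception × radiation-use efficiency, thermal-time senescence) in
   which a stress factor `f ∈ [0, 1]` scales daily gross assimilation
   (`CVF_f = f · CVF`); `f` can be calibrated against sparse observations
   by particle swarm optimisation of the MSE cost.
2. **Temporal stability** — `TD_i = dtw(LAI_i,y1, LAI_i,y2)` between the
   pixel's own two years, complemented:
   `TS_i = 1 − (TD_i − TD_min)/(TD_max − TD_min)`. Chronic stress ⇒ low
   TD ⇒ high TS; single-season or year-varying stress ⇒ low TS.
3. **Spatial clustering** — Anselin's local Moran's I of TS on the rice
   mask (3×3 queen neighbourhood, rice neighbours only, row-standardised
   weights), min–max normalised.
4. **The index** — the geometric mean
   `SIST = (S_norm × TS × I_norm)^(1/3) ∈ [0, 1]`: high exactly where a
   pixel is strongly stressed, stressed the same way both years, and
   surrounded by equally stable pixels.

All DTW computations use the Sakoe–Chiba band `|j − (n/m)·i| ≤ r`
(default r = 3 samples = 15 days), which absorbs year-to-year
transplanting shifts that would contaminate aligned distances.

A synthetic-scene generator with known per-pixel truth (healthy /
heavy-metal / abrupt / nutrition regimes), land-cover post-processing
(small-object removal, confusion-matrix statistics) and broom-style
`tidy()`/`glance()`/`autoplot()` methods round out the toolkit. See the
methods vignette (`vignettes/sist-methods.Rmd`) for the models, parameter
defaults and design rationale.

## Worked example

```r
library(sistr)

sc <- generate_scene(scenario_config(seed = 1))   # 100 x 100 two-year scene
sc
#> Synthetic two-year scene: 100 x 100 grid, 8956 rice pixels
#> # A tibble: 4 × 2
#>   class           n
#>   <chr>       <int>
#> 1 abrupt        676
#> 2 healthy      7772
#> 3 heavy_metal   382
#> 4 nutrition     126

res <- run_pipeline(sc$scene, references = sc$references)
glance(res)
#> # A tibble: 1 × 7
#>   n_rice n_defined mean_s_final mean_ts mean_sist td_min td_max
#>    <int>     <int>        <dbl>   <dbl>     <dbl>  <dbl>  <dbl>
#> 1   8956      8956       0.0996   0.858     0.288   1.76   27.3

ev <- evaluate_discrimination(res, sc$truth)
ev$by_class
#> # A tibble: 4 × 5
#>   class           n mean_sist mean_ts mean_s_final
#>   <chr>       <int>     <dbl>   <dbl>        <dbl>
#> 1 abrupt        676     0.293   0.739       0.117
#> 2 healthy      7772     0.272   0.865       0.0738
#> 3 heavy_metal   382     0.566   0.936       0.528
#> 4 nutrition     126     0.426   0.856       0.294

round(c(auc = ev$auc, r = ev$r_contamination), 3)
#>   auc     r
#> 0.998 0.865
```

Reading the table: heavy-metal pixels combine a high mean stress level
(0.53 — strongly depressed canopy), the highest temporal stability (0.94 —
the depression repeats across years) and spatial clustering, so their mean
SIST (0.57) exceeds every other class. Abrupt single-season stress is
filtered by its low stability (0.74); nutrition stress is as chronic but
varies between years and is field-scattered, landing in between. Ranking
pixels by SIST separates heavy-metal pixels from all others with AUC 0.998,
and SIST correlates with the generator's latent contamination level at
r = 0.87.

`autoplot(res)` maps the component surfaces and the index;
`plot_lai_series()` draws per-pixel seasonal trajectories. A thin CLI over
the same functions lives at `inst/scripts/sist.R`
(`synth` / `run` / `dtw` / `accuracy` subcommands).

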