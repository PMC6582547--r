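# mwagg — moving-window aggregation of fine-grain environmental heterogeneity

Broad-extent ecological data (bird atlases, gridded range and abundance
products) are typically reliable only at coarse resolutions of 10 km or
more, while the environmental factors that drive them — land cover,
topography, microclimate — act at much finer scales. Aggregating a
fine-resolution predictor straight up to the response grain (taking the
variance or diversity of each whole coarse cell, *direct data aggregation*,
DDA) erases the within-cell spatial structure that the organism actually
experiences, a familiar face of the modifiable areal unit problem.

`mwagg` implements *moving-window data aggregation* (MWDA), which keeps that
structure by working in three steps:

1. **Define the analysis scales** — the predictor grain (resolution of the
   environmental raster), the response grain (resolution of the ecological
   data), and the *scale-of-effect*: the neighbourhood radius *x* at which
   the process responds to its environment, expressed as a Moore (square)
   window reaching *x* map units from the focal cell.
2. **Moving window** — evaluate a heterogeneity metric over the
   neighbourhood of every fine cell, yielding a fine-resolution surface of
   local heterogeneity at the process-relevant scale.
3. **Aggregate** — summarise that surface (mean or median) within each
   coarse response-grain cell.

Built-in metrics are Shannon evenness for categorical rasters,

    J' = -sum_i p_i ln(p_i) / ln(S),

with `p_i` the proportion of class *i* among the retained cells and `S` the
number of classes (optionally fixed by an explicit class universe, with
`J' = 0` when `S = 1`), and population variance, range and mean for
continuous rasters; arbitrary user reductions plug into the same engine.
The window engines are exact (summed-area tables, one table per land-cover
class) and resolve edges by torus wrapping.

The package also contains the machinery to study *when the scale-of-effect
is recoverable*: neutral-landscape simulation (spectral-synthesis fractional
Brownian surfaces whose roughness is set by a parameter in (0, 1], plus
weighted classification into land-cover classes), response simulation
`y = MWDA_w + N(0, sigma)` with sigma calibrated to percentiles of the MWDA
measure, univariate OLS fits compared by AIC, Spearman comparison of MWDA
against DDA, and a logit-transformed proportion regression for coarse
response data. See the methods vignette
(`vignettes/moving-window-aggregation.Rmd`) for the full model description
and design choices.

## Worked example

A fragmented versus a clumped four-class landscape (200 × 200 cells of
25 m), aggregated to 2.5 km response cells with Shannon evenness in a 100 m
neighbourhood:

```r
library(mwagg)
rough  <- classify(simulate_fbm(0.2, 200, 200, seed = 1, cell_size = 25),
                   c(0.4, 0.3, 0.2, 0.1))
smooth <- classify(simulate_fbm(1.0, 200, 200, seed = 1, cell_size = 25),
                   c(0.4, 0.3, 0.2, 0.1))

mwda <- winmove_agg(rough, window_spec(100), "shannon", grain = 2500)
mwda
#> <coarse_grid> 2 x 2 cells of 2500 map units
#>   MWDA, metric shannon_evenness, window radius 100
round(mwda$values, 3)
#>       [,1]  [,2]
#> [1,] 0.584 0.549
#> [2,] 0.538 0.544
round(nomove_agg(rough, "shannon", grain = 2500)$values, 3)
#>       [,1]  [,2]
#> [1,] 0.476 0.454
#> [2,] 0.431 0.453
```

In the fragmented landscape every 100 m neighbourhood mixes classes, so the
MWDA measure (≈ 0.54–0.58) sits above the whole-cell evenness. The clumped
landscape inverts the picture:

```r
round(nomove_agg(smooth, "shannon", grain = 2500)$values, 3)
#>       [,1]  [,2]
#> [1,] 0.634 0.641
#> [2,] 0.739 0.621
round(winmove_agg(smooth, window_spec(100), "shannon", grain = 2500)$values, 3)
#>       [,1]  [,2]
#> [1,] 0.347 0.309
#> [2,] 0.360 0.307
```

Whole coarse cells look diverse (DDA ≈ 0.62–0.74) because they contain
several large patches, but at the 100 m scale an organism mostly sits inside
a single patch (MWDA ≈ 0.31–0.36). The two measures disagree exactly where
within-cell spatial structure matters — which is the information MWDA
carries into a coarse-grain model and DDA discards.

Scale-of-effect selection on a coarse response table then works by fitting
the response against the MWDA measure at several candidate radii and taking
the AIC-minimal model (`select_scale()`), or, for a non-binomial proportion
index such as atlas occupancy, through `logit_proportion_model()`.

## Command line

A thin CLI wraps the same functions (`exec/mwagg`): `agg winmove` /
`agg nomove` for raster aggregation (ESRI ASCII grids in and out),
`simulate` for neutral-landscape bundles, `study run` / `study summarize`
for the full simulation study from a YAML configuration, and `fixtures` for
the worked-example rasters. Every run writes a `manifest.json` (command,
configuration, seed, versions) from which it can be reproduced.

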