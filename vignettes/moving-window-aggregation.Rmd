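---
title: "Moving-window aggregation: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Moving-window aggregation: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mwagg)
```

## The problem and the method

Ecological response data at broad extents are usually coarse: an occupancy
or abundance index per 10 km cell, say. Environmental predictors are often
far finer — 25 m land cover, 30 m elevation. When the scale at which an
organism responds to heterogeneity (its *scale-of-effect*, e.g. a foraging
neighbourhood of a few hundred metres) is much smaller than the response
grain, summarising each coarse cell directly (direct data aggregation, DDA)
measures heterogeneity at the wrong scale: a cell made of a few large
uniform patches scores as "diverse" even though no location in it is
locally diverse.

Moving-window data aggregation (MWDA) separates the two scales. For every
fine cell a heterogeneity metric is computed over the Moore neighbourhood
whose radius equals the scale-of-effect; the resulting fine-grain surface is
then summarised (mean by default, median optionally) within each coarse
cell. The coarse value is the *average local heterogeneity experienced at
the organism's scale*, not the heterogeneity of the bookkeeping unit.

Formally, with fine raster $z$, window half-width $h$ cells and metric $m$,

$$\mathrm{winmove}(z)_{ij} = m\bigl(\{z_{kl} : |k-i|\le h,\ |l-j|\le h\}\bigr),
\qquad
\mathrm{MWDA}_c = \frac{1}{|c|}\sum_{(i,j)\in c} \mathrm{winmove}(z)_{ij},$$

where $c$ ranges over coarse cells. DDA applies $m$ once to all fine cells
of $c$.

## Metrics

* **Shannon evenness** (categorical): $J' = -\sum_i p_i\ln p_i / \ln S$
  with $p_i$ the class proportions among retained cells. By default $S$ is
  the number of distinct classes *in the window*; passing `class_universe`
  fixes $S$ globally instead (appropriate when the class set is defined a
  priori, e.g. evenness of broadleaf versus coniferous forest). When
  $S = 1$ we define $J' = 0$, the limit of Shannon diversity as one class
  dominates. `include_classes` drops cells of all other classes before the
  proportions are formed — a window left with no retained cells yields a
  missing value rather than zero, because such a neighbourhood carries no
  information about the evenness of the retained classes.
* **Variance** (continuous) uses divisor $N$: the window is the complete
  population of its neighbourhood, not a sample from one.
* **Range** and **mean**, and arbitrary user reductions via
  `metric_spec("user_defined", fn = ...)`.

## Scales, units and geometry

All radii, cell sizes and extents are in map units (metres in the
examples). A window radius converts to a half-width in cells by
round-half-up; the conversion errors rather than silently degenerating to a
single-cell "window". Grids are row-major with array cell `[1, 1]` at the
top-left and the map origin at the lower-left corner of the extent, the
layout shared by common raster formats. Fine and coarse grids must tile
exactly (the coarse cell size an integer multiple of the fine size, the
extent a whole number of coarse cells); partial coverage is out of scope.

Two edge policies are available in `winmove_agg()`. `"whole"` (default)
computes the window surface across the entire fine raster with torus
padding of the full extent, so neighbourhoods straddle coarse-cell
boundaries as they do on a real contiguous study region. `"per_landscape"`
treats every coarse cell as an independent landscape with its own torus —
the correct choice when coarse cells are simulated independently, as in the
simulation study below. On a single landscape the two coincide.

Missing cells propagate conservatively: any window containing a missing
fine cell is missing (except for the class-filtering rule above), and the
coarse summary skips missing window values.

## Numerical implementation

Window metrics are computed for every fine cell (dense, never strided) with
summed-area tables on the torus-padded grid: sums and sums of squares for
mean and variance, one table of counts per land-cover class for evenness.
Variance is computed after centring on the grand mean, which keeps the
table well conditioned on large windows; the engines agree with a naive
double-loop reference to better than $10^{-12}$ on the test suite's random
grids. Range uses an explicit shift-stack of window offsets, and
user-defined metrics fall back to a per-cell loop.

## The neutral-landscape generator

The simulation study needs landscapes whose spatial autocorrelation is
controlled by a single knob. `simulate_fbm()` synthesizes Gaussian fields in
the Fourier domain with power-spectrum exponent $\beta$ and min–max rescales
each landscape to $[0,1]$. The autocorrelation parameter $d \in (0,1]$ is
interpreted as the variogram exponent of a fractional Brownian surface
($\gamma(r) \propto r^{d}$, Hurst exponent $d/2$): values near zero give
rough, fragmented, essentially uncorrelated surfaces, and one gives smooth,
clumped landscapes. Because a discrete, finite, stationary spectral field
is only an approximation to an intrinsic fractional Brownian surface, the
mapping $\beta(d) = 0.5347 + 4.1861\,d - 1.6817\,d^2$ was calibrated once by
matching the lag-1 Moran's I of synthesized surfaces to exact fractional
Brownian surfaces (simulated by Cholesky factorisation of the intrinsic
covariance on 40–64 cell grids) at $d \in \{0.1, 0.25, 0.5, 0.75, 1\}$. The
surrogate reproduces the rough-to-smooth gradient and the window-variance
profiles of the exact surfaces at both ends of the range; it does not claim
distributional identity, and the test suite validates it by the Moran's-I
ordering property rather than by distribution.

Categorical landscapes are produced by `classify()`: cumulative intervals
of a weight vector cut the continuous values, half-open on the right with
the last interval closed at 1 (so with weights $(0.5, 0.25, 0.25)$ a value
of exactly $0.5$ falls in class 1). Breaks apply to the raw values, not to
rank quantiles, so realised class proportions deviate from the weights on
autocorrelated surfaces — intentional, as it mirrors how patchy real
landscapes deviate from target class budgets. Per-landscape weight vectors
are drawn from a symmetric Dirichlet(1) (uniform on the simplex) and sorted
descending; this sampling law is an explicit modelling choice — any
exchangeable law on the simplex would serve — and both the class count and
the weights are exposed to the caller.

## The simulation study

`run_simulation_study()` measures two things: how much information MWDA
retains beyond DDA (Spearman correlation between the two measures across
coarse cells), and whether the scale-of-effect can be recovered from a
coarse response by model selection.

Five autocorrelation scenarios set the range the per-landscape parameter is
drawn from: `none` (0.1 for every landscape), `low_varied` (0.1–0.5),
`varied` (0.1–1), `high_varied` (0.5–1) and `high` (1 for every landscape).
Each landscape stands for one coarse response cell and is its own torus.
Four window sizes cover 1, 4, 9 and 49% of the coarse-cell area (window
side 10, 20, 30 and 70% of the cell side). The metric is population
variance for continuous landscapes and Shannon evenness (per-window $S$)
for categorical ones.

For each replicate dataset, true window $w$ and noise level, a response is
simulated as $y_w = \mathrm{MWDA}_w + \varepsilon$,
$\varepsilon \sim N(0, \sigma)$, with $\sigma$ an empirical percentile of
the MWDA values pooled across replicates within the scenario × window
combination: the 1st percentile ("low" noise), the 10th ("moderate") or the
median ("high"). Percentiles use the linear-interpolation definition. Each
of the four candidate models $y \sim \mathrm{MWDA}_{w'}$ is fit by OLS and
compared by $\mathrm{AIC} = n\ln(\mathrm{RSS}/n) + 2k$ with $k = 3$;
additive likelihood constants are dropped because they are shared by every
candidate. Exact AIC ties break toward the smaller radius, a deterministic
and conservative rule. Since every candidate has the same $k$ and $n$, AIC
and BIC always rank candidates identically in this design — the test suite
asserts this consequence. The small-sample correction (AICc) is not
applied; with a shared $k$ it too would leave rankings unchanged.

Correct-selection percentages are reported per scenario × window × noise
combination and also averaged across combinations per noise level (both
views are in `summarize_study()`), together with the $R^2$ of the
correct-scale model.

### Study sizes

The default geometry is 100 × 100 fine cells per landscape, 50 landscapes
per dataset and 20 replicate datasets (40 in the dedicated worst-case run),
with window radii held at the same 1/4/9/49% area fractions — a desk-scale
design that preserves the ratio structure the results depend on. Two
consequences of this scaling are worth stating. First, $R^2$ of the
true-scale model is a population quantity (signal variance against
$\sigma^2$) and does not depend on the number of coarse cells. Second,
correct-selection rates *do*: AIC selection among fixed-dimension
candidates is consistent in the number of coarse cells, so recovery
percentages at 50 cells are conservative relative to studies with hundreds
or thousands of response cells. Scenarios in which every landscape shares
the same autocorrelation parameter (`none`, `high`) concentrate the MWDA
measure tightly across landscapes; with $\sigma$ calibrated to the
*level* (a percentile of the pooled values) rather than the *spread* of
the measure, the signal-to-noise ratio in those scenarios is intrinsically
small and selection there is hard at any desk scale. The categorical arm
is easier in this regard because per-landscape class weights add genuine
between-landscape variation in evenness.

### What the generator does and does not emulate

The simulated landscapes are isotropic Gaussian(-derived) surfaces with
independent coarse cells, classified by global value breaks. Real
landscapes are anisotropic, exhibit dependence *between* neighbouring
coarse cells, mix gradient- and patch-structured variables, and carry
classification error and missing data. Passing tests on the simulated grid
therefore demonstrates the correctness of the aggregation and selection
machinery and the qualitative regimes in which scale recovery succeeds or
fails — not that a particular field dataset will identify its
scale-of-effect.

## Regression for coarse proportion responses

`logit_proportion_model()` supports the typical downstream analysis: a
non-binomial proportion index (e.g. fraction of surveyed subcells occupied)
is logit-transformed and modelled by ordinary linear regression with
optional two-way interactions, comparing candidate heterogeneity measures
by AIC/BIC. Proportions at exactly 0 or 1 must be adjusted before the
transform; the default is the empirical squeeze
$y' = (y(n-1) + 0.5)/n$, with a fixed clamp into $[\varepsilon,
1-\varepsilon]$ ($\varepsilon = 0.005$) as the alternative. Both are
standard; the choice is exposed because it slightly affects coefficients
when boundary values are common.

## Degenerate inputs and tie-breaks, summarised

* Window radius below half a cell, windows larger than the landscape,
  non-nesting grains, torus padding wider than the grid: errors, never
  silent truncation.
* Constant vectors in the Spearman comparison: `NA` (the correlation is
  undefined), not an error.
* Empty value collections after filtering: missing values, skipped by
  coarse summaries; all-missing coarse cells stay missing.
* AIC ties: smaller radius wins. Classification at interval boundaries:
  right-open intervals, last closed.
* All stochastic components (surfaces, weights, datasets, responses) are
  reproducible from integer seeds; replicate datasets derive their seeds
  from the base seed so each replicate is independently regenerable.

## Known limitations

Reprojection, non-nested or ragged grids, multi-band rasters, circular or
kernel-weighted windows, and spatially correlated regression errors are out
of scope. Raster input/output is plain-text ESRI ASCII grid; values, cell
size, origin and missing cells survive the round trip, but coordinate
reference systems are not represented. The spectral landscape surrogate is
stationary within a landscape; it does not reproduce the realisation-scale
wander of intrinsic fractional Brownian motion, which slightly narrows the
spread of whole-landscape summaries at fixed autocorrelation.
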