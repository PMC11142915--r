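---
title: "Assessing persistent forest-structure change across the boreal and taiga-tundra ecotone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing persistent forest-structure change across the boreal and taiga-tundra ecotone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(borealshift)
```

## The question and the approach

High-latitude North America is shifting toward a greater presence of trees
and shrubs, most conspicuously in the taiga-tundra ecotone (TTE) — the
transitional zone between closed boreal forest and treeless tundra. Whether
that shift persists depends on future climate, on the current state of
forest structure, and on recent site history. borealshift implements a
landscape-scale assessment that links three independent views of structure:

1. **Current canopy height** from spaceborne-lidar segment observations of
   RH98 (the 98th-percentile relative height of returned photons, a
   top-of-canopy proxy), quality-filtered and gridded.
2. **Potential future canopy height** from a bioclimatic random-forest
   model applied to GCM-ensemble climate projections across 4 SSP scenarios
   and 4 twenty-year periods through 2100, differenced against the same
   model's current prediction.
3. **Recent canopy-cover history** as per-pixel ordinary-least-squares
   trends in a multi-decadal annual tree-canopy-cover (TCC) series.

Both change signals are summarised to catchment-scale landscape medians
across a 6-class forest-gradient stratification and cross-tabulated into a
9-class taxonomy of recent-by-future change direction.

Real continental inputs (lidar archives, downscaled climate grids, annual
TCC maps, catchment polygons) are deliberately out of scope: the package
ships a synthetic-data generator that emulates their schemas, value ranges
and statistical structure with known ground truth, so every stage is
exercised and verified at desk scale.

## Lidar filtering and gridding

Segment observations carry quality attributes from which seven retention
predicates are evaluated; a point is retained only if it passes all seven:

| predicate | rule |
|---|---|
| strong beam | `beam == "strong"` |
| snow-free | `!snow_flag` |
| cloud-free | `!cloud_flag` |
| night / low light | `solar_elevation < 5` degrees |
| valid height | `rh98 <= 30` m and at most the landcover-class maximum |
| reference agreement | `height_diff_ref < 25` m |
| geolocation | `geoloc_error < 2.5` m |

Boundary semantics follow the inequality directions literally: strict `<`
everywhere except the inclusive 30 m validity bound. Removal counts
attribute each rejected point to *every* predicate it fails, so the counts
are diagnostics, not a partition. Landcover-specific height maxima are a
user-editable map (`filter_thresholds()`), defaulting to the 30 m bound for
every class; unknown classes either fall back to that bound or are
rejected, at the caller's choice.

After filtering, a canopy-height flag zeroes assumed-erroneous heights
(keeping genuinely unvegetated terrain in the training data without
admitting spurious tall returns over tundra and barren ground), and a 30 m
cap truncates the remaining high-end outliers. The order
filter → flag → cap is the package default; both flag and cap are
idempotent, so re-running a stage is harmless. The flag itself is consumed
as an input column — the package does not invent a rule for constructing
it, since its derivation is a data-production step upstream of this
pipeline.

Gridding uses a **maximum-aggregation rule**: each 1 km cell takes the
maximum RH98 over the points inside it, estimating the tallest canopy
present. Cells are half-open (`[x0, x1) × [y0, y1)`): a point exactly on a
shared edge belongs to the cell to its east or south, a deterministic
convention matching common raster registration. Empty cells are nodata;
points outside the grid are counted and skipped.

## The height model

The training table links every occupied height cell to 22 predictors: 3
soil variables (permafrost probability, depth to bedrock, organic carbon
density at 0 m — held constant through time, so they act as fixed site
constraints) and the 19 bioclimatic variables derived from monthly
temperature and precipitation. An 80/20 uniform random split reserves a
held-out test set. The regressor is a random forest limited to 100 trees;
only the tree count is pinned — the remaining hyperparameters are the
library defaults and are exposed to the caller, since nothing in the method
depends on them. Fitting is single-threaded and seeded, so results are
bit-reproducible.

Evaluation reports test R² (`1 − SSE/SST`), bias
(`mean(predicted − reference)`, in metres) and a two-sided one-sample
t-test of zero mean error for the bias p-value — the conventional choice
when no specific test is mandated. When the reference is constant the R²
is undefined and reported as missing rather than coerced.

Predictor influence is measured by **permutation importance** on the
held-out set: the mean increase in test MSE when one predictor's column is
shuffled, averaged over 10 permutations by default, with ties broken
alphabetically so rankings are deterministic. Under the synthetic
generative law (below), annual mean temperature must and does rank first;
this mirrors the dominance of temperature over precipitation and soil in
climate-limited northern forests. Correlated predictors share importance
under permutation — a known property, which is why the synthetic law keeps
the causal temperature variable only moderately correlated with the other
temperature-family layers.

A deliberate property of a bagged regressor is reduced dispersion:
predictions average many trees, so the predicted-height distribution has
no more variance than the reference distribution and extremes are
attenuated. Differencing future predictions against *the same model's*
current prediction (rather than against observations) cancels much of the
resulting level bias, which is exactly why the pipeline differences before
any spatial aggregation.

## Scenario ensembles

For each of the 16 scenario keys (4 SSPs × 4 periods) the model is applied
to every available GCM's covariate stack and the predictions are reduced
pixel-wise to the **ensemble median** — robust to a single eccentric model
and standard practice for CMIP-style ensembles. Nodata entries are ignored
rather than propagated, so a pixel is lost only when every GCM is missing
there; a per-pixel count of contributing GCMs is kept for audit. With an
even number of values the median is the mean of the two central values.
Missing GCM-scenario combinations simply shrink that key's ensemble
(matching the 7–9 models per scenario typical of downscaled archives); a
key with no GCM at all is a hard error. Differences are computed at 64-bit
in memory; file export quantises to 32-bit floats.

## Canopy-cover trends

Per pixel, cover is regressed on calendar year by ordinary least squares;
nodata years are omitted pairwise. The p-value is the two-sided t-test of
the slope on `n − 2` degrees of freedom. Slope units (% cover per year) are
invariant to translating the year axis, so the calendar year is used
directly as the regressor. Pixels with fewer than `min_obs = 10` finite
years are masked: the cutoff rarely binds on a complete 37-year series but
guards against spurious two-or-three-point slopes in gappy data. The
default series spans 1984–2020 inclusive (37 annual maps); the span is
configurable.

## Landscape summaries and the 9-class taxonomy

Landscape medians use cell-centre containment: a cell contributes to the
polygon containing its centre, the same half-open rule as gridding, making
zonal statistics exactly consistent with an enumeration oracle.
(Exact-area weighting would change little at these landscape-to-cell size
ratios and is left as a possible extension.) Landscape areas are computed
in the grid's local equal-area frame, so area equals cell count times cell
area.

A landscape's median change is classified as `-`, `0` or `+` against a
**stable band**: `0` iff `|median| <= band`, boundary inclusive. The band
defaults to 0.5 m for height differences and 0.05 %/yr for TCC slopes. A
zero-width band would make the stable class measure-zero, contradicting
the premise that some landscapes genuinely are stable; the chosen widths
are small against the signals the generator plants (several metres of
height change at the cold edge; ±0.3 %/yr cover trends) yet wide enough to
absorb estimation noise in landscape medians. Both are configurable and
recorded in the output. Enlarging the band can only move landscapes into
`0`, never directly between `+` and `-` — a monotonicity the tests verify.

The cross-tabulation always emits all 9 recent × future classes, including
zero-area ones, with areas in km² and proportions relative to the **full
domain area** (all landscapes, classified or not); landscapes missing
either median are reported separately as unclassified. Distribution
summaries per gradient class use standard boxplot conventions: median,
quartile hinges (type-7 quantiles), and whiskers at 1.5 × IQR beyond each
hinge.

The two non-TTE gradient classes follow the positional rule of the
gradient scheme — interior boreal landscapes sit south of (warmer than) the
TTE, tundra landscapes north of (colder than) it — which is how the
synthetic generator assigns bands; when consuming real polygons the class
is an input attribute.

## The synthetic study system

The generator's defaults define the study conditions; they are not tuning
knobs. All draws flow from one master seed through independent named
substreams, so adding draws to one stage never perturbs another, and a
fixed configuration reproduces every product bit-for-bit.

**True height law.** `height = hmax · logistic(k · (T − t0)) + b_p · P_wet
− c_pf · permafrost`, clipped at 0, with defaults `hmax = 20` m,
`k = 0.45` per °C, `t0 = −2` °C, `b_p = 0.004` m/mm, `c_pf = 3` m. The
logistic makes temperature dominate the variance (matching the expected
importance ranking) and saturate in the warm interior — which is what
concentrates *future height gains* in the cold transitional zone, where
the law is steepest, rather than in the already-tall boreal interior.

**Covariates.** Annual mean temperature runs from −10 °C at the north edge
to +4 °C at the south plus smooth spatial noise; the other bioclim layers
are built as plausible affine functions of the temperature and
precipitation fields plus independent smooth fields (correlation length
~12 cells, a free parameter of the generator, not an inference target).
Permafrost probability falls logistically with temperature. Smooth fields
are sums of 12 random cosine modes — cheap, seeded, and mean-zero.

**Futures.** Warming at a pixel is `(w0 + g_GCM) · rank(SSP) ·
index(period)` with `w0 = 0.4` °C and a per-GCM smooth perturbation
`g_GCM` bounded below `0.75·w0`, so warming is strictly positive and
strictly monotone in both severity rank and period at every pixel — about
+6.4 °C under the severest scenario by 2081–2100, a plausible high-Arctic
magnitude. Precipitation layers scale up by ~1.2 % per rank × period unit.
Soil layers are identical in every stack.

**Lidar points.** 10,000 uniformly placed segments by default; RH98 is the
law at the containing cell plus N(0, 0.5 m) noise. Each of the seven
predicates is failed by an independent Bernoulli draw at its configured
fraction (10 % weak beams, 5 % snow/cloud/solar, 2 % for the height-range,
reference-difference and geolocation checks — roughly the ordering by
which real quality screens remove data), and the truth table records every
draw, so filtering can be checked point-for-point against ground truth.

**TCC series.** Planted slopes interpolate from +0.3 %/yr at the north
edge to −0.05 %/yr at the south with 0.05 %/yr pixel spread, plus N(0,
2 %) annual noise, clipped to [0, 100] — positive cover trends concentrated
at the cold margin, weak or stable cover in the interior, which is the
recent-history pattern the assessment links to.

**Landscapes.** Rectangular tiles (default 5 × 6 = 30) in latitudinal
bands, one gradient class per band from tundra (north) to interior boreal
(south). Rectangles are sufficient to verify the zonal logic; real
catchment geometry adds nothing to the computations being tested.

**What passing tests do and do not show.** The generator produces smooth,
stationary fields, spatially uniform warming ramps, linear cover trends and
independent noise. It does not emulate disturbance (fire, harvest, insect
outbreaks), orbital sampling geometry, seasonal compositing, non-linear or
non-stationary climate responses, spatially correlated observation error,
or real catchment topology. Green tests therefore demonstrate that the
pipeline's *computations* are correct and internally consistent — not that
the fitted model or its projections are accurate for real boreal data.

## Problem sizes and numerical choices

The shipped configuration runs the full pipeline on a 50 × 50 grid of 1 km
cells with 3 GCMs (48 future stacks), 10,000 points and a 37-year TCC
series — about ten seconds end to end — and the model-recovery checks use
75 × 75 grids (5,625 cells, at least 5,000 training cells) over five seeds.
These sizes give stable statistics while keeping a full verification run
interactive.

Noiseless TCC series are detected by a zero residual sum of squares; their
p-value is defined as 0 for a non-zero slope and 1 for a zero slope rather
than dividing by a zero standard error. Zonal medians and ensemble medians
use the standard even-count convention (mean of the central pair).
Training rows with any missing covariate are dropped and counted rather
than imputed. Co-registration of grids is checked exactly; nothing is
silently resampled.

## Known limitations

- Trend p-values assume independent annual errors; autocorrelation-robust
  variants are out of scope.
- Permutation importance splits credit among correlated predictors; the
  ranking is interpreted only for the dominant variable.
- Cell-centre zonal containment slightly misweights cells straddling
  polygon edges; negligible at the intended landscape-to-cell size ratio.
- The stable-band widths are conventions, not estimates; conclusions about
  the stable class should be checked against a range of bands.
- No spatial cross-validation: the 80/20 split is random, so spatial
  autocorrelation can flatter the held-out R² on smooth fields — one more
  reason the synthetic R² is not evidence about real-data skill.
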