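# borealshift

Landscape-scale assessment of persistent forest-structure change across the
North American boreal forest and the taiga–tundra ecotone (TTE).

High-latitude forests are shifting toward more, and taller, woody
vegetation, most visibly in the transitional landscapes between closed
boreal forest and tundra. borealshift is for ecologists and remote-sensing
analysts who want to ask whether such a shift will *persist*: it links the
**current** state of forest structure (quality-filtered spaceborne-lidar
canopy heights), its **recent history** (multi-decadal trends in annual
tree canopy cover), and its **projected future** (a climate-driven canopy
height model applied to GCM-ensemble scenarios through 2100), and
summarises the agreement of recent and future change direction landscape
by landscape.

## The method

1. **Lidar filtering & gridding.** ATL08-style RH98 segment observations
   are retained only if they pass seven quality predicates (strong beam;
   snow-free; cloud-free; solar elevation < 5°; RH98 ≤ 30 m and below the
   landcover-class maximum; height difference from reference elevation
   < 25 m; vertical geolocation error < 2.5 m). A canopy-height flag zeroes
   assumed-erroneous heights, a 30 m cap truncates outliers, and points are
   gridded at 1 km by a *maximum*-aggregation rule (the cell's value is the
   tallest canopy observed in it).

2. **Height model.** A random-forest regression (100 trees) of gridded
   height on 22 predictors — 3 soil variables held constant through time
   and 19 bioclimatic variables — trained on 80 % of cells, evaluated on
   the held-out 20 % (R², bias with a t-test), and ranked by permutation
   importance.

3. **Scenario ensembles.** The model predicts potential canopy height for
   every available GCM under 4 SSPs × 4 twenty-year periods (2021–2100);
   per scenario, predictions reduce to the pixel-wise ensemble **median**,
   and the current prediction is subtracted, giving 16 difference maps
   `Δh = h_future − h_current` that normalise away model-level bias.

4. **Recent trends.** Per pixel, annual tree canopy cover (1984–2020) is
   regressed on year by ordinary least squares, returning slope (%/yr) and
   a two-sided p-value on n − 2 degrees of freedom.

5. **Landscape taxonomy.** Both change signals are summarised to landscape
   (catchment) medians, classified as decreasing / stable / increasing
   (`−`, `0`, `+`) against a stable band (defaults 0.5 m, 0.05 %/yr), and
   cross-tabulated into the 9 recent × future classes with equal-area
   accounting in km² and as proportions of the domain.

Real continental archives are out of scope; a synthetic-data generator
(`gen_config()`, `gen_covariate_stacks()`, `gen_canopy_points()`,
`gen_tcc_series()`, `gen_landscapes()`) emulates their schemas and
statistical structure with known ground truth so the whole pipeline runs
and is verified at desk scale. See the vignette
(`vignettes/structure-change-pipeline.Rmd`) for the model, the generator's
assumptions, and every numerical convention.

## Worked example

```r
library(borealshift)

cfg <- gen_config(seed = 1)          # 50 x 50 km domain, 3 GCMs, 10,000 points
run <- run_change_assessment(cfg)    # the full pipeline, ~10 s

run$filtered$n_retained              # 7223 of 10000 points pass all 7 filters
run$gridded$n_occupied               # 2383 occupied 1 km cells
run$metrics                          # held-out R2 = 0.93, bias = 0.12 m (p = 0.20)
head(run$importance, 3)
#>                         predictor importance        sd rank
#> 1   bio01_annual_mean_temperature  11.563419 0.8364196    1
#> 2          permafrost_probability   4.984311 0.3472157    2
#> 3 bio10_mean_temp_warmest_quarter   1.715471 0.1767013    3
run$change_table                     # SSP245, 2081-2100 by default
#> <change_class_table> recent x future change directions
#>  recent future class area_km2  n proportion
#>       -      -   -/-        0  0      0.000
#>       0      -   0/-        0  0      0.000
#>       +      -   +/-        0  0      0.000
#>       -      0   -/0        0  0      0.000
#>       0      0   0/0      160  2      0.064
#>       +      0   +/0       80  1      0.032
#>       -      +   -/+        0  0      0.000
#>       0      +   0/+      600  7      0.240
#>       +      +   +/+     1660 20      0.664
#> unclassified: 0.0 km2 (0 landscapes); domain: 2500.0 km2
```

Reading the output: annual mean temperature dominates the height model, as
it must under the generator's saturating temperature–height law; the mean
predicted height change under the middle-of-the-road scenario by 2081–2100
is ~2.9 m, concentrated at the cold northern edge where the law is
steepest; and the modal change class is `+/+` (recent cover gain *and*
projected height gain), carried by the transitional (TTE) landscape bands —
the signature of a persistent shift concentrated in transitional forests,
while interior boreal landscapes stay in the stable classes.

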