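# wormyield

Earthworms are soil ecosystem engineers: they restructure soil, accelerate
organic-matter cycling and nutrient mineralization, and measurably increase
aboveground plant biomass — by about 23.3% on average in mesocosm
add/exclusion experiments. `wormyield` turns that experimental evidence into a
spatial attribution: given gridded layers of earthworm abundance, soil
properties, crop yields, harvested areas and fertilizer rates, it estimates
how much of observed crop production is attributable to earthworms, per grid
cell, per crop, per region and globally.

It is written for agroecologists and geospatial analysts who want a tested,
reusable implementation of this multiplicative upscaling approach — either to
apply it to real raster layers or to study its behavior on synthetic data
with a known implanted truth.

## The model

The fractional yield effect of earthworms in grid cell *i* for crop *k* is

> *E*<sub>*i,k*</sub> = *c*<sub>*i,k*</sub> · *p*<sub>*i*</sub> · *t*<sub>*i*</sub> · *n*<sub>*i,k*</sub> · *a*<sub>*i*</sub> · 0.233

where *c*, *p*, *t*, *n* are dimensionless coefficients for crop type
(cereal / legume), soil pH class (< 5.6 / 5.6–7.0 / > 7.0), soil textural
class (sandy / loamy / clayey) and crop-specific N application rate
(≤ 30 / > 30 kg N ha⁻¹ yr⁻¹), and *a* = 0.1032 · abundance<sup>0.409</sup> is
a continuous power-law response to earthworm abundance (individuals m⁻²).
Each coefficient is a category's meta-analytic effect size divided by the
sample-size-weighted mean effect of its factor, so coefficients average to 1
and rescale the 23.3% baseline up or down. Observed yields are treated as the
with-earthworm state, so the counterfactual yield is
*y*<sub>obs</sub> / (1 + *E*) and the relative contribution of earthworms to
observed production is *E* / (1 + *E*).

Per-crop contributions (tonnes) are yield differences times harvested area;
cross-crop effect maps weight by harvested area per cell; regional summaries
sum production over a region-identifier grid (eight continental-scale
agricultural regions by default).

## Worked example

```r
library(wormyield)

# 1. Reconstruct the coefficient table from the shipped effect sizes
co <- coefficient_table()
head(co, 3)
#>                factor      category coefficient weighted_mean_effect_percent
#> crop_type.1 crop_type Cereal grains   1.2711725                     24.70947
#> crop_type.2 crop_type       Legumes   0.3719222                     24.70947
#> soil_ph.1     soil_ph           Low   1.2345524                     27.07864

# 2. Generate a 100 x 100 synthetic world with an implanted truth and
#    run the full pipeline on its observed yields
tw  <- generate_with_truth(world_config(seed = 7))
run <- run_pipeline(tw$world)
print(run)
#> <worm_run> 6 crops, mode counterfactual_division, denominator analyzed
#>  region crop_group observed_t counterfactual_t contribution_t contribution_pct
#>  Global     cereal   58053733         52795377      5258355.7         9.057739
#>  Global     legume    9108060          8851271       256789.2         2.819362
#>  Global        all   67161793         61646649      5515144.9         8.211730

# 3. The pipeline recovers the implanted regional truth exactly
m <- merge(tw$truth, run$summary, by = c("region", "crop_group"),
           suffixes = c(".truth", ".est"))
max(abs(m$contribution_t.est - m$contribution_t.truth) /
      pmax(m$contribution_t.truth, 1))
#> [1] 1.516791e-15
```

In this synthetic world earthworms account for about 9.1% of cereal and 2.8%
of legume production (5.5 Mt of the 67 Mt total): the cereal/legume gap
follows directly from the crop-type coefficients (1.271 vs 0.372), and the
absolute numbers are properties of the synthetic yield and area
distributions, not estimates for the real world.

## Command line

A thin wrapper over the same functions ships at `inst/cli/wormyield.R`:

```sh
Rscript inst/cli/wormyield.R coefficients --out coefficients.csv
Rscript inst/cli/wormyield.R synth --out world/ --truth --seed 7
Rscript inst/cli/wormyield.R run --config run.yaml
Rscript inst/cli/wormyield.R summarize --run out/ --world world/ --denominator all
```

Rasters are read and written as plain-text ESRI ASCII grids (`.asc`) with an
explicit nodata value; category grids carry a sidecar CSV legend. Every run
writes a manifest recording the mode, parameters and masked-cell counts.

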