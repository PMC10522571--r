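---
title: "Methods: attributing crop production to earthworms on gridded layers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: attributing crop production to earthworms on gridded layers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormyield)
```

## The model and its assumptions

Mesocosm experiments that add or exclude earthworms report an average
increase of 23.3% in aboveground plant biomass, with the size of the effect
varying by crop type, soil pH, soil texture, nitrogen input and earthworm
abundance. `wormyield` upscales this evidence spatially with a multiplicative
model: the fractional yield effect in cell $i$ for crop $k$ is

$$E_{i,k} = c_{i,k}\, p_i\, t_i\, n_{i,k}\, a_i \times 0.233$$

with $c, p, t, n$ the category coefficients for crop type, pH class,
textural class and crop-specific N-rate class, and
$a_i = 0.1032 \cdot x_i^{0.409}$ the continuous response to earthworm
abundance $x_i$ (individuals m$^{-2}$).

The model inherits three structural assumptions. First, **additivity on the
multiplicative scale**: the factors act independently, with no interaction
terms — the meta-analytic evidence does not resolve interactions. Second,
**short-term effects only**: the mesocosm evidence captures nutrient- and
growth-mediated benefits, not long-term gains via erosion control or water
dynamics, so the model says nothing about them. Third, a **continuous
abundance response** instead of abundance categories: most cells on global
earthworm maps fall below the 100 individuals m$^{-2}$ threshold of the
lowest experimental category, so a power law through the origin — near-zero
effect at a few individuals per square metre — is the conservative choice.

### Coefficients from effect sizes

Each factor's categories come with meta-analytic sample sizes $n_j$ and
percent effects $e_j$. The factor's weighted mean effect is
$\bar e = \sum_j n_j e_j / \sum_j n_j$, and category $j$'s coefficient is
$e_j / \bar e$, so the sample-size-weighted mean of the coefficients is 1 by
construction (a shipped test asserts this). Grasses are a special case: they
have no usable global crop layer, so they receive no coefficient, but their
154 data points still inform the crop-type mean — dropping them would
silently inflate the cereal coefficient. This is encoded by the
`applies_to_map` flag in the effect-size table.

The shipped table (`inst/extdata/effect_sizes.csv`) is a transcription of the
published per-category effect sizes. Its internal consistency is pinned by
unit tests: the per-factor sample-size totals (302, 250, 178, 208), the
weighted means (24.71, 27.08, 27.35, 17.74) and all ten printed coefficients
are reproduced to the printed precision. Coefficient arithmetic always uses
the unrounded weighted means; the rounded published values appear only in
test tolerances (±0.005 on means, ±0.001 on coefficients).

### From effect to contribution

The published phrase "yields with and without earthworm impact" leaves open
whether observed yields already contain the earthworm benefit. The package
default, `counterfactual_division`, says yes: observed yield is the
with-earthworm state and the counterfactual is $y_{obs}/(1+E)$, making the
relative contribution to observed production exactly $E/(1+E) \in [0, 1)$.
This matches the framing of contributions as a share of *current* production
and is the convention under which the synthetic known-truth recovery is an
algebraic identity. The alternative, `forward_multiplication`
($y_{with} = y_{obs}(1+E)$), is selectable and recorded in every run
manifest. The two conventions give contributions that differ by a factor of
$(1+E)$ per cell, which matters at the larger effect sizes.

Similarly, the "% of total" denominator is ambiguous about cells that lack
earthworm data. Default (`denominator = "analyzed"`): such cells are excluded
from numerator and denominator alike, mirroring the omission of cells without
earthworm observations. The alternative (`"all"`) divides by all observed
production; it never increases the reported percentage.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| baseline effect | 0.233 | fraction | mean biomass increase across experiments |
| abundance prefactor, exponent | 0.1032, 0.409 | — | published best fit; kept even if a user refits |
| pH class bounds | 5.6, 7.0 | pH | boundaries belong to Medium, matching the interval notation "(5.6–7.0)" with strict Low/High inequalities |
| texture bounds | sand > 70%, clay > 35% | mass % | exceedance thresholds; both cannot hold when sand + clay ≤ 100, so the classes partition the simplex |
| N-rate bound | 30 (inclusive Low) | kg N ha⁻¹ yr⁻¹ | ≤ 30 is the low-input class |
| depth weights | 5, 10, 15, 30, 40 | cm | thicknesses of the standard 0–5, 5–15, 15–30, 30–60, 60–100 cm soil intervals |

The soil depth weighting deserves a note: "weighted average of the top five
layers" does not state the weights, so thickness weighting is the documented
default, with equal weighting obtainable by passing a uniform stack. When
some layers are missing in a cell, weights are renormalized over the
available layers (`renormalize = TRUE`), consistent with the
exclude-missing philosophy used in upscaling; `renormalize = FALSE` gives the
all-or-nothing alternative.

## Numerical and convention choices

* **Grid conventions.** Cell-center registration, north-up rows,
  longitude–latitude axes, cell size in arcminutes. These are fixed because
  nothing upstream states them; `align_check()` enforces that all layers in a
  computation share shape, origin and cell size exactly.
* **Missing data.** `NA` is the single missing representation; every operator
  propagates it and none fabricates values in masked cells. Block upscaling
  (`upscale_mean`) averages the valid cells of each block, returns missing
  for all-missing blocks, and pads non-divisible grids with missing cells at
  the south/east edges rather than erroring — the behavior of common raster
  aggregators.
* **Degenerate inputs.** Zero abundance gives exactly $E = 0$ (power law
  through the origin). Zero harvested area contributes zero tonnes and is
  excluded from area weighting. A factor whose weighted mean effect is zero
  has no defined coefficients and errors. Negative user-supplied coefficients
  are clamped at $E = 0$ with a warning; the shipped coefficients are all
  positive, so the clamp is unreachable by default.
* **Power-law fitting** uses ordinary least squares on
  $\log m = \log k + b \log x$ — the fitting procedure behind the published
  parameters is not named, and log–log OLS recovers noiseless power-law data
  to numerical precision (a test cross-checks the noisy case against a
  brute-force grid search over the exponent).
* **Raster I/O** is the plain-text ESRI ASCII grid format with an explicit
  `NODATA_value` mapping one-to-one onto the missing mask, plus CSV legends
  for category grids. Values are written at full double precision, so
  write–read round trips and rerun-identity checks are exact.

## The synthetic world

No third-party global data products are bundled; `generate_world()` emulates
the statistical structure the pipeline is sensitive to, on a 100 × 100 grid
of 5-arcminute cells by default (tests use 20–40 cell grids; the acceptance
script uses the 100 × 100 default — sizes chosen so every code path is hit
with comfortably fast runs):

* **Earthworm abundance**: log-normal with median 30 individuals m$^{-2}$
  (meanlog $\log 30$, sdlog 1.1), mildly smoothed in log space, with 15% of
  cells masked. Under these defaults ~86% of cells fall below
  100 individuals m$^{-2}$, reproducing the dominance of low-abundance cells
  on global maps; a test verifies the majority property by sampling.
* **Soil pH**: one smooth base field (Gaussian-filtered white noise) around
  pH 6.2, a slight increase with depth across the five-layer stack, clipped
  to [3.5, 9]; 2% of cells per layer are masked to exercise renormalized
  depth weighting.
* **Texture**: a smooth sand field in [5, 95]%, with clay taking a smooth
  fraction of the remainder, so sand + clay ≤ 100 holds everywhere and all
  three textural classes occur.
* **N rates**: a two-component mixture (means ~15 and ~120 kg N ha⁻¹ yr⁻¹)
  assigned by spatially coherent low/high zones (45% low), so both N
  categories are exercised in every default world.
* **Crops**: four cereals (wheat, rice, maize, barley) and two legumes
  (soybean, dry bean) with log-normal yields around crop-typical means and
  harvested areas that are zero in 30% of cells.
* **Regions**: a nearest-seed partition into eight contiguous zones carrying
  the UN SDG regional-grouping names (Australia/New Zealand combined with
  Oceania). Region assignment is raster-based throughout; country-polygon
  rasterization is out of scope.

Everything is deterministic given the configured seed (one R RNG stream, so
bit-identical across runs on the same R version).

**What the synthetic world does not emulate**: real spatial covariance
between drivers (low pH co-occurring with low fertilizer input in the
tropics, say), the latitudinal structure of cropland, sampling bias in
earthworm observations, or map uncertainty. Passing tests therefore
demonstrate that the *machinery* is correct — classification, masking,
algebra, aggregation — not that any particular real-world number is right.
Real global contributions require the real input layers.

### The known-truth harness

`generate_with_truth()` treats the generated yields as baseline
(without-earthworm) yields, evaluates $E$ with the shipped parameters, sets
observed yield to baseline × (1 + $E$), and records
baseline × $E$ × area summed per region as the implanted truth. Running the
pipeline in division mode on the observed yields must recover this truth
exactly, because $y_{obs}/(1+E)$ = baseline algebraically; the acceptance
suite requires agreement within $10^{-9}$ relative (observed agreement is at
machine precision). This identity is the package's primary end-to-end
validation surface, together with exact regional-to-global conservation and
monotonicity of contributions in abundance.

## Known limitations

* The published global and regional headline figures are not reproducible
  here by design: they require the external crop, soil, fertilizer and
  earthworm maps. The synthetic-world numbers are properties of the
  generator, not estimates.
* The effect model is static and short-term; no erosion/water-dynamics
  benefits, no earthworm-inoculation scenarios.
* Uncertainty is not quantified — coefficients enter as point values.
* No reprojection or mosaicking: all layers must already share one geometry.
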