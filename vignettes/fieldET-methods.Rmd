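---
title: "Methods: daily field-scale evaporation from NDVI and tower meteorology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: daily field-scale evaporation from NDVI and tower meteorology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fieldET)
```

## The model and its assumptions

`fieldET` estimates evaporation (E) by running the Priestley–Taylor
PT-JPL model per pixel and per daytime hour. The model reduces
Priestley–Taylor potential evaporation, `α·Δ/(Δ+γ)·(Rn − G)`, to actual
evaporation through five multiplicative constraints, and partitions it
into soil (`LE_s`), canopy (`LE_c`) and interception (`LE_i`) latent
heat fluxes; their sum is the total LE, converted to mm/h via the latent
heat of vaporization and summed over daytime hours to mm/day.

The driving assumptions are:

* **NDVI is constant within a day.** Each daily grid is reused for every
  daytime hour of that date. Phenology moves slowly relative to a day,
  so this mainly neglects diurnal changes in canopy water content.
* **Meteorology is spatially uniform.** Tower Ta, RH and Rn apply to
  every pixel; all spatial variation in the flux fields enters through
  NDVI (via fAPAR, fIPAR, LAI and the canopy/soil radiation split) and,
  through LAI, the soil heat flux. This is defensible over a single
  field within the tower's footprint scale and wrong across strong
  mesoscale gradients.
* **Daytime only.** Hours with `Rn > 0` are modeled; nighttime E is
  taken as zero in daily totals. Daytime condensation is excluded: every
  flux component is floored at zero.
* **The tower's energy balance closes on the residual.** Measured LE is
  evaluated against `Rn − G − H`, which attributes the whole closure gap
  to the latent heat flux and assumes H is measured correctly.

## Parameters

All model constants live in `ptjpl_params()` so that choices the source
material leaves open are explicit, overridable experiment parameters:

| parameter | default | units | role |
|---|---|---|---|
| `alpha` | 1.26 | – | Priestley–Taylor coefficient |
| `beta` | 1.0 | kPa | soil-moisture sensitivity in `f_SM = RH^(VPD/β)` |
| `gamma` | 0.066 | kPa/°C | psychrometric constant (no pressure forcing, so fixed; override for elevation) |
| `k_rn` | 0.6 | – | net-radiation extinction through the canopy |
| `k_par` | 0.5 | – | PAR extinction used to invert LAI from cover |
| `savi_slope/offset` | 0.45 / 0.132 | – | linear NDVI→SAVI proxy |
| `fapar_slope/offset` | 1.3632 / −0.048 | – | SAVI→fAPAR, clipped to [0, 1] |
| `fipar_slope/offset` | 1.0 / −0.05 | – | NDVI→fIPAR, clipped to [0, 1] |
| `topt` | estimated | °C | optimum of the plant temperature response |
| `lambda_v` | 2.26e6 | J/kg | latent heat of vaporization |
| `g_amplitude`, `g_period` | 0.31, 74 000 | –, s | diurnal soil-heat-flux cosine |

Decisions worth spelling out:

* **NDVI-only vegetation inputs.** The pipeline's imagery input is NDVI,
  so SAVI is a linear proxy of NDVI rather than a reflectance-based
  index. The fAPAR/fIPAR mappings above are the conventional linear
  forms; they are assumptions, not site calibrations, and are exposed in
  `ptjpl_params()` precisely because of that.
* **Topt estimation.** `estimate_topt()` returns the air temperature of
  the daytime hour maximizing `fAPAR·Rn·Ta/VPD` over the season (the
  standard phenology-peak proxy), computed at the tower pixel; hourly Ta
  drives `f_T`. Both the estimate and the use of hourly Ta are
  configurable (`estimate_topt. = FALSE` keeps a fixed `topt`).
* **Soil heat flux on soil net radiation.** G is the diurnal cosine
  applied to `Rn_s`, not total Rn, which yields per-pixel G through the
  LAI-dependent radiation split — that is what makes G spatially
  varying here. The cosine peaks three hours before solar noon; solar
  time uses the longitude offset against the timezone meridian (4
  min/degree) and ignores the equation of time (≤ ~15 min, i.e. a phase
  error in G of a few W/m²).
* **`f_APAR_max` per pixel.** The plant-moisture constraint scales fAPAR
  by its per-pixel seasonal maximum over the supplied stack; a
  field-wide scalar can be passed instead.
* **Daytime defined as Rn > 0.** A solar-elevation rule would differ
  only in the twilight hours where fluxes are ~0.

## Tower quality control

Missing records are filled by time-linear interpolation between the
nearest valid neighbours; leading/trailing gaps take the nearest valid
value (no extrapolation; a degenerate single-anchor series extends that
anchor). Negative daytime LE — implausible, as daytime condensation is
rare — is set missing and refilled the same way. If a refill itself
lands negative (possible only when both anchors are negative nighttime
values), it is floored at zero so screening can never leave a negative
daytime LE. Gap filling is idempotent, and both operations report their
counts for the QC log. Which fields are filled is selectable
(`gap_fill_fields`), since it is ambiguous whether such filling should
touch meteorology, fluxes, or both — the default fills both.

## Water accounting

Hourly LE converts to mm/h, sums to daily field means and per-pixel
daily grids, and accumulates over the season (per field and per pixel).
The daily series is smoothed with a Savitzky–Golay filter — local
least-squares polynomials, default window 15 days and order 3 (the
smoothing scale is a presentation choice, hence CLI-configurable via
`--window`/`--polyorder`); at the edges the window is truncated rather
than padded, so the filter never extrapolates and still reproduces
polynomials up to the fit order exactly. Zonal statistics use
pixel-center containment (edge pixels whose centers fall outside the
ring are excluded), with histograms defaulting to 0.05 mm/day bins.
Underperforming areas are pixels below the zonal mean minus `k` zonal
standard deviations in cumulative E (default `k = 1.5` — plumbing, not
a calibrated threshold). Whether irrigation joins precipitation in the
cumulative water-supply curve is ambiguous in practice; both modes are
provided (`include_irrigation`).

## Evaluation

Modeled and closure-corrected tower E are paired on daytime, in-season
hours. The default compares the *field mean* of the modeled grid against
the tower (a tower integrates over a footprint, not a pixel); a
tower-pixel mode exists for homogeneity checks. Statistics are
`r² = (cov(x,y)/(σ_x σ_y))²`, mean bias, bias as a percent of the
measured range, and MAE. Moments use the population (1/n) convention
throughout; r² is the squared Pearson correlation under either
convention. RMSE is deliberately not reported — MAE weighs all errors
equally.

## The synthetic world

The generator (`synthetic_config()` defaults) states one concrete world
rather than tunable scenery:

* **Scene**: 64 × 64 pixels at 3 m; double-logistic NDVI phenology
  (base 0.15, peak 0.90; green-up rate 0.12 d⁻¹, senescence 0.10 d⁻¹;
  inflections 45 days after sowing and 35 days before harvest — a
  maize-like season with its NDVI plateau in July), sown DOY 121 and
  harvested DOY 270 over a 150-day simulated season; three circular
  patches of radius 6 px whose seasonal amplitude is reduced by 30 %.
* **Meteorology**: clear-sky Rn peaking at 650 W/m² on a half-sine over
  a fixed 06–18 h daylight window; days are cloudy with probability 0.3,
  scaling Rn by 0.6; Ta = 12 °C + 12 °C seasonal sinusoid (peak ~DOY
  201) + 6 °C diurnal cycle + N(0, 1.5 °C) daily anomaly; RH anti-phase
  with Ta around 0.65 (amplitude 0.25); rain on 25 % of days with
  gamma depths of mean 8 mm — Great-Plains-summer magnitudes.
* **Tower**: true fluxes come from the same PT-JPL code at the tower
  pixel; H is constructed so `Rn − G − H` equals the true LE exactly,
  and the measured LE is `true·(1 − gap) + N(0, σ)` with gap 0.15 (a
  conventional eddy-covariance closure deficit; the source material
  states none) and σ = 15 W/m². The gap being multiplicative on LE only
  is deliberate: it makes the residual correction's assumption (H
  correct) literally true, so the correction is exactly invertible on
  synthetic truth and recovery tests are sharp.
* **RNG**: one integer seed; the NDVI stack, meteorology and tower noise
  use documented fixed offsets of it (seed, seed+1, seed+2), with the
  per-day draw order fixed (cloud, Ta anomaly, RH anomaly, wet-day,
  depth, rain hour). Identical configs are bit-identical.

What it does **not** emulate: sensor radiometry and cross-sensor biases,
cloud masks or gap-filled-imagery artifacts, footprint weighting, u*
filtering, advection, or any soil-water balance (f_SM responds to
atmospheric humidity only). A green recovery test therefore establishes
internal consistency of the pipeline — QC, model, accounting and
evaluation composing correctly — not fidelity to a real field.

## Numerical choices

* Half-open hourly records `[t, t+1h)`; timestamps are local standard
  time, with the UTC offset a required reader argument.
* ASCII raster grids and CSVs are written with `%.17g`, so doubles
  round-trip bit-exactly through disk; the -9999 sentinel marks missing.
* `f_c` is capped at 0.98 before the LAI logarithm; all fractions are
  clipped to [0, 1]; `f_SM = 1` when VPD ≤ 0; `f_g = 0` when fIPAR = 0.
* Component sums (`LE = LE_s + LE_c + LE_i`, `Rn = Rn_s + Rn_c`) are
  exact by construction, not to a tolerance.
* Ties in the Topt argmax resolve to the earliest hour (`which.max`).

## Known limitations

Radiation is the only cloud signal (NDVI stays smooth on cloudy days, as
with gap-filled imagery products); the constraint formulations are the
canonical published forms, not site-fitted; γ is constant; λ is
temperature-independent; and the evaluation inherits whatever error the
residual closure correction carries on real towers, where H is not
guaranteed correct.
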