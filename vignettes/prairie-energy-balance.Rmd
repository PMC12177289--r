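---
title: "Methods: synthetic prairie scenes, LST retrieval and diversity-energy-balance linkage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic prairie scenes, LST retrieval and diversity-energy-balance linkage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prairiescape)
```

This vignette documents the models, parameter choices and numerical
decisions behind `prairiescape`. The package analyses a restored tallgrass
prairie experiment observed from the air: 8 blocks of 3 plots (~0.40 ha
each), seeding treatments (control / mid / high diversity) crossed with
management (annual burning vs. haying), a VNIR imaging spectrometer
(400–1000 nm, ~1 m pixels) and a broadband thermal camera (7.5–14 μm,
~1.4 m pixels), plus quadrat species-cover surveys. Because the original
imagery cannot be regenerated at will, the package pairs every retrieval
stage with a forward simulator whose ground truth is fully known, so
correctness is established by parameter recovery rather than by comparison
with archived rasters.

## The thermal model and its retrieval

A single broadband channel sees

$$L_\mathrm{sensor} = \left[\varepsilon\,B(T_s) + (1-\varepsilon)\,L^\downarrow\right]\tau + L^\uparrow,$$

where $B(T)$ is the Planck radiance integrated over the band response
(default: flat/boxcar over 7.5–14 μm on a 0.02 μm quadrature grid;
triangular available), $\varepsilon$ the band-effective surface emissivity,
and $(\tau, L^\downarrow, L^\uparrow)$ the band-effective atmosphere. With
one channel, only band-effective quantities are identifiable, which is why
the package works with a single $(\tau, L^\downarrow, L^\uparrow,
\varepsilon)$ throughout and converts radiance units only at I/O
boundaries (W m⁻² sr⁻¹ μm⁻¹ everywhere internally).

**Atmosphere from tarps.** Each calibration tarp contributes one equation
that is linear in $(u, v, w) = (\tau, \tau L^\downarrow, L^\uparrow)$:
$L_i = \varepsilon_i B(T_i)\,u + (1-\varepsilon_i)\,v + w$. Three tarps of
contrasting emissivity and temperature give an exact, closed-form 3×3
solve (`solve_atmosphere()`), preferred over nonlinear iteration because it
is testable to machine precision and fails loudly (condition-number check
naming the nearly-collinear tarp pair) instead of silently converging to a
poor optimum. Tarp emissivity itself comes from the Stefan–Boltzmann ratio
of the infrared-thermometer and thermocouple readings,
$(T_\mathrm{IRT}/T_\mathrm{TC})^4$, clipped to 1 with a warning. The tarp
surface temperature entering the solve is the thermocouple (contact)
reading: the IRT reading is the radiometric quantity the emissivity
estimate consumes, so using it as $T_s$ as well would double-count the
emissivity correction.

**Emissivity from NDVI.** Per pixel, the vegetation fraction is
$P_v = (\mathrm{NDVI} - \mathrm{NDVI}_s)/(\mathrm{NDVI}_v -
\mathrm{NDVI}_s)$ clipped to $[0,1]$, and $\varepsilon = \varepsilon_s +
(\varepsilon_v - \varepsilon_s) P_v$ — i.e. bare-soil emissivity 0.95
below the soil threshold, dense-vegetation emissivity 0.985 above the
vegetation threshold, linear and continuous between. The thresholds
$\mathrm{NDVI}_s = 0.2$ and $\mathrm{NDVI}_v = 0.5$ are configurable
defaults in the conventional range for this method; the emissivities are
standard literature values for dry sandy soil and green vegetation. NDVI
is computed at 1 m and moved to the 1.4 m thermal grid by
nearest-pixel-center lookup (ties to the smaller index), matching how a
practitioner pairs the two sensors without resampling artifacts.

**Planck inversion.** `invert_planck()` inverts the strictly monotone band
integral by linear interpolation on a cached 0.005 K lookup table built
from the exact quadrature over the physical bracket (260–360 K by
default). The interpolation error is ~10⁻⁸ K — far below the 10⁻⁴ K
nominal tolerance — and out-of-range radiances raise an error reporting
the attainable bracket; in rasters they are flagged missing and counted.

## The VNIR chain

Atmospheric correction is a per-band empirical line anchored on the same
three tarps: `radiance = gain·reflectance + offset`, least squares per
band (exact with three collinear points, overdetermined otherwise, with
per-band residual RMS kept as a diagnostic). A full radiative-transfer
correction is deliberately out of scope: the empirical line is
self-contained, download-free, and exact on the simulator's linear forward
model, so calibration errors never confound tests of the downstream
science. Retrieved reflectance is clamped to [0, 1.5] with logged counts —
bright targets legitimately exceed 1 under noise, so hard failure would be
wrong. Index bands are selected by nearest center without interpolation
(at 2.3 nm spacing the difference is negligible and the indices are
defined at single wavelengths: NDVI 680/800 nm, WBI 900/970 nm). Albedo is
the unweighted mean over all bands with centers in 450–900 nm inclusive;
bandwidth weighting was considered and rejected as unspecified in the
index definition (the choice is exposed in the code path should a user
need it).

## What the synthetic scene emulates

`make_layout()` reproduces the experimental design: 8 blocks × 3 plots,
management alternating by block, each block holding one plot per seeding
level in a seed-determined order. Plots are 100 m × 40 m = 0.40 ha, which
lets the 2×3 subplot array sit on an exact 30 m grid while keeping ≥ 5 m
from plot edges (the survey design: plot center, meter-7 and meter-14
points on four 15-m cardinal transects — nine locations — plus the six
subplots, 15 in all; the ground-spectroscopy design samples every meter
along the four transects, 60 positions).

**Cover and composition.** An 18-species pool (4 C3 grasses, 6 C4 grasses,
8 forbs) carries relative-abundance weights per seeding level: control
plots dominated by smooth brome and a weedy forb, the mid mix spread over
short/mid-stature natives, the high mix dominated by tall C4 grasses.
Burning multiplies C3 weights by 0.7 and boosts C4/forbs, removes litter
(litter share of non-vegetated ground 0.25 burned vs 0.75 hayed) and adds
0.10 to green cover; seeding raises mean vegetation cover (0.55 / 0.78 /
0.85 for control / mid / high). A per-plot latent "establishment" effect
(sd 0.04) shifts cover and tilts composition coherently, and the same
per-plot conditions drive both the quadrat sampler and the pixel fields,
so field tables and imagery stay spatially consistent — the property the
diversity–index regressions rest on. Quadrat draws add lognormal
per-species noise (log-sd 0.6, shares < 0.5 % dropped), so richness and
Shannon H vary realistically between locations.

**Surface fields.** Endmember spectra are smooth parametric curves rather
than library spectra (keeping the package download-free): green vegetation
with a logistic red edge to a 0.60 NIR plateau and a Gaussian 970 nm
liquid-water absorption scaled by canopy water; litter flat at 0.18
(bright in the visible, well below the green NIR plateau, no water dip);
soil brightening linearly 0.10→0.28. The litter level matters: it encodes
the mechanism by which burning (removing standing dead material) raises
VNIR albedo — with litter as bright as the green canopy's 450–900 nm mean
the albedo contrast between managements would vanish, contradicting the
treatment pattern the simulator exists to emulate. Reflectance is the
cover-weighted endmember mixture; canopy water is 0.8·green cover with
30 % multiplicative noise; temperature is
$T = 318 - 12\,g - 5\,w + \eta$ K (green cover $g$, water $w$), with
spatially correlated noise $\eta$ (Gaussian-smoothed white noise,
correlation length 10 px, sd 0.8 K) — the field data imply spatial
structure without stating it, so the correlation length is an explicit
knob. Three tarps (flat reflectance 0.85 / 0.45 / 0.05; thermal emissivity
0.92 / 0.80 / 0.96; thermocouple temperatures 305 / 315 / 325 K) sit in
the southern margin; their emissivities and brightnesses are free
simulator parameters chosen to keep the 3×3 atmospheric solve well
conditioned. The default atmosphere (τ = 0.95, L↓ = 1.5, L↑ = 0.8
W m⁻² sr⁻¹ μm⁻¹) represents a short (~1.5 km), dry mid-summer path.

**Forward models and commensurability.** VNIR at-sensor radiance is a
per-band affine map (smoothly varying gain and offset) plus Gaussian noise
(sd 0.005), standing in for atmospheric effects in exactly the form the
empirical line inverts. The thermal forward model box-averages the
blackbody radiance field $B(T)$ (radiance mixes linearly; temperature does
not) from 1 m to 1.4 m with area weights, defines the effective truth
temperature $T_\mathrm{eff} = B^{-1}(\overline{B(T)})$, and applies the
NDVI-threshold emissivity on the thermal grid — the same law the retrieval
uses. This makes forward and inverse models commensurable: a single
thermal-grid emissivity cannot exactly represent a mixture of per-1-m
$\varepsilon B(T)$ products, so defining truth at the scale the retrieval
can see is what makes "noise-free round trip exact to < 0.01 K" a
meaningful specification rather than an approximation. Tarp pixels are
painted with their own emissivities (deliberately breaking the NDVI law,
as real tarps do) and are therefore masked out of round-trip error
statistics. Thermal sensor noise is specified in kelvin-equivalent units
(default 1.5 K, converted via $\partial B/\partial T$ at 300 K) and added
last.

## Survey and linkage choices

Shannon indices use natural log (the community-ecology convention) and are
computed with vegan, excluding ground rows (litter, bare soil) from the
denominators; functional-group H aggregates covers to C3/C4/forb first.
Locations without vegetation get richness 0 and H = 0. The plot-level
community is the mean cover across retained locations; the rare-species
rule removes species whose *maximum* relative cover across plots stays
below 5 % (a mean-based variant is exposed via `stat = "mean"`; the
max-based reading is the stricter and more common one). Bray–Curtis
distances come from vegan's `vegdist`; ordination itself (NMDS) is out of
scope — the package supplies the distance matrix an `metaMDS` call would
consume. Box summaries use type-7 quantiles with whiskers at the most
extreme points within 1.5 IQR.

Regressions are fit at the sampling-location level (matching the point
clouds such analyses plot; plot-level aggregation is a straightforward
`aggregate` away), in the overall / by-management / by-seeding layout.
ANCOVA is the classic two-stage form: the interaction model
`y ~ x * group` F-tests slope heterogeneity; the additive refit
`y ~ x + group` F-tests intercept differences under a common slope, and
both p-values are always reported. Significance codes extend the
`ns`/`**`/`***` map with `*` for 0.01 ≤ p < 0.05 so that weakly
significant fits remain representable.

## Problem sizes and what the tests show

The default scene is 600 × 400 VNIR pixels with 261 bands. The replicated
end-to-end checks (treatment-sign recovery over 100 seeded scenes) run the
full 8-block layout with narrow margins and a 9.2 nm spectral grid — the
indices use single nearest bands and a range mean, so spectral thinning
changes nothing statistically while keeping 100 pipeline replicates
affordable; noise-robustness statistics use 200 replicates of a 50 × 50 px
thermal scene, and ANCOVA calibration uses 1000 null and 200 power
replicates. All randomness flows from one root seed, fanned out per stage
through deterministic sub-seeds, and generators restore the session RNG
state.

Passing these tests shows that the implementation inverts its own forward
models exactly, that the statistics hold their nominal size and power, and
that the configured treatment effects propagate through the full chain
with the expected signs. It does not show that the simulator reproduces
real prairie spectra (endmembers are parametric, not measured), real
atmospheric physics (the VNIR forward model is affine by construction),
BRDF/illumination geometry, georeferencing, or the magnitudes of real
treatment effects — only their directions are encoded.

## Known limitations

- One broadband thermal channel: no split-window methods, no directional
  emissivity, and the band-effective atmosphere is only as good as the
  tarp measurements anchoring it.
- The NDVI-threshold emissivity is a two-endpoint interpolation; mixed
  senescent/soil surfaces with unusual emissivity are outside its model.
- The empirical line assumes spatially uniform atmosphere and sensor gain
  across the scene.
- Cover tables and pixels are coupled through plot-level conditions, not
  through a shared sub-plot random field, so within-plot correlations
  between quadrats and pixels are weaker than between-plot ones.
- Local metric coordinates only; no map projections or georectification.
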