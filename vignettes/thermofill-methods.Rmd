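---
title: "Thermal niche filling: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermal niche filling: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermofill)
```

## The question and the quantities

Ectotherm body temperatures track their environment, so experimentally
assayed tolerance limits (CTmax, CTmin — or lethal limits) define a
*fundamental thermal niche*: the band of body temperatures a species can
function in. Whether a species actually occupies all the places whose
extreme body temperatures fall inside that band is the question this
package quantifies. Three niches are involved:

* **fundamental niche** — the interval `[CTmin, CTmax]` from assays;
* **potential thermal niche / range** — the extreme body temperatures (and
  the grid cells producing them) within the fundamental niche, across the
  habitat the species could plausibly reach;
* **realized niche / range** — the extreme body temperatures across (and
  the cells of) the observed distribution.

Four statistics summarise their relationship per species:

* **warm niche filling** (°C) `= realized warm limit − potential warm
  limit`; negative values are *underfilling* (the species avoids tolerable
  warm places), positive values are *underprediction* (it occupies places
  hotter than its assayed limit);
* **cool niche filling** (°C) `= potential cool limit − realized cool
  limit`, with the same sign convention on the cold edge;
* **range filling** — the proportion of potential-range cells occupied
  (occupied cells outside the potential are ignored);
* **equatorward bias of range underfilling** — underfilled proportion of
  the equatorward half of the potential range minus that of the poleward
  half, the halves split at the midlatitude of occupied cells. Positive
  values mean the species is missing from tolerable habitat mostly on its
  equatorward side.

Two competing hypotheses about biotic range limitation make opposite
predictions for how these statistics change with latitude, and the
package's synthetic scenarios (below) implement both as ground-truth
worlds: under a *temperate trade-off*, high-latitude species are excluded
from their equatorward, thermally tolerable habitat (warm filling becomes
more negative with latitude; bias becomes more positive); under *reduced
abiotic limitation in the tropics*, low-latitude ranges are truncated at
both edges (warm underfilling greatest near the equator, bias near zero).

## From climate to body temperatures

**Terrestrial species.** Air temperature is a poor proxy for the body
temperature of a small ectotherm in the sun, so terrestrial extremes are
operative temperatures from a lumped-parameter steady-state energy
balance,

`a·S + e·s·T_air_K^4 = e·s·T_e_K^4 + c_p·g_H·(T_e − T_air) + w·L·g_v·(e_s(T_e) − rh·e_s(T_air))/P`

with shortwave absorptance `a` (default 0.85), longwave emissivity `e`
(0.95), Stefan–Boltzmann constant `s`, molar convective conductance
`g_H = 1.4·0.135·sqrt(u/d)` and vapour conductance
`g_v = 1.4·0.147·sqrt(u/d)` (forced-convection scalings with wind speed
`u` and characteristic dimension `d`), skin wetness `w` (0.1), molar
latent heat `L`, and Magnus saturation vapour pressure `e_s`. The
characteristic dimension derives from body mass at unit density,
`d = (mass_g·1e−6)^(1/3)` m, so a 1 g animal (1 cm) is tightly coupled to
air and a 1 kg animal (10 cm) is not. The right-hand side is strictly
increasing in `T_e`, so the root is unique; a vectorised Newton iteration
solves it to a residual below 1e−8 W m⁻² (well inside the 1e−6 contract),
starting from air temperature — which makes the zero-load, dry-skin case
(`T_e = T_air`) exact. Non-convergence raises an error rather than
returning a partial field.

Microhabitat use follows the conservative assumption of the main
analysis: animals equilibrate to *shade* during heat extremes (a fraction
`shade_solar_fraction = 0.1` of solar flux) and to full *sun* during cold
extremes. The warm extreme of a cell is the hottest hourly shaded
operative temperature across the hottest day; the cool extreme the
coldest hourly sun-exposed operative temperature across the coldest day.
Full-sun warm and full-shade cool auxiliaries are retained for the
behavioural analysis.

**Marine species.** Subtidal body temperatures are sea surface
temperatures; the extremes are the annual extreme daily SSTs. Intertidal
species occupy the coastal band (land cells with an ocean cell among
their eight neighbours; ocean cells within 200 km great-circle distance
of such a cell) and experience both media where both exist: on
coastal-ocean cells the more extreme of air and SST is taken at each
edge; coastal-land cells provide air only. Hourly variation in the ocean
is deliberately not modelled.

**Dormancy.** Species recorded as seasonally dormant do not experience
the most extreme months: summer dormancy masks each cell's six warmest
months before the warm extreme is selected, winter dormancy the six
coldest before the cool extreme, `both` applies both. Months are ranked
per cell by the medium's monthly mean, ties broken by month index, and
extremes are *recomputed* from the monthly/diurnal climate model
restricted to the active months (the synthetic climate materialises no
daily series to mask). This makes masking idempotent and guarantees it
can only cool warm extremes and warm cool extremes. The six-month
duration is a fixed convention exposed through the dormancy classes, not
an inference.

## Potential ranges by successive restriction

1. **Encounterable habitat.** Subtidal: all ocean cells. Intertidal: the
   coastal band. Terrestrial: every cell of the biogeographic realm(s)
   the realized range intersects — realms are the contiguity units, so an
   intersected realm is available in full. A stricter flood-fill variant
   (`contiguity = "flood"`), which keeps only the connected components of
   those realms touching the realized range, is available for sensitivity
   analysis.
2. **Thermal clipping.** Cells are dropped where the warm extreme exceeds
   the upper limit or the cool extreme undershoots the lower limit;
   one-limit species are clipped on their one known side only (±Inf act
   as present-but-vacuous sentinels). Cells without body-temperature data
   are dropped and logged; an empty potential is a legal, flagged result.
3. **Depth/elevation correction.** Cells outside a species' known
   elevation or depth bounds are removed; species without bounds are left
   as-is. The same correction applies to realized ranges.

The three restrictions commute; every removed cell appears exactly once
in a restriction log with its reason (`no_climate`, `too_hot`,
`too_cold`, `too_hot_cold`, `depth_elevation`), which the
cold-underprediction scenario later reuses.

Niche limits are the maximum warm and minimum cool extremes over occupied
cells with climate data; the covered fraction is reported rather than
imposing a coverage threshold. Species whose realized range has no
climate-covered cells are excluded with a flag, as are
range-filling/bias calculations for species whose realized and potential
ranges do not overlap.

**Tie and hemisphere rules for the bias split.** Cells exactly at the
split latitude go to the equatorward half. For trans-equatorial species
the halves are assigned by absolute latitude relative to the absolute
split latitude. Both rules are deterministic conventions; the second is a
documented choice where no canonical definition exists. A consequence of
the first is a small negative structural offset in the bias of ranges
spanning an odd number of grid rows (the split row inflates the
equatorward half by construction, of order `−2·(underfilled fraction) /
(rows)`; about −0.016 on clean rectangular test ranges). This is a
property of the measure, not an artefact of the implementation.

## The synthetic world and species

The generators provide *study conditions*, not decoration: every
statistical claim the tests make is made under these defaults.

**World** (`world_config()`): a 1° regional sector, 140 latitude rows
(−70..70) by 40 longitude columns, two superelliptical continents
(near-uniform width over their latitude span, so that cell-fraction-based
range carving is latitudinally unbiased), five terrestrial realms stacked
latitudinally within continents and never spanning the equator — as with
real biogeographic realms, and necessary here because the climate is
hemispherically symmetric and an unobstructed habitat would otherwise
give every species a mirror-image "bipolar" potential range. Elevation
and depth are smoothed random fields; land fraction 0.35. One degree
resolution (rather than a coarser desk grid) keeps potential ranges
~10–20 rows deep, so edge statistics vary smoothly instead of jumping in
row-sized quanta.

**Climate** (`climate_config()`): monthly mean air temperature
`T(cell, m) = 28 − 0.6·|lat| + A(|lat|)·cos(2π(m − peak)/12) + noise`,
with seasonal amplitude `A = 2 + 0.125·|lat|` °C (tropics more
seasonally stable) and a hemisphere-dependent peak month (July north,
January south, so dormancy masks differ by hemisphere). SST uses a
flatter profile (27 − 0.35·|lat|, amplitude 1 + 0.02·|lat|) with a
−1.8 °C freezing floor. The land diurnal cycle is an 8 °C peak-to-trough
sinusoid peaking at 14:00 (zero over the ocean); solar flux is a daytime
half-sine scaled by `900·cos(lat)` W m⁻²; wind and humidity carry mild
cell-level scatter; spatial noise is a smooth 0.5 °C field constant
across months. The seasonal amplitude slope (0.25 °C of annual span per
degree latitude) deliberately equals the terrestrial breadth slope below,
which keeps the latitudinal extent of potential ranges roughly constant —
the configuration in which the scenarios' °C signatures are cleanly
expressed rather than confounded with range size. Acclimation
temperatures are emitted directly as `warm extreme − 2 °C` and `cool
extreme + 4 °C`, standing in for the warmest week before the hottest day
and the coldest seven weeks before the coldest day; only the resulting
temperatures enter any downstream computation, so the windows themselves
are not simulated.

**Species** (`scenario_config()`): each species draws a realm
(70/10/20% terrestrial/intertidal/subtidal), a target cell of its medium,
and a tolerance breadth from the per-realm linear model `breadth = b0 +
b1·|lat_target| + N(0, 2)` with `b0 = 22`, `b1 = 0.25` °C/° on land and
`b0 = 12`, `b1 = 0.02` in the ocean (terrestrial breadths widen strongly
with latitude; marine breadths barely). Limits are positioned so the
band's warm and cool edges sit latitudinally symmetric about the target:
the slack beyond the local zonal span is split between the edges in
inverse proportion to the local zonal temperature gradients. This makes
the realized latitudinal midpoint track the generator's target — the
premise of any parameter-recovery claim about latitude covariates. Drawn
breadths that cannot cover the local span trigger a bounded retry at a
new target (30 tries, then an `unplaceable` flag). Half the species keep
only one limit (80% of those the upper), matching the structure of real
tolerance compilations; terrestrial species carry dormancy classes
(80% none), log-normal body masses, categorical dispersal distances,
ARR values (30% missing, to exercise the class/realm fallback),
preferred temperatures (70% of terrestrial) and occasional
elevation/depth bounds.

**Scenarios** (`realize_range()`): realized ranges are carved from the
potential by geographic rules whose *thermal* signature the filling
statistics must recover:

* `perfect` — realized = potential, verbatim;
* `temperate_tradeoff` — remove the `k·|lat_mid|/90` most equatorward
  fraction of cells (ascending absolute latitude, ties by longitude);
* `reduced_abiotic` — remove `k·(1 − |lat_mid|/90)`, split equally
  between the equatorward-most and poleward-most cells (an odd cell drops
  its remainder rather than biasing one end);
* `cold_underprediction` — additionally occupy up to
  `ceiling(k·|lat_mid|/15)` rows of logged `too_cold` cells beyond the
  poleward cold edge, producing realized niches colder than the lower
  limit.

Except under `perfect`, carving first confines the potential to the
contiguous latitudinal band containing the target: a realized range grows
from one colonized region, and without this rule the symmetric ocean
would produce bipolar marine "ranges" whose latitudinal midpoints are
meaningless. Emptying removals retain a single poleward (or central) cell
and flag the range.

## Sensitivity analyses

**Acclimatization.** The ARR (acclimation response ratio — the slope of a
tolerance limit against experimental acclimation temperature) converts
local acclimation temperatures into cell-specific limits:
`upper(cell) = CTmax + ARR_u·(acclim_warm(cell) − assay)` and
analogously below. Missing species ARRs fall back to class means, then
realm means, from user-supplied tables (`arr_fallback_tables()` builds
them from a pool); the assay acclimation temperature is required input
with no silent default. The acclimatized potential range is the ordinary
construction with the cell-specific limits; ARR = 0 reproduces the static
analysis bit-for-bit, and positive ARR with acclimation warmer than assay
at the warm edge (cooler at the cold edge) can only enlarge the
potential and reduce underprediction.

**Behavioural thermoregulation.** Relaxing the always-shaded assumption:
in each occupied cell and hot-day hour the animal can hold any body
temperature between the shaded and sunny operative temperatures, and
holds the one closest to its preferred temperature `T_pref` (a weighted
mean when the species table provides weights; otherwise the single
estimate). The behaviourally adjusted realized warm limit is the maximum
achieved value over cells and hours; it is bounded between the all-shade
and all-sun maxima by construction.

## Statistical models

`fit_filling_trend()` fits, per response, a linear model with a
realm-by-|latitudinal midpoint| interaction plus dispersal distance, log
body mass, log realized range size, and tolerance-metric type, on
complete cases only. Range filling is log-transformed first (zero
proportions are excluded and counted, since no canonical zero-handling
exists) and drops the range-size covariate, whose shared geometric
constraints with range filling would make it circular. Metric type is
dropped automatically when aliased with realm; any other rank deficiency
is an error naming the aliased terms. Per-realm slopes are linear
combinations of the main effect and interaction coefficients with
covariance-propagated standard errors. Generalised variance-inflation
factors above 3 are flagged, never removed — pruning is a user decision.
Nested taxonomic random intercepts (class/order/family/genus via lme4)
are available behind `random_effects = TRUE`; the default is plain least
squares, and the backend used is recorded in the fit. Multimodel
averaging over term subsets is deliberately out of scope: it is an
off-the-shelf procedure orthogonal to the pipeline, and a single full
model keeps the scenario-recovery logic transparent.

`fit_breadth_relationships()` fits breadth against |latitudinal midpoint|
and warm filling against breadth, slopes and intercepts varying by realm;
realms with fewer than three two-limit species are omitted with a
warning. `scenario_signature()` reduces a filling table to the three
discriminating quantities (warm-filling slope, bias slope, mean bias) and
labels the implied hypothesis.

## Problem sizes, determinism and limitations

The standard study conditions — 140×40 one-degree cells, 300 species —
run end-to-end in well under a minute per scenario; the brute-force
oracle comparisons use 200 random species on worlds of at most 20×20
cells, where unvectorised loops are feasible. All generators consume
explicit seeds through `withr::with_seed`, so a pipeline rerun under the
same configuration is byte-identical down to its written CSVs.

What passing the synthetic tests does **not** show about real data: the
climate has no topographic lapse, no aridity, no interannual variability
and no real microclimate model behind the operative temperatures (the
heat balance is an explicit, testable operator, with every parameter
surfaced for tuning against a microclimate simulator); ranges are carved
by the scenario rules rather than demography or dispersal; traits are
independent of taxonomy, so random-intercept machinery is exercised but
not stressed; realized marine ranges are constrained to one latitudinal
band by construction; and the bias measure carries the small structural
offset described above. Statistical recovery under these conditions
validates the *computations* — on real compilations the same statistics
inherit all the measurement error of assays, range polygons and climate
products.

Latitude cells are counted, not area-weighted; a geodesic-area-weighted
variant of range filling would be a straightforward extension but is not
what the cell-proportion definition measures. Longitude does not wrap in
the default sector; periodic grids are supported by the grid
specification but not exercised by the generators.
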