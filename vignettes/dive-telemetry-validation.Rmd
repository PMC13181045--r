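---
title: "Validating ocean model temperatures with satellite-tag dive telemetry"
author: "diveTherm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating ocean model temperatures with satellite-tag dive telemetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diveTherm)
```

## The problem

Argos satellite tags glued to the carapace of marine turtles record pairs of
depth and temperature during each dive and transmit them when the animal
surfaces. Because the animals dive continuously and range into waters that
conventional platforms rarely sample, these transmissions are an attractive,
low-cost source of vertical temperature profiles — provided the telemetry can
be decoded into properly timed, quality-controlled profiles, and provided one
can quantify how well those profiles agree with the gridded analysis products
oceanographers actually use.

`diveTherm` implements that chain as a reusable, testable pipeline:

1. **decode** a documented tag CSV dialect into per-dive temperature
   profiles, reconstructing sample times retroactively from elapsed-time
   trailers;
2. **collocate** the profiles with a daily gridded temperature product on
   its native grid and vertical levels;
3. **summarise** agreement with Pearson correlation, BIAS, RMSE and unbiased
   RMSE, stratified by season, depth range and sub-region;
4. **cross-check** the upper ocean against ARGO-style float profiles;
5. **simulate** all of the above from a known-truth ocean, so that every
   stage can be verified against values that are exactly known.

The real turtle dataset this design follows is available only on request,
and the operational model product is terabytes of gridded fields; the
synthetic generator therefore stands in for both, and everything the package
claims about its own correctness is demonstrated on synthetic data.

## Tag records and the decoding procedure

Each transmission carries three kinds of rows. `FIX` rows hold the Argos
position fix: tag id, UTC time, latitude, longitude, and a location quality
(LQ) class from the set Z, B, A, 0, 1, 2, 3. `DIVE` rows hold up to six
depth–temperature pairs — one 30-minute block of samples taken every 5
minutes — flanked by a near-surface temperature with its age
(`sst`, `sst_time_min`) and, as a trailer, the elapsed minutes between the
block's most recent pair and the transmission (`dt_time_min`). `DIAG` rows
carry battery diagnostics and are discarded.

Decoding proceeds in four steps, each exposed as its own function:

* `parseTagFile()` validates the dialect and drops diagnostics.
* `filterFixes()` removes fixes without coordinates or LQ, and (by default)
  every class except 0. Class 0 has a nominal precision around 1,500 m,
  commensurate with a ~4 km model grid; admitting only it mirrors the field
  practice this package reimplements, although the set is configurable
  (`allowed_lq`), since discarding the *more* precise classes 1–3 is a
  conservative choice one may wish to revisit.
* `segmentDives()` reconstructs each record's time range from its trailer
  and groups records whose ranges are contiguous on the 5-minute lattice;
  any gap longer than one sampling interval starts a new dive.
* `reconstructDiveProfile()` assigns sample `k` (counted backward from a
  record's anchored last pair) the time `fix_utc - dt_time_min - 5k`
  minutes, merges records, enforces temporal coherence, discards surfacing
  samples at exactly 0 m (the sensor may have read air temperature;
  sub-surface depths in (0, 0.5] are kept), and rejects dives that lack a
  discernible start and end or contain half-empty pairs. Rejections are
  typed reason codes, never silent drops, and per-file counts reconcile:
  every candidate dive becomes either a profile or a rejection.

**Temporal-coherence truncation.** Occasionally the merged sample sequence
is not strictly increasing in time (inconsistent trailers). The profile is
then truncated at the temporally coherent part. Which part to keep is a
genuine design choice: we default to the run that *ends at the most recent
sample* (`truncate = "suffix"`), on the grounds that the most recently
stored data, nearest the transmission anchoring the clock, is the best
timed; samples not strictly earlier than the final one are removed first,
and a forward scan then keeps a strictly increasing run (duplicated
timestamps count as incoherent). The alternative (`"prefix"`, keep the
earliest coherent run) is provided. For the sequence −40, −35, −45, −30
minutes before the fix, suffix mode keeps −40, −35, −30.

## Collocation

Each profile is matched to the model cell whose centre minimises the
great-circle distance to the fix (ties broken deterministically by lowest
latitude then longitude index; land cells are skipped via the sea mask;
fixes farther than `max_match_km = 25` km from any sea cell go unmatched,
with the reason logged) and to the daily slice containing the mid-dive
timestamp. The simulator schedules dives inside a single civil day, so this
mapping is unambiguous there; for real data a dive spanning midnight simply
falls to the day of its midpoint.

Profiles sharing a (cell, day) are **averaged before interpolation**:
temperatures at identical depths are averaged, depth grids are merged by
union otherwise, and the combined profile is linearly interpolated onto the
model levels inside the observed depth span — never extrapolated. A group
reduced to a single depth contributes only where a model level lies within
half the local level spacing of that depth (the natural reading of "within
half a spacing" when the observation itself has no spacing). Each covered
level yields one matched pair, labelled with its meteorological season
(DJF/MAM/JJA/SON), depth range ((0,15], (15,30], (30,50], (50,100] m,
right-closed; deeper levels carry no range label and are excluded from
stratified statistics, where observations are too sparse), and sub-region.

Sub-regions ship as an editable GeoJSON (`inst/extdata`): a coastal-band
polygon for the western-coast current region (WACC), then northern, middle
and southern basin boxes, tested in that priority order. The literature
definitions involve bathymetry (a 100 m isobath, a pit, a peninsula
transect) that cannot be reproduced from text alone; the shipped polygons
are documented straight-line approximations, and any analysis needing exact
boundaries should replace the file.

## Validation statistics

For observed series $y$ and model series $y'$ of length $N$:

$$r = \frac{\mathrm{cov}(y, y')}{\sigma_y\,\sigma_{y'}}, \qquad
\mathrm{BIAS} = \frac{1}{N}\sum_{i=1}^{N} (y'_i - y_i),$$

$$\mathrm{RMSE} = \sqrt{\tfrac{1}{N}\sum_i (y'_i - y_i)^2}, \qquad
\mathrm{uRMSE} = \sqrt{\mathrm{RMSE}^2 - \mathrm{BIAS}^2}.$$

Positive BIAS means the model is warmer than the observations. uRMSE is the
centred (bias-free) error; the decomposition
$\mathrm{uRMSE}^2 + \mathrm{BIAS}^2 = \mathrm{RMSE}^2$ is enforced to
$10^{-9}$ relative tolerance in the tests, and uRMSE is invariant under any
constant model offset. The square root is clamped at zero against
floating-point negatives. Significance for $r$ uses the exact
$t = r\sqrt{(N-2)/(1-r^2)}$ transformation on $N-2$ degrees of freedom (the
test is swappable; sample $(n-1)$ normalisation is used consistently, and
cancels in $r$).

`stratifiedSummary()` emits one row per occupied stratum with both a pair
count (`n_pairs`) and the raw sample count behind those pairs (`n_obs`),
since "number of observations" is ambiguous between the two; strata with
fewer than 3 pairs or degenerate variance get explicit `NA` statistics. The
`report_filter = "r_significant"` option marks rows passing the customary
reporting rule ($r > 0.6$, $p < 0.05$) without removing the others.
`layerProfileSummary()` gives per-level mean profiles, BIAS and uRMSE by
season or sub-region. Statistics are pair-weighted ("computed over the
entire dataset"), not per-profile-averaged.

The ARGO check (`pairArgoTurtle()`, `binnedBias()`) forms all cross pairs
within 10 km and ±15 days (both inclusive) sharing a 1-m depth bin, and
reports per-bin BIAS (oriented ARGO minus turtle, configurable) and counts
down to 12 m, with empty bins kept as `n = 0`.

## The synthetic ocean and its parameters

The truth field is a seasonally forced logistic thermocline:

$$T(z, t, \phi) = T_{deep} + \bigl(T_{surf}(t, \phi) - T_{deep}\bigr)\,
\frac{1}{1 + e^{(z - \mathrm{MLD}(t))/w}},$$

with $T_{surf} = T_{mean} + A\cos\!\bigl(2\pi(\mathrm{doy} -
\mathrm{doy}_{peak})/365.25\bigr) + g(\phi - \phi_0)$ and the mixed-layer
depth interpolating on the same phase between its winter and summer
extremes. Dates are UTC civil dates; day-of-year uses the 365.25 divisor
with no leap-day special case. The form was chosen for smoothness and for
closed-form checks: at $z = \mathrm{MLD}$ the temperature is exactly halfway
between surface and deep, and both tails saturate.

Defaults describe a mid-latitude semi-enclosed basin: `t_deep` 13 °C,
`t_mean` 19 °C, `a_surf` 6 °C (winter surface ≈ 13 °C, late-summer ≈ 25 °C),
peak at day 226, MLD 90 m (winter) to 15 m (summer), thermocline half-width
`w_thermo` 20 m, meridional surface gradient −0.2 °C/deg. Deep winter mixing
coinciding with near-zero stratification is deliberate — it is what makes
real winter basins nearly isothermal.

The model product samples this truth on a regular 1/24° grid (~4.2 km) over
35 vertical levels (< 4 m spacing in the upper 100 m, coarser below) and
perturbs it with a per-level systematic bias $b(z)$ and i.i.d. Gaussian
noise — the two quantities the validation statistics are supposed to
recover. Turtle dives are trapezoidal (35 % descent, 30 % bottom, 35 %
ascent) with maximum depth from an exponential of mean 25 m hard-capped at
175 m (the deepest dive the emulated tags report) and duration coupled to
depth at ≥ 2.4 min/m, capped at the tag's 240-min storage limit — deep dives
are long resting dives, consistent with a storage cap that is actually
binding. The coupling also keeps the vertical distance between consecutive
5-minute samples below ~6 m for dives above 100 m (~10.5 m at the 175 m
cap), which is what makes the linear-interpolation error of collocation
provably small (< 0.05 °C) against this truth field. Each dive ends with a
fix whose LQ class is drawn from a configurable distribution (default: half
the mass on class 0, so the filter is exercised) and whose position is
perturbed by the class-typical error (1,500 m sd at LQ 0). Temperatures are
recorded as truth exactly by default (`obs_noise_sd = 0`), so the
encode→decode round trip and the perfect-model null are exact; a sensor
noise term is available. The tags' duty cycle is undocumented, so a
`transmission_prob` knob exists but defaults to 1. ARGO-style profiles are
truth at 1-m resolution plus independent noise (default sd 0.05 °C).

Every generator takes a seed and is bit-reproducible. What the generator
does **not** emulate: bathymetry and land (the sea mask defaults to all
sea), internal waves and fronts, sensor drift and thermal lag, Argos
message corruption, or any horizontal structure beyond the linear surface
gradient. Passing tests therefore demonstrate the *processing chain* is
correct — not that real tag data are this well behaved.

## Numerical and design choices

* Great-circle (haversine) distances throughout; "nearest grid point" is a
  distance minimisation over sea-cell centres with a deterministic
  index-order tie-break.
* Linear depth interpolation (no method was mandated; linear is monotone
  and transparent).
* Tag files are written with 17 significant digits so that
  decode(encode(d)) reproduces every triple bit-exactly.
* Degenerate inputs are errors where the caller can fix them (negative
  depth, empty series, unequal lengths, unknown LQ symbols, malformed rows
  with their line number) and typed rejections where they are data quality
  (dive structure problems).
* The gridded field is held in memory as a `[time, depth, lat, lon]` array
  with a plain-text long-CSV serialisation (`readGriddedField()` /
  `writeGriddedField()`); axes and the variable semantics mirror a CF-style
  daily product.
* Pipeline runs (`runPipeline()`) write every stage product, a run log that
  accounts for each dropped record with a reason code, and a manifest with
  the seed, a config hash and per-stage counts; wall-clock time is kept out
  of all outputs so identical configs produce bit-identical files.

## Problem sizes

The shipped test suite and the acceptance script run entirely on synthetic
data at deliberately desk-sized scales, chosen as the smallest that leave
the statistical checks well-posed: the identity and correlation oracles use
1,000 and 100 random series; the round-trip check encodes 500 dives; the
parameter-recovery experiment decodes 490 dives into ≥ 2,000 matched pairs
against a 1.6° × 1.5° grid at 1/24°, which recovers an injected 0.5 °C bias
to within $3\sigma/\sqrt{N}$ and a 0.3 °C noise sd to within 10 %; the
perfect-model null (zero bias, zero noise) bounds every matched pair by the
0.05 °C interpolation allowance.

## Limitations

The sub-region polygons are approximations; the truth field is horizontally
near-uniform, so spatial strata mostly exercise bookkeeping rather than
geophysics; the 100 m analysis cap, depth-range edges and ARGO thresholds
are configuration, not discoveries; and no claim is made about assimilation
impact — the package measures agreement, nothing more.
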