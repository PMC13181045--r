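# diveTherm

Seawater temperature profiles from satellite-tag dive telemetry, validated
against gridded ocean model products.

Argos satellite tags on marine animals (here: loggerhead sea turtles)
record depth–temperature pairs every 5 minutes during dives and transmit
them on surfacing. `diveTherm` turns those transmissions into
quality-controlled vertical temperature profiles and measures how well they
agree with a daily gridded ocean temperature field and with ARGO-style
float profiles. Because real tag datasets are typically available only on
request, the package includes a first-class synthetic generator — a
known-truth seasonal thermocline ocean, a perturbed gridded "model
product", simulated turtle dives encoded in the tag CSV dialect, and
ARGO-style profiles — so the entire chain is testable end to end.

It is aimed at movement ecologists and operational oceanographers working
with animal-borne sensors: people who need a decoder for elapsed-time tag
telemetry, a defensible collocation procedure, and the standard validation
statistics, with every quality-control drop accounted for.

## What it computes

For observed temperatures $y$ and model temperatures $y'$ at $N$ matched
points:

- Pearson correlation $r = \mathrm{cov}(y, y') / (\sigma_y \sigma_{y'})$,
  with a two-sided $t$-test on $N-2$ degrees of freedom;
- $\mathrm{BIAS} = \frac{1}{N}\sum_i (y'_i - y_i)$ (positive = model
  warmer than observed);
- $\mathrm{RMSE} = \sqrt{\frac{1}{N}\sum_i (y'_i - y_i)^2}$;
- unbiased RMSE $\,\mathrm{uRMSE} = \sqrt{\mathrm{RMSE}^2 -
  \mathrm{BIAS}^2}$, the residual error with the systematic offset removed.

These are reported per stratum — season (DJF/MAM/JJA/SON), depth range
((0,15], (15,30], (30,50], (50,100] m) and sub-region — after a collocation
step that matches each decoded dive to the nearest model sea cell and daily
slice, averages profiles sharing a cell and day, and linearly interpolates
onto the model's vertical levels within the observed depth span only.

The decoding stage reconstructs sample times retroactively from each
record's elapsed-time trailer (`dt_time_min`), filters satellite fixes by
Argos location quality (default: class 0 only), splits records into dives
by 5-minute-lattice contiguity, truncates temporally incoherent sequences,
and discards surfacing (0 m) samples. An upper-ocean consistency check
pairs turtle samples with ARGO-style profiles within 10 km and ±15 days at
1-m depth bins.

## Worked example

Simulate two tagged turtles against the known-truth ocean, decode their tag
files, and validate against a model product carrying a known +0.5 °C bias
and 0.3 °C noise:

```r
library(diveTherm)

truth  <- oceanTruthParams()                  # seasonal logistic thermocline
window <- seq(as.Date("2021-01-01"), as.Date("2021-12-31"), by = "day")

sim    <- turtleSimParams(n_turtles = 2, n_dives_per_turtle = 20, seed = 1)
dives  <- simulateTurtleDives(sim, truth, window)
tagDir <- file.path(tempdir(), "tags")
encodeTagFiles(dives, tagDir)

dec <- decodeTagDirectory(tagDir)             # LQ-0 fixes only, by default
dec$profiles[[1]]
#> DiveProfile SYN201/SYN201_0001  fix 2021-11-21 12:00 UTC  LQ 0  (41.6822N, 17.7245E)
#>   17 samples, 10:25 .. 11:45, depth 2.0-24.1 m

span  <- range(as.Date(sapply(dives, function(d) as.character(d$date))))
prod  <- modelProductParams(bias_profile = 0.5, noise_sd = 0.3, seed = 2)
field <- generateModelField(truth, prod, seq(span[1], span[2], by = "day"),
                            sim$bbox)
pairs <- collocate(dec$profiles, field)

print(stratifiedSummary(pairs, by = "depth_range"), digits = 3)
#>   depth_range n_pairs n_obs     r        p  bias  rmse urmse
#> 1        0-15      97  2350 0.895 5.09e-35 0.493 0.572 0.290
#> 2       15-30      59  1818 0.839 1.03e-16 0.487 0.595 0.342
#> 3       30-50      29  1214 0.764 1.43e-06 0.500 0.584 0.301
#> 4      50-100      38  1758 0.912 1.56e-15 0.527 0.599 0.286
```

Reading the table: 21 of 40 simulated dives carried an LQ-0 fix and were
decoded (the rest are removed by the location-quality filter, with counts
in `dec$counts`); the recovered BIAS sits at the injected +0.5 °C in every
depth range, and uRMSE at the injected 0.3 °C noise level. `n_pairs` counts
matched (level, cell, day) pairs; `n_obs` the raw tag samples behind them.

The same chain runs as one call — `runPipeline()` — from a YAML or list
configuration that surfaces every constant (sampling interval, 175 m /
240 min tag caps, 100 m analysis cap, depth-range edges, ARGO thresholds,
admitted LQ classes), writes all stage outputs plus a manifest and a
reason-coded log, and is bit-reproducible under a fixed seed. A thin CLI
(`inst/scripts/divetherm`) exposes `simulate`, `decode`, `matchup`,
`stats`, `argo-check` and `run-all` subcommands.

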