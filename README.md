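# lumenosc

Mechanics and multiscale analysis of epithelial organoid **size
oscillations** — the repeated inflate-and-collapse cycles of single-layer
spherical organoids (pancreas- or liver-derived cultures and similar
systems) driven by osmotic inflation of the lumen and rupture of the cell
shell.

The package is aimed at groups doing long-term live imaging of organoid
cultures who want to (a) simulate the mechanics of the oscillation cycle,
(b) reason analytically about when oscillations should occur, and
(c) quantify them from segmented bright-field or light-sheet data.

## What is inside

**Scaling law.** A sphere has $V \sim A^{3/2}$; cells secrete an
osmotically active substance at a constant per-cell rate, so
$n \sim \int A(t)\,dt$ and the van 't Hoff pressure obeys

$$\Pi \sim \frac{\int A(t)\,dt}{A(t)^{3/2}}.$$

Pressure stays constant iff the surface grows like $t^2$: exponential
cell-number growth outruns the secretion and predicts no rupture, linear
growth falls behind and predicts oscillations
(`pressure_from_surface()`, `constant_pressure_exponent()`,
`classify_growth()`, `fit_piecewise_exp_linear()`).

**Agent-based simulator.** Cells are agents on a closed shell subject to
junction springs, outward luminal pressure $P = \kappa n/V$ and a
sphere-restoring bending force, integrated as an overdamped SDE
(Euler-Maruyama). The lumen gains substance per cell per hour, the shell
unseals when the mean neighbour distance crosses a rupture threshold,
vents, and reseals (`simulation_params()`, `division_schedule()`,
`simulate_organoid()`).

**Trace features.** From projected-area time series (mm², 30-min frames):
well-median normalisation to the fifth frame, 5 %-rule decline phases,
duration- and correlation-gated expansion phases, oscillation events,
expansion factors, circularity QC, Tukey-fence outliers and
Kruskal-Wallis well comparisons (`extract_features()`,
`culture_summary()`).

**Morphometry.** On nuclei-centroid clouds: Delaunay and proximity cell
graphs, convex-hull volume/surface, and centroid-matching segmentation
evaluation with recall/precision/F score (`delaunay_degrees()`,
`proximity_degrees()`, `match_centroids()`).

**Fixtures.** Seeded generators for every input shape, each carrying its
ground truth (`make_sawtooth_trace()`, `make_growth_curve()`,
`make_shell_cloud()`, `make_well_ensemble()`).

## Worked example

```r
library(lumenosc)

# 1. Which exponent balances secretion and growth?
p_star <- constant_pressure_exponent()
round(as.numeric(p_star), 4)
#> [1] 2

# 2. Simulate a small organoid under linear division for 100 h
p <- simulation_params(seed = 1)
traj <- simulate_organoid(p, division_schedule("linear", m = 0.25),
                          t_end = 100, N0 = 16)
traj
#> organoid trajectory: 10001 records, t = [0, 100] h, N = 16 -> 41, 5 rupture(s)

# 3. Extract mesoscale features from a synthetic well
well <- make_well_ensemble(n_organoids = 8, seed = 1)
f <- extract_features(well)
f[1:3, c("organoid_id", "oscillation_events", "avg_expansion_factor")]
#>   organoid_id oscillation_events avg_expansion_factor
#> 1       org01                  4            0.1582791
#> 2       org02                  3            0.1681717
#> 3       org03                  6            0.2607328

# 4. Evaluate a segmentation against ground truth
sc <- make_shell_cloud(N = 200, fn_rate = 0.2, seed = 3)
match_centroids(sc$gt, sc$seg)
#> centroid matching: TP 165, FP 0, FN 35 | recall 0.825, precision 1.000, F 0.904
```

The simulated trajectory reports, per 0.01-h step, the cell number, lumen
volume and substance, the best-fit radius, the pressure and rupture
events — the five ruptures above are the size-oscillation cycles of a
16-cell organoid whose linear division cannot keep up with secretion.
The feature table mirrors what the bright-field pipeline measures per
organoid; the matching result mirrors the nuclei-segmentation evaluation
(here recall 0.825 against a known 20 % deletion rate).

A command-line wrapper for shell use is installed at
`inst/cli/lumenosc` (subcommands `simulate`, `scaling`, `features`,
`morpho`, `generate`; all randomness flows from `--seed`).

## Vignette

`vignettes/organoid-oscillations.Rmd` documents the model assumptions,
the calibrated defaults and their rationale, the detection conventions
(including the deliberately pinned edge cases), and known limitations.
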