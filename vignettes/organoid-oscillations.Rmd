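---
title: "Modelling and measuring organoid size oscillations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and measuring organoid size oscillations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lumenosc)
```

Epithelial organoids grown from adult stem cells form a closed single-layer
cell shell around a fluid-filled lumen. The cells secrete osmotically active
substances into the lumen, the resulting van 't Hoff pressure inflates the
shell, and when the mechanical stress on the cell-cell junctions grows too
large the shell ruptures, vents the lumen, deflates and reseals. Live-imaged
cultures therefore show *size oscillations*: repeated inflation-collapse
cycles, more frequent in small organoids than in large ones. This vignette
documents the model and the analysis conventions implemented in `lumenosc`,
in the order a study would use them: the analytic scaling law, the
agent-based simulator, bright-field trace feature extraction, point-cloud
morphometry, and the synthetic-data generators used for validation.

## The osmotic scaling law

For a spherical monolayer the volume and surface obey $V \sim A^{3/2}$.
If every superficial cell secretes at a constant rate, the luminal amount
of substance is $n \sim \int A(t)\,dt$, and the osmotic pressure follows
$$\Pi \;\sim\; \frac{n}{V} \;\sim\; \frac{\int A(t)\,dt}{A(t)^{3/2}}.$$
`pressure_from_surface()` evaluates this by cumulative trapezoidal
integration. Requiring $\Pi$ constant pins the surface growth law: for
$A(t)=t^p$ the log-log slope of $\Pi$ is $1-p/2$, which vanishes at
$p=2$. `constant_pressure_exponent()` recovers this balanced exponent
numerically (root-bracketed fitted slope on a log-spaced grid; the first
5 % of the evaluation window is discarded because the trace of a power
law is singular at $t\to 0$):

```{r exponent}
p_star <- constant_pressure_exponent()
round(as.numeric(p_star), 4)
```

The direct implication, implemented in `classify_growth()`: cell counts
that grow at least like $t^2$ (in particular exponentially) keep the
pressure bounded and predict **no** oscillations; sub-quadratic growth
(linear counts, i.e. a mitosis rate decaying like $1/t$) predicts
rupture-driven oscillations. The classifier fits the last half of the
points (the asymptotic regime) on log-log axes and also accepts a
better-fitting exponential with positive rate; $t^2$ itself counts as
balanced. Both $N(t)$ and hull-derived $A(t)$ entry points are valid,
since the shell is one cell thick and $N \propto A$.

Observed growth records are summarised by
`fit_piecewise_exp_linear()`: $N(t) = N_0 e^{rt}$ up to a transition
time $t^*$, then a continuous linear continuation with slope $m$.
For fixed $(r, t^*)$ the model is linear in $(N_0, m)$, so $r$ is
profiled by 1-D optimisation and $t^*$ by a scan over the observed time
points — the sampling grid (30-min frames) is the finest identifiable
resolution. Near-ties resolve to the latest candidate, so purely
exponential records report $t^*$ at the end of the record with $m$ equal
to the instantaneous slope there.

## The mechanical agent-based model

`simulate_organoid()` integrates an overdamped Langevin model of the
shell. Each cell is an agent with a 3-D position and a fixed radius
(cell growth is neglected; daughters inherit the parent radius). Three
forces act on cell $i$:

* **junction springs** along the neighbour graph,
  $-k_\mathrm{spring}(\lVert x_i-x_j\rVert-\ell_0)\,\hat u_{ij}$;
* **luminal pressure** pushing outward along the radial direction,
  $P\,a_i\,\hat r_i$ with $P=\kappa n/V$ (ideal-gas/van 't Hoff law,
  $\kappa$ lumping $i_{vH}RT$) and the equal area share
  $a_i = 4\pi R_\mathrm{fit}^2/N$ (cells are treated as homogeneous);
* **bending**, realised as a harmonic restoring force toward the
  instantaneous best-fit sphere radius $R_\mathrm{fit}$ (the mean
  cell-centre distance). This is the simplest term that preserves the
  spherical shape while leaving uniform growth of $R_\mathrm{fit}$
  completely unpenalised.

Positions advance by Euler-Maruyama,
$x \leftarrow x + (F/\gamma)\,\Delta t + \sigma\sqrt{\Delta t}\,\xi$;
with $\sigma=0$ the map is the deterministic explicit Euler update and
trajectories are bit-reproducible for a fixed seed. The lumen gains
substance at $J_\mathrm{in}$ per cell per hour; when the mean neighbour
distance over all edges exceeds $\ell_\mathrm{rupt}$ the shell unseals
and vents at a constant $J_\mathrm{out}$ (a pressure-proportional
outflow is available as an option) until the mean distance relaxes
below $\ell_\mathrm{seal}$. Division follows a `division_schedule()`:
Poisson draws at the instantaneous rate, or deterministic tracking of a
target curve (including a lookup table interpolating an observed
growth record). Daughters are placed a tangential offset of
$0.2\,\rho$ from the parent.

The neighbour graph is the spherical Delaunay triangulation of the cell
positions projected radially onto their best-fit sphere, computed by
stereographic projection from one of the cells followed by a planar
Delaunay triangulation. For cells in convex position this is exactly
the convex-hull adjacency; for a jittered monolayer it keeps every cell
in the graph, which is the physically meaningful neighbourhood. It is
rebuilt after every division and every `rebuild_every = 5` steps (a
configurable speed-accuracy trade-off).

### Parameter choices and calibration

No mechanical parameter values are available from experiments, so the
defaults are *calibrated*, in micrometres and hours: cell radius
$\rho = 10$, rest length $\ell_0 = 20$ (one cell diameter),
$k_\mathrm{spring} = 1$, $k_\mathrm{bend} = 0.5$, $\gamma = 1$ (spring
relaxation time $\gamma/k = 1$ h), $\Delta t = 0.01$ h (safely below
the explicit-Euler stability bound $\gamma/4k_\mathrm{spring}$),
$\sigma = 0.05\,\mu m/\sqrt{h}$ (the noise amplitude is not
experimentally constrained; it is kept small and documented as free).
Rupture at $\ell_\mathrm{rupt} = 22$ (10 % junction strain), reseal at
$\ell_\mathrm{seal} = 21$. The osmotic constants $\kappa = 1$,
$J_\mathrm{in} = 3$, $J_\mathrm{out} = 4000$ and the initial pressure
$p_0 = 7\times10^{-4}$ (about 10 % of the rupture-scale pressure, so
runs do not start mid-rupture) were set by a Laplace-type force
balance and confirmed by simulation so that:

* a 64-cell organoid under slow linear division first ruptures on the
  scale of ten hours and then cycles;
* venting and deflation complete within 0.5–2 h, the observed duration
  of a collapse;
* exponentially dividing organoids (rates of a few percent per hour)
  stay below the rupture threshold throughout, as the scaling law
  demands.

### What the simulation studies use

The size-effect study runs a **common slow schedule** (linear,
0.25 cells/h, 100 h, ten seeds) across initial sizes
$N_0 \in \{16, 64, 256\}$. A deliberately slow common rate is used
because a fast absolute rate confounds the comparison: 1 cell/h grows a
16-cell organoid 8.6-fold in 100 h, and the division-driven surface
relief then masks the surface-to-volume effect under study (in
cultures, absolute division rates scale with organoid size — all
organoids grow about six-fold — so equal *absolute* rates across sizes
are not the experimentally relevant comparison either). Under these
conditions the median rupture count per 100 h is non-increasing in
$N_0$. The growth-regime study simulates a 64-cell organoid with an
exponential phase ($r=0.05$/h to $t^*=40$ h) and a linear continuation
(2 cells/h to 90 h): no ruptures occur before $t^*$ and at least one
after, for every tested seed.

```{r sim, eval = FALSE}
p <- simulation_params(seed = 1)
traj <- simulate_organoid(p, division_schedule("linear", m = 0.25),
                          t_end = 100, N0 = 16)
sum(traj$rupture_event)  # inflation-rupture cycles in 100 h
```

Known limitations: cells are mechanically identical (no cell-size
heterogeneity, which the data show matters for dense organoids), and
fusion, rotation, migration and intra-luminal duct dynamics are out of
scope.

## Bright-field trace features

The mesoscale pipeline starts from tables of projected luminal areas
(mm², 0.5-h frames) per organoid and well, the output shape of
watershed-based bright-field segmentation.

* **Normalisation** divides every area in a well by the median across
  the well's organoids of the *fifth* frame's area; the first four
  frames are kept but flagged, because segmentation during organoid
  formation is unreliable. Phase detection runs on frames 5 onward.
* **Decline phases** start at the time point after which the area drops
  by more than 5 % and end when the area increases again. The 5 % is
  referenced to the running local maximum since the previous phase end:
  the source rule does not name the reference, and the running peak
  makes the rule scale-free and lets slow stair-step declines
  accumulate into one phase.
* **Expansion phases** are the intervals between a decline's end and
  the next decline's start (trace start and end act as virtual
  boundaries), accepted when they span at least five frames and the
  Pearson correlation of the linear fit exceeds 0.9. Only degree-1
  fits are used since only slopes are reported downstream.
* A **size-oscillation event** is a decline followed immediately by an
  accepted expansion; a terminal unrecovered decline is not an event.
* **Expansion factors** are the mean and maximum accepted slope per
  organoid, per hour on the *normalised* scale (the measured factors
  are dimension-light; raw-area slopes would conflate size with
  speed). Organoids with no accepted phase contribute `NA` and are
  omitted from culture medians — scoring them 0 would bias the medians
  downward.
* **Quality control**: circularity $4\pi A/P^2$ per frame; any frame
  below 0.6 flags the organoid as deficiently segmented and excludes
  it. Outliers in average expansion use Tukey fences
  ($1.5\times$ IQR) with type-7 (linear-interpolation) quartiles,
  pinned for reproducible masks.
* **Culture summaries**: per-well medians/IQRs and a Kruskal-Wallis
  comparison of final normalised areas across wells. With a single
  well the comparison is skipped; when every value is identical the
  tie-corrected statistic is undefined and is reported as
  $H=0,\ p=1$.

```{r features}
we <- make_well_ensemble(n_organoids = 8, seed = 1)
f <- extract_features(we)
f[1:3, c("organoid_id", "initial_area", "oscillation_events",
         "avg_expansion_factor", "mean_circularity")]
```

## Point-cloud morphometry

Nuclei-centroid clouds (voxel units) support two neighbour graphs and a
segmentation-evaluation metric:

* `delaunay_degrees()` — the Delaunay cell graph. Adjacency is defined
  geometrically: two centroids are neighbours iff their Voronoi cells
  share a proper face, decided per pair by a small quadratic-program
  feasibility test with a degeneracy margin. On generic clouds this
  equals the tetrahedralisation adjacency (verified against a
  brute-force empty-circumsphere oracle); on degenerate cospherical
  inputs it gives the canonical polytopal answer (a regular octahedron
  has degree 4 everywhere — antipodal Voronoi cells touch only in a
  point).
* `proximity_degrees()` — centroids closer than a cutoff (default 50
  voxels) are neighbours.
* `approximate_volume_surface()` — convex-hull volume and surface of
  the cloud, a stand-in for mesh-based surface approximation that is
  adequate for convex, near-spherical organoids.
* `match_centroids()` — evaluation against a ground-truth cloud: a
  segmented centroid within ten voxels of a ground-truth centroid is a
  true-positive candidate and the closest wins. Matching is one-to-one
  and resolved globally greedily by ascending distance, which is
  deterministic and coincides with the per-centroid rule whenever no
  segmented centroid is nearest to two ground-truth centroids (the
  per-centroid formulation is silent on that conflict). Distances are
  in voxel units; an isotropic-micron mode can be had by scaling the
  inputs by the voxel size. Recall, precision and F follow the usual
  definitions; two empty clouds score 1 by convention (with a
  warning), one empty side scores 0.

## Synthetic fixtures

All validation inputs are generated, never downloaded, and each
generator attaches its ground truth: `make_sawtooth_trace()` (exact
injected event counts), `make_growth_curve()` (piecewise exp-linear
truth with optional multiplicative lognormal noise — noise must keep
counts positive), `make_shell_cloud()` (paired ground-truth/segmented
clouds with known deletion/addition/displacement rates) and
`make_well_ensemble()` (lognormal initial areas; smaller organoids
receive more injected oscillation events, emulating the observed size
dependence). Fixed seeds give bit-identical outputs. These fixtures
exercise every code path but are idealised: real traces carry
autocorrelated segmentation noise, missing frames and drift that the
generators do not emulate, so passing round-trips demonstrate
correctness of the *rules*, not robustness to every imaging artefact.

## Numerical conventions

Trapezoidal integration on log-spaced grids for pressure traces
(doubling the grid changes the trace by well under 0.1 %); burn-in of
5 % before constancy scoring; `uniroot`/`optimize` tolerances of
1e-6–1e-8; degenerate-geometry errors for coplanar or collinear hull
input; capped repulsion with a warning when two cells coincide within
1e-9 µm; Delaunay degeneracy margin of 1e-7 on the unit-scaled cloud.
Simulation problem sizes in the bundled studies (hundreds of cells,
10,000 steps, tens of seeds) were chosen to keep a full validation run
on a laptop in minutes while leaving the qualitative regimes clearly
resolved.
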