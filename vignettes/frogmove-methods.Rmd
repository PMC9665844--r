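---
title: "Methods: space use and navigation metrics for tracked poison frogs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: space use and navigation metrics for tracked poison frogs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frogmove)
```

## Scope and data model

`frogmove` analyses relocation ("fix") tables of individually tracked
poison frogs: one row per timestamped planar position, with an optional
behaviour annotation (`parental`, `mating`, `other`). Coordinates are
treated as an already-projected local engineering frame in metres — study
plots of this kind are mapped with precision compasses and laser distance
meters, so no geodesy is involved anywhere, and GPS ingestion is out of
scope. Timestamps are timezone-naive local clock time (stored as UTC);
calendar days break at local midnight. Duplicate `(animal, time)` fixes
are an error by default (`on_duplicate = "keep_first"` opts into silent
deduplication) because silent merging hides data problems.

## Sampling-rate standardisation

Tracking data of this kind are sampled irregularly, and behaviours of
interest (tadpole transport, courtship) are oversampled. Because every
spatial metric is sensitive to sampling rate, fixes are standardised by a
two-step downsampling procedure:

1. **Day-level thinning.** Days whose fix count exceeds the dataset daily
   mean by more than `daily_excess` (default 2) are reduced toward
   `target_daily` (default 4) fixes. The first and last fix of the day and
   every parental/mating fix are always retained; remaining slots are
   filled greedily by the fix maximising the minimum time gap to the fixes
   already kept (earliest fix on ties). In the original field workflow this
   selection was made by an experienced observer; the greedy rule is a
   deterministic, reproducible stand-in for that unrecoverable manual
   choice, and it preserves the same stated goals (temporal spread, rare
   behaviours).
2. **Minimum-interval scan.** A linear scan keeps a fix when at least
   `min_interval_min` (default 60) minutes have passed since the last kept
   fix, *or* when the animal moved more than `fast_move_m` (default 20)
   metres from it — so long, fast movements such as tadpole transport keep
   their intermediate points. The scan is idempotent, and its output is
   always a subset of its input, which bounds daily travel from above by
   the triangle inequality.

The fast-move comparison is made against the last *kept* fix (the
alternative — the immediately preceding raw fix — is not what a minimum
sampling interval means operationally; the choice is configurable through
the scan parameters and documented here because the field protocol leaves
it open). Navigation trajectories use a plain 15-min minimum-interval scan
(`nav_downsample()`), matching the finer protocol used after experimental
releases.

## Behaviour days and covariates

A fix is *parental* when annotated so or within 1 m of a known breeding
pool; male *O. sylvatica* are exempt from the pool-proximity rule (they
attend pools without providing care), implemented as a configurable
species-sex exemption table. A fix is *mating* when annotated so or within
1 m of an opposite-sex individual on the same day. A day is `parental` if
it has any parental fix, else `mating` if it has any mating fix, else
`other`; parental overrides mating because parental movements are larger
in scale. Daytime temperature is the mean of logger readings between
sunrise and sunset (fixed 06:00/18:00 by default — the study sites are
equatorial — and overridable per site). Capture–recapture extent is the
maximum pairwise distance among captures, reported only for animals whose
captures span at least 30 days.

## Space-use estimators

* **Daily travel**: cumulative Euclidean step length within a calendar
  day. A closed loop has positive travel; travel always dominates net
  displacement.
* **Movement extent**: the minimum convex polygon (MCP) over 100% of
  fixes, area by the shoelace formula; and the maximum linear distance
  (set diameter, computed on hull vertices and identical to the brute
  force pairwise maximum). Collinear fix sets yield a degenerate hull with
  zero area and a flag.
* **Home range**: the 95% utilization-distribution (UD) contour of a
  Gaussian-product-kernel density estimate. Bandwidths are selected per
  axis by the two-stage direct plug-in method (Sheather–Jones/Wand–Jones
  family, via `stats::bw.SJ(method = "dpi")`); a diagonal bandwidth
  matches the vector selector conventional in home-range work, and full
  bandwidth matrices are out of scope. The density is evaluated on a
  `grid_cells`² grid (default 256²) padded by `grid_pad` (default 3)
  bandwidths beyond the fix bounding box. The home range is the smallest
  superlevel set holding 95% of the *grid mass* (the utilization reading
  of "95%", as opposed to a sample-point quantile), and its area is the
  count of super-threshold cells times the cell area. Contour polygons at
  the threshold are attached for mapping; polygonized area differs from
  the cell-count area at O(cell size), which is documented rather than
  reconciled. Home ranges are only reported for animals tracked at least
  7 days with at least 8 fixes.

On bivariate normal data the 95% UD area has the closed form
π·χ²₀.₉₅(2)·σ² ≈ 18.8·σ², which the test suite uses as its oracle
(15% tolerance at n = 2000, where residual deviation is dominated by
plug-in oversmoothing of order h²/σ² ≈ 5%). The KDE grid extent and
resolution are free parameters; tests check convergence rather than any
particular grid.

## Navigation metrics

For a translocation record (release point and time, distance class,
pre-translocation home area, post-release track):

* **Home centre**: the coordinate-wise arithmetic mean of
  pre-translocation fixes ("geometric average" in the tracking
  literature); the home polygon is their convex hull.
* **Homing success**: true when some fix within the class window (3 days
  for ~50 m, 6 days for ~200 m, counted as 24-h periods from release —
  the protocol releases animals mid-afternoon, so calendar days would
  truncate the first window asymmetrically) comes within
  `(1 − homing_fraction)` (default 30%) of the release-to-home-centre
  distance. Both boundaries are inclusive. Homing is evaluated on the
  full-resolution track; area and straightness metrics use the 15-min
  downsampled track, exactly as the measures are split in the field
  protocol.
* **Explored area**: the union of 5-m perceptual-range buffers around
  every vertex and segment of the downsampled track. The union is
  computed on a raster distance field (default 0.25-m cells) with linear
  sub-cell coverage correction; against the exact "stadium" closed form
  10·L + 25π for a straight L-m path the relative error is ~3·10⁻⁵,
  far inside the 0.5% acceptance band. A single fix gives exactly π·r².
* **Straightness**: net displacement from the release site to the end of
  the homing trajectory divided by the cumulative path length, on the
  downsampled track truncated at the first fix inside the 10-m buffered
  home polygon — so the "end" is arrival, not post-arrival wandering.
* **Angular deviation**: signed difference between the bearing to the
  first crossing of the orientation band (the annulus 10 ± 5 m for 50-m
  classes, 40 ± 20 m for 200-m classes, i.e. ~20% of the translocation
  distance) and the bearing to home, wrapped into (−π, π]. The default
  `fix` mode uses the first fix inside the band; when a single step jumps
  the whole band, the crossing is linearly interpolated at the centre
  radius and flagged. An `interp` mode always interpolates the
  centre-radius crossing. Both are provided because sparse sampling makes
  the underlying field measurement ambiguous; `fix` is the default as the
  more conservative reading of "the first point where the frog crossed".
* **Homing duration**: release to the (linearly interpolated) crossing of
  the 10-m home buffer, with nights excluded. Implemented as the overlap
  of the release-to-entry interval with daytime windows (06:00–18:00);
  this equals "elapsed time minus 12 h per complete night" whenever both
  endpoints are in daytime and handles nightfall-boundary and
  partial-night releases without going negative.
* **Homeward normalization**: the rigid motion taking the release site to
  the origin and the home bearing to +y, used to overlay trajectories and
  to put angular deviations on a common scale (home = 0).

## Circular statistics

Initial orientation is tested with the directed Rayleigh (V) test:
`V = r·cos(θ̄ − μ)` with `u = V·√(2n)` against the one-sided
standard-normal upper tail. This is the "specified mean direction"
variant appropriate when home defines the expected direction; the plain
Rayleigh test is also exposed. The plain normal tail is used without
higher-order correction because its measured type-I error at n = 20 is
0.0499 (40,000-rep simulation) — already calibrated. For n < 5 the
asymptotic tail is unreliable and a seeded Monte-Carlo p-value (uniform
resampling) is forced with a warning. Sex differences in angular
distributions are compared by mapping angles to (cos θ, sin θ) and
running a two-group MANOVA; Wilks' Λ is converted to its exact F for two
response variables (Pillai's trace available by flag, since the
trigonometric-MANOVA convention does not fix the statistic).

## The synthetic-data generator

The generator exists so that every pipeline stage is testable without
field data; its defaults encode the study conditions the pipeline
assumes.

**Residents** follow a discrete Ornstein–Uhlenbeck walk
`x_{t+1} = x_t + κ(c − x_t) + ε`, `ε ~ N(0, σ²_daytype·I)`, at 48 latent
15-min daytime steps per day, with κ = 0.15 and σ chosen per species-sex
preset so that stationary spreads (σ_stat = σ/√(κ(2−κ))) give home
ranges of a few tens of m², the magnitude typical of these frogs.
Parental days overwrite a 5-h midday block with an out-and-back excursion
to the animal's pool (40 m away for the two larger species, 12 m for
*O. sylvatica*), reproducing the long fast movements of tadpole
transport. The observation operator samples 3–7 fixes per day
(probabilities 0.25/0.45/0.12/0.10/0.08 for 3–7, median 4) from slots at
least 75 min apart, adds two higher-frequency parental fixes on parental
days, annotates one mating fix on mating days, and adds 0.2 m of mapping
noise. Those spacing and count choices are made once, at design time, so
that the raw synthetic data are oversampled on behaviour days (as real
data are) while the two-step downsampling restores the 3–7 (median 4)
protocol.

**Translocations** follow a three-state switching walk at 15-min daytime
steps: `local` (mean-reverting steps near the release site), `explore`
(correlated random walk, von Mises turning angles, κ_turn = 4), and
`home` (von Mises headings around the true home bearing, κ_home = 8),
absorbed at the 10-m buffered home polygon. Von Mises headings make the
directedness-straightness relationship analytically tractable, and the
state mixture reproduces the qualitative phenotypes seen after field
releases: holding near the release site then direct return, versus
wide-ranging exploration. Sex and species presets modulate the explore
transition (males more exploratory) and step scale (*O. sylvatica*
smaller and, for 200-m releases, much less home-directed).

`make_study()` assembles the full dataset (fixes, pools, encounters,
temperature log, translocation records) deterministically from one seed;
the `"null"` scenario averages presets within species so the sexes are
exchangeable, and the `"paper_like"` scenario injects the caring-sex and
male-exploration effects.

What the generator does **not** emulate: vertical (climbing) movement —
so, as in real plot mapping, arboreal excursions are invisible to the
planar metrics; tag loss, predation, and injury; spatially heterogeneous
habitat; autocorrelated measurement error. Tests passing on synthetic
data therefore validate the estimators and the pipeline plumbing, not
field-data idiosyncrasies such as missed relocations or mapping drift.

## Numerical choices and test problem sizes

* UD threshold: cells are ranked by density and the threshold is the
  density at which cumulative normalized mass first reaches the UD level;
  ties are resolved by rank order, exact for the continuous densities
  that arise in practice.
* Buffer-union raster: 0.25-m cells with linear coverage correction; the
  grid doubles its cell size if it would exceed 4·10⁷ cells.
* Band-crossing and buffer-entry interpolation use root-finding on the
  (continuous) distance function along a step, tolerance 10⁻¹⁰.
* Degenerate inputs: single-fix trajectories downsample to themselves;
  zero translocation distance is an error; zero path length makes
  straightness undefined; zero resultant length leaves the mean direction
  undefined and flagged.
* Test problem sizes are chosen so the whole suite runs in minutes on one
  core: 200 random instances for geometry oracles (n ≤ 12 for the O(n³)
  hull oracle), 10 seeds × n = 2000 for the KDE closed form, 100 tracks
  for threshold monotonicity, 10,000 replicates for V-test calibration
  (the Monte-Carlo SE ≈ 0.0022 then sits well inside the ±0.01
  acceptance band on the type-I error), 400 label permutations for
  MANOVA p-uniformity, 450 simulated days (~2000 fixes) for stationary
  spread recovery, and a 10,000-replicate brute-force oracle for homing
  success calibration.

## Known limitations

* The KDE is a plain fixed-bandwidth estimator; autocorrelation-aware
  estimators (aKDE, Brownian bridges) are deliberately out of scope, so
  home ranges from strongly autocorrelated tracks inherit the classical
  negative bias of effective sample size.
* Grid-based UD areas change by O(cell size) under grid refinement.
* The day-level thinning rule is a reproducible surrogate for an
  observer's manual selection; on real data the two need not pick the
  same fixes, only the same sampling intensity.
* Statistical modelling of the exported tables (LM/LMM/beta-regression on
  sex, temperature, weight) is intentionally left to standard tools; the
  package's job ends at model-ready tidy tables.
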