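# frogmove

Space-use and navigation analysis for individually tracked poison frogs
(*Allobates femoralis*, *Dendrobates tinctorius*, *Oophaga sylvatica*) and
similar small territorial amphibians.

Field studies of these frogs track individuals for days to weeks in mapped
forest plots (planar coordinates in metres), annotate behaviours at each
relocation, and test navigation by translocating animals away from their
home areas. `frogmove` implements the full quantitative pipeline for such
studies:

* **Preprocessing** — two-step downsampling to a common sampling rate
  (day-level thinning toward ~4 fixes/day, then a 60-min minimum-interval
  scan that retains intermediate points of long (>20 m) fast movements),
  behaviour-day labelling (parental > mating > other, 1-m pool and
  opposite-sex proximity rules), sunrise-to-sunset temperature covariates,
  and capture–recapture extent with the ≥30-day span filter.
* **Space use** — daily travel (cumulative step length per day); movement
  extent as the minimum convex polygon (MCP) and as the maximum linear
  distance; and the home range as the 95% utilization-distribution (UD)
  contour of a Gaussian-kernel density estimate with two-stage direct
  plug-in bandwidths, i.e. the area *A* such that the kernel UD
  `f̂(x, y)` satisfies `∫_{f̂ ≥ c} f̂ = 0.95` with `A = |{f̂ ≥ c}|`.
* **Navigation** — homing success (≥70% of the release-to-home distance
  within 3/6 days for 50/200-m translocations), explored area (union of
  5-m perceptual-range buffers around the 15-min downsampled track),
  trajectory straightness (net displacement over path length, truncated
  at arrival), angular deviation from the home direction at the 10 ± 5 m
  or 40 ± 20 m band, homing duration with 12-h nights excluded, and
  homeward trajectory normalization.
* **Circular statistics** — the directed Rayleigh (V) test
  `V = r·cos(θ̄ − μ)`, `u = V√(2n)` for orientation toward a specified
  home direction, and a two-group trigonometric MANOVA on
  `(cos θ, sin θ)` for sex comparisons of angular distributions.
* **Simulation** — a site-fidelity (discrete Ornstein–Uhlenbeck) resident
  model and a three-state biased correlated random walk (local / explore /
  home, von Mises headings) for translocations, assembled by
  `make_study()` into complete deterministic synthetic studies.

Functions take data frames of fixes (one row per relocation) and return
tibbles, so stages chain with the pipe; test objects support `tidy()` and
`glance()`, and results have `autoplot()`/`plot_*()` methods.

## Worked example

Generate a synthetic study (2 animals per species and sex, 10 tracking
days, one translocation each) and run the full pipeline:

```r
library(frogmove)

study <- make_study(seed = 1, n_animals = 2, n_days = 10)
out <- run_pipeline(study)

dplyr::select(out$space_use, animal_id, sex, days_tracked,
              daily_travel_mean_m, extent_area_m2, home_range_m2)
#> # A tibble: 12 × 6
#>   animal_id sex    days_tracked daily_travel_mean_m extent_area_m2 home_range_m2
#>   <chr>     <chr>         <int>               <dbl>          <dbl>         <dbl>
#> 1 Af_f_01   female           10                4.43           11.4          17.4
#> 2 Af_f_02   female           10               12.1           104.           22.0
#> 3 Af_m_01   male             10               19.2           124.           44.8
#> 4 Af_m_02   male             10               13.9           168.           84.0
#> 5 Dt_f_01   female           10                6.94           33.6          60.2
#> 6 Dt_f_02   female           10                6.33           18.7          33.5
#> # ℹ 6 more rows
```

Per animal: days tracked, mean daily travel (m), MCP extent (m²), and the
95% UD home range (m²). In this paper-like scenario the caring sex ranges
wider — compare the *A. femoralis* males (home ranges 45–84 m²) with the
females (17–22 m²).

```r
dplyr::select(out$navigation, animal_id, distance_class, homing,
              explored_area_m2, straightness, homing_duration_h)
#> # A tibble: 12 × 6
#>   animal_id distance_class homing explored_area_m2 straightness
#>   <chr>     <chr>          <lgl>             <dbl>        <dbl>
#> 1 Af_f_01   d50            TRUE               576.        0.633
#> 2 Af_f_02   d200           TRUE              3069.        0.512
#> 3 Af_m_01   d50            TRUE              1656.        0.262
#> 4 Af_m_02   d200           TRUE              4589.        0.257
#> # ℹ 8 more rows
```

`homing` applies the 70%-of-distance criterion within the class window;
straightness and duration are reported only for homing animals. The
homeward-normalized angular deviations feed the directed Rayleigh test
(home direction = 0):

```r
rayleigh_homeward(out$angles$angular_deviation_rad, mu = 0)
#> Directed Rayleigh (V) test, mu = 0
#>   V = 0.477  u = 2.337  n = 12  p = 0.0097222 (asymptotic)
```

The simulated animals are significantly oriented toward home at the band
crossing (V = 0.48, p ≈ 0.01). `plot_homeward(study$translocations,
study$animals)` draws the normalized trajectories, and
`autoplot(home_range_ud(fixes))` maps a kernel UD with its 95% contour.

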