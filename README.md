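# kitecollide

Spatial collision-probability simulation between marine megafauna and a
tethered tidal kite.

Collision risk is a central consenting question for marine renewable energy
devices. For horizontal-axis turbines the classic blade-strike estimate

    P_C = N ω L cos(α) / v

(`N` blades turning at `ω` revolutions per second, animal of length `L`
passing at speed `v` under angle `α` to the flow) summarises the risk over
the rotor disc. A sub-sea tidal kite breaks that picture: a 3 m wing on a
25 m tether flies a figure-of-eight downstream of its seabed foundation, so
an animal can pass one component safely and still be struck by another
seconds later, and the risk is strongly non-uniform across the water column.

`kitecollide` simulates the full 4D encounter. The animal is a prolate
ellipsoid (semi-axes `L/2`, `L/3`, `L/3`) in straight transit; the device is
a tether capsule plus a parametric plate kite posed by three rotations about
the bottom joint:

    β(t) = arccos( (H − D + (h/2)·sin(4π/T·(t − δ))) / L_tether )   vertical, period T/2
    γ(t) = arcsin( (w/2)·sin(2π/T·(t − δ)) / (L_tether·sin β) )     lateral, period T

with `α` (spin about the tether axis) tracking the flight direction — a 2:1
Lissajous figure-of-eight. Per time step the exact minimum distances from
the ellipsoid to both components are evaluated; a distance below 1 mm is a
collision, recorded per component. An ensemble over `n` evenly spaced phase
lags `δ` per start position on a cross-sectional grid turns the
deterministic kinematics into a probability map, summarised by

    P_A      = 100 · NColl / NSim                      (whole cross-section)
    P_SweptA = 100 · NColl / (NCollPos · n_delays)     (collision-prone positions only)

where `NCollPos` counts the grid positions with at least one collision. The
distance kernels (ellipsoid–capsule, ellipsoid–mesh) and the trajectory loop
are compiled (Rcpp); the full 15 750-trial baseline sweep runs in about one
second and is bit-reproducible.

## Worked example

```r
library(kitecollide)

cfg   <- simulation_config()   # baseline: 21 x 15 grid, 50 phase lags, dt = 0.1 s
sweep <- run_sweep(cfg)        # 15750 deterministic trials
component_probabilities(sweep)
#> Collision metrics over 15750 trials
#>   collisions: 1772 (kite-only 520, tether-only 1222, both 30)
#>   collision-prone positions: 128
#>   P_A = 11.25%  (kite 3.49%, tether 7.95%)
#>   P_SweptA = 27.69%
#>   tether/kite ratio = 2.4
```

Read: over the whole investigated cross-section an animal transiting at a
uniformly random position and phase has an 11.25 % collision probability;
restricted to the 128 grid positions where a collision is possible at all
(the "swept area", the number comparable to `P_C` above) it is 27.69 %.
Most collisions are with the tether, not the wing. The per-position map
shows the structure — certainty at the mooring point, a mid-height minimum,
and a second maximum around the mean flight depth (13 m above the seabed):

```r
m <- probability_map(sweep)
m[m$z == 13 & abs(m$y) <= 2, c("y", "z", "p", "p_kite", "p_tether")]
#> # A tibble: 5 × 5
#>       y     z     p p_kite p_tether
#>   <dbl> <dbl> <dbl>  <dbl>    <dbl>
#> 1    -2    13  0.52   0.32     0.2
#> 2    -1    13  0.4    0.28     0.16
#> 3     0    13  0.32   0.28     0.16
#> 4     1    13  0.4    0.28     0.16
#> 5     2    13  0.52   0.32     0.2
```

`plot_probability_map(m)` renders the full scaled-circle figure.

`convergence_study(cfg, c(0.2, 0.1, 0.05))` repeats a sweep over decreasing
time steps to verify count stabilisation. A command-line wrapper is shipped
in `inst/cli/kitecollide.R`:

```sh
Rscript inst/cli/kitecollide.R sweep --config config.yaml --out-dir out
```

writing `trials.csv`, `metrics.csv`, `map.csv` and `manifest.json`.

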