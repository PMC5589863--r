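# spherochip

Multiscale image cytometry for anchored-droplet spheroid arrays.

Droplet-microfluidic chips trap agarose droplets — each seeded with ~200
cells — in a hexagonal array of capillary anchors (680 µm pitch, 250 µm
anchors, ~500 sites per 2 cm²). The cells in each droplet compact into one
spheroid per anchor, which is then cultured, stained and perfused in place
and imaged in bright field plus fluorescence. `spherochip` turns those
images into quantitative biology at three scales — population, spheroid and
single cell — and ships a synthetic image generator with planted ground
truth so the entire pipeline is testable without microscope data.

The pipeline implements:

* **Anchor grid** — matched-filter detection of the hexagonal anchor array
  (zero-mean hexagon template, gradient-space correlation, sub-pixel
  centres), frame-to-frame tracking, per-anchor cropping.
* **Segmentation** — bright-field objects from the Sobel gradient magnitude
  (Otsu support, rim exclusion, distance-map watershed split) and
  fluorescence objects from a per-anchor automatic threshold; largest-object
  selection; focus filtering by bright-field variance.
* **Morphometry** — area, smoothed-contour perimeter, equivalent diameter
  `D = 2√(A/π)` and shape index

  `ShI = 4πA / P²`   (1 for a perfect circle → 0 for a line),

  with the morphological sorting: discarded (D < 9 µm or out of focus),
  cell unit (9–40 µm), cell aggregate (D > 40 µm, ShI < 0.5), spheroid
  (D > 40 µm, ShI > 0.5).
* **Formation kinetics** — per-anchor exponential-relaxation fits
  `A(t) = A∞ + (A₀ − A∞)·exp(−t/τ)` with broom-style `tidy()`/`glance()`.
* **Single-cell cytometry** — nuclei / dead-cell / ALB peak detection with
  radial positions r/R; per-spheroid viability
  `100·(area − dead pixels)/area`; volume-effect correction of ALB peaks
  (cubic background `a(r/R)³ + b(r/R)² + c` fitted off-peak, subtracted,
  scaled by the centre background, chip-mean normalised to 1); BrdU/DAPI
  ratio-histogram gating; 3-nearest-neighbour distances with decile gating;
  a whole-frame 2-D culture mode.
* **Perfusion dynamics** — region-resolved (continuous / intermittent / no
  drug) dead-cell kinetics N̄_dead(t), per-spheroid viability trajectories,
  mean dead-cell r/R over time, and co-culture endothelial-core metrics.
* **Statistics** — the study's test conventions (Student/Welch t, Welch
  ANOVA + Games–Howell, Kruskal–Wallis + Mann–Whitney with Šidák
  correction) and Tukey box summaries with √n widths.

## Worked example

Simulate a small chip, render four channels, and run the whole analysis:

```r
library(spherochip)

layout <- chip_layout(chamber_w_um = 5000, chamber_h_um = 3500)
truth  <- simulate_chip(layout, sim_config(), seed = 42)
imgs   <- list(brightfield = render_chip(truth, "brightfield"),
               dapi  = render_chip(truth, "dapi"),
               fitc  = render_chip(truth, "fitc"),
               tritc = render_chip(truth, "tritc"))
res <- analyze_chip(imgs)
res
#> <chip_analysis> 33 anchors | 33 objects (25 spheroids) | 849 cell peaks
table(res$objects$class)
#> aggregate  spheroid      unit
#>         4        25         4
```

The 33 planted anchors are all found; objects sort into the three
morphological classes. Spheroid-level and cell-level readouts:

```r
sph <- res$objects[res$objects$class == "spheroid", ]
mean(sph$diameter_um); sd(sph$diameter_um)
#> 77.3   16.3        # planted from a 72.9 +/- 18.6 um distribution
mean(res$spheroids$viability, na.rm = TRUE)
#> 96.5               # percent; 5% of cells were planted dead
alb <- res$cells[res$cells$channel == "fitc" & !res$cells$excluded, ]
mean(alb$normalized)
#> 1                  # chip-normalisation identity, exact by construction
```

The normalised ALB amplitude is flat and low in the core and rises towards
the rim (0.67 for r/R ≤ 0.4 vs 1.09 beyond — the planted volume-corrected
radial profile). Formation kinetics from the time-lapse simulator:

```r
fit <- fit_formation(simulate_formation(seed = 42))
glance(fit)
#>   n_traces n_converged tau_median tau_iqr tau_pooled r_squared_median
#> 1      150         150       10.9    1.28       11.0            0.988
```

150 noisy traces generated at τ = 11 h are fitted back to a median τ of
10.9 h. Each result type has a plot: `autoplot(fit)` for the formation
spaghetti, `plot_death_series()`, `plot_radial_profile()`,
`plot_tukey_box()`, `plot_anchor_map()`.

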