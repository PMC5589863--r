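---
title: "Multiscale image cytometry of anchored-droplet spheroid arrays: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale image cytometry of anchored-droplet spheroid arrays: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spherochip)
```

## The system and the analysis problem

Anchored-droplet chips trap agarose droplets, each seeded with ~200 cells,
in a hexagonal array of micro-fabricated anchors (680 µm pitch, 250 µm
anchor diameter, ~500 sites per 2 cm² chamber). Over roughly a day the
cells in each droplet compact into a single spheroid, which can then be
cultured, stained and perfused in place. A motorised microscope images the
whole array in bright field plus up to three fluorescence channels, and all
quantification happens at three scales from those images:

* **population** — how many spheroids, their size and shape distributions,
  chip-level viability and proliferation;
* **spheroid** — per-object morphometry, class, viability, marker signal;
* **cell** — individual nuclei, dead cells and protein-expression peaks,
  each with a radial position inside its spheroid.

`spherochip` implements that pipeline end-to-end, together with a synthetic
image generator that plants known ground truth, so every stage is testable
without access to microscope data.

## Anchor detection and tracking

Anchors appear as dark hexagonal rims. Detection is matched filtering: a
regular-hexagon template (`build_hex_template()`) inscribed in a square of
side equal to the anchor diameter, zero-meaned and unit-normalised. Because
the rim is a *band*, its gradient magnitude carries a double ring; the
filter therefore correlates the Sobel gradient magnitude of the frame with
the gradient of the template's rim band, which peaks sharply at the true
centre (sub-pixel refinement by a 1-D parabola per axis; on noise-free
synthetic chips centres are recovered to ~0.2 px). Candidate maxima are
thresholded at mean + 3 sd of the response map and non-maximum-suppressed
at half a pitch — both exposed as arguments, since only the existence of a
"properly scaled hexagonal mask" convolution is fixed by the method, not
its constants. Time-lapse frames are linked by globally-nearest-neighbour
assignment gated at half a pitch (`track_anchors()`); anchors are physically
fixed, so tracks tolerate missed frames and re-acquire with a recorded gap.

## Segmentation

Two routes, matching the two imaging modes:

* **Bright field** (`segment_brightfield()`): objects have textured
  interiors, so the Sobel gradient magnitude is high inside them and ~zero
  on the smooth droplet background. The smoothed gradient map is
  thresholded by Otsu's criterion, cleaned by closing and hole-filling,
  restricted to a circular zone inside the anchor rim, eroded by 2 px (the
  outward bleed of a Sobel-plus-smoothing boundary response, measured on
  rasterised disks), and touching objects are split by a watershed on the
  distance map. The exclusion radius defaults to the hexagon's inscribed
  circle (apothem) minus a rim allowance — using half the vertex-to-vertex
  diameter would leave the rim mid-edges inside the zone and produce rim
  fragments as objects.
* **Fluorescence** (`segment_fluorescence()`): a per-anchor automatic
  threshold (Otsu) on the crop after smoothing at the nucleus scale
  (default σ = 2 px). The pre-smoothing matters: spheroid images are
  three-mode (background, diffuse out-of-focus object signal, bright
  nuclei), and Otsu on the raw histogram tends to split off the bright
  nuclei instead of the object. Smoothing folds the nuclei into the diffuse
  mode and restores the intended two-class problem. The chosen threshold is
  returned with every result; a crop with zero dynamic range yields no
  objects and a flagged, undefined threshold.

When several objects occupy one anchor (pre-fusion aggregates), the largest
is the spheroid of interest (`select_primary_object()`, ties to the lower
label, logged). Objects whose bright-field variance over the mask falls
below a threshold are out of focus and discarded (`focus_filter()`).

A monolayer (2-D culture) mode applies the same fluorescence routines to
whole frames, skipping anchor detection, the variance filter and
morphological sorting, and returns one ratio per image (`analyze_2d()`).

## Morphometry and classification

For a mask of area $A$ and perimeter $P$:

$$\mathrm{ShI} = \frac{4\pi A}{P^2}, \qquad D = 2\sqrt{A/\pi}.$$

The shape index is 1 for a perfect circle and tends to 0 for elongated
objects — which makes the perimeter estimator critical. Pixel-edge counts
(and raw marching squares) bias the perimeter of a rasterised disk upward,
giving ShI ≈ 0.78–0.88 for objects that should score 1. `mask_perimeter()`
therefore measures the length of the 0.5-level marching-squares contour
after a circular moving-average smoothing of its vertices, with a window
that scales with the contour's vertex count so the estimate is invariant
under integer mask scaling;
rasterised disks of radius 10–50 px then measure within ~1.5% of $2\pi r$
and ShI within 0.01 of 1. The cost is a small downward bias on sharp
corners (a rasterised square reads ≈ 0.82 instead of π/4 ≈ 0.785); since
the classification threshold at ShI = 0.5 separates round spheroids from
straggly aggregates, fidelity near ShI = 1 is the right trade.

Classification (`classify_object()`): discarded if $D < 9$ µm or out of
focus; cell unit if $9 \le D \le 40$ µm; aggregate if $D > 40$ µm and
ShI < 0.5; spheroid if $D > 40$ µm and ShI ≥ 0.5. The boundary conventions
($D = 40$ → unit, ShI = 0.5 → spheroid's side of the strict "< 0.5"
aggregate rule) are fixed here and asserted in tests; the underlying rules
use strict inequalities in both directions, so the measure-zero boundaries
needed a documented choice.

## Formation kinetics

Projected spheroid area during compaction is modelled as exponential
relaxation

$$A(t) = A_\infty + (A_0 - A_\infty)\,e^{-t/\tau},$$

fitted per anchor by Levenberg–Marquardt (`fit_formation()`, via
`minpack.lm`). The functional form behind a single "characteristic time" is
a modelling choice of this package; exponential relaxation is the simplest
law with that property and recovers its parameter exactly on noise-free
traces. Whether a population's τ should be the median of per-trace fits or
a single fit to the median trace is ambiguous, so `glance()` reports both
(`tau_median`, `tau_pooled`); on synthetic populations they agree within a
few percent. Non-convergent traces (e.g. constant series) are retained and
flagged rather than dropped.

## Single-cell cytometry

**Peaks.** Nuclei, dead cells and ALB expression maxima are local maxima of
the Gaussian-smoothed crop (σ = 1 px), restricted to the spheroid mask
dilated by 2 px, with prominence measured against a grayscale-opening
(top-hat) baseline and greedy non-maximum suppression at a configurable
separation (default 6 px ≈ two nucleus radii at the default calibration).
The top-hat baseline is what keeps the smooth out-of-focus dome from
gating in: structures wider than the structuring element survive the
opening and retain ~zero prominence, while sharp peaks keep their full
height. The automatic prominence floor is max(6 × noise sd, 10% of the
crop's dynamic range). Each peak gets $r/R$, its distance to the spheroid
centroid over the equivalent radius $R = D/2$; values slightly above 1 are
legitimate for boundary pixels of irregular masks.

**Viability.** Per spheroid,
$$\mathrm{viability}(\%) = 100\,\frac{\text{object area} - \#\{\text{pixels above the dead-stain threshold}\}}{\text{object area}},$$
with the threshold chosen per anchor on the dead channel. In the pipeline
the threshold is additionally required to stand clear of the crop's robust
background level (median + 4 MAD); otherwise the anchor contains no dead
signal and Otsu would be splitting noise.

**Volume-effect correction of ALB.** Wide-field images of a fluorescent
sphere collect out-of-focus light that brightens the centre. Per spheroid,
mask pixels farther than a configurable exclusion radius (default 4–5 µm)
from every peak are fitted with $a x^3 + b x^2 + c$ in $x = r/R$; each
peak's amplitude is corrected by subtracting the background at its radius,
scaled by $1/c$ (the background at the centre) to damp inter-spheroid
variability, and finally divided by the chip mean so the chip average of
normalised amplitudes is exactly 1. Spheroids whose fit fails or returns
$c \le 0$ are excluded from the chip mean and flagged. Correction preserves
amplitude ranks whenever the planted background is radially symmetric and
the peaks share a radius — an invariant asserted in the tests.

**BrdU gating.** The per-nucleus BrdU/DAPI amplitude ratio is split by
Otsu's criterion; the upper class is BrdU⁺. A split is only trusted when it
explains at least 75% of the ratio variance (a bimodality score); below
that the histogram is effectively unimodal and the gate falls back to
mean + 2 sd, flagged. On a unimodal normal population the best two-class
split explains ~64% of the variance and a well-separated planted positive
class ~85%, which locates the 0.75 default.

**Neighbour distances.** Within each spheroid, every nucleus gets the mean
Euclidean distance to its 3 nearest neighbours; cells below the first or
above the last decile of the chip-wide distribution are gated for radial
comparison. Quantiles use linear interpolation (R type 7) throughout.

## Perfusion death kinetics and co-culture

Anchors are assigned to three static horizontal bands (I drug-exposed
continuously, II intermittently with a 1 h half-period, III never);
spheroids are anchored, so static membership is faithful even though the
flow boundary wobbles. Per region and frame the pipeline reports
$\bar N_{\mathrm{dead}}$ (dead-cell peaks per spheroid), per-spheroid
viability trajectories with threshold-crossing counts and final
histograms, and the mean $r/R$ of dead cells. Dead-cell *counts* use peak
detection on the dead channel; the viability formula counts pixels — both
are implemented because they answer different questions (kinetics of
discrete deaths vs fraction of affected tissue).

Hetero-spheroid (co-culture) chips add endothelial cores: connected
components of the thresholded endothelial label inside the spheroid mask,
each reported with its centroid distance to the spheroid centre over $R$,
plus the spheroid's total label signal (`detect_cores()`).

## Statistics and reporting conventions

`compare_groups()` orchestrates the study's test choices: two-tailed
Student's or Welch's t for two groups; Welch's ANOVA followed by a
hand-implemented Games–Howell post hoc (Welch-type standard errors and
degrees of freedom against the studentized-range distribution — for two
groups it reduces exactly to Welch's t, which the tests use as an
independent check); and Kruskal–Wallis followed by pairwise Mann–Whitney U
with Šidák correction $p_{\mathrm{adj}} = 1 - (1-p)^m$. Stars follow
p < 0.05 / 0.01 / 0.001. Under a 3-group null the full rank-based chain
holds its family-wise type-I error below 0.055 at nominal 0.05 (asserted by
simulation with 5000 replicates). `tukey_box()` encodes the box-plot
conventions: type-7 quartiles, whiskers at the most extreme point within
1.5 IQR, the mean reported alongside the median, box width ∝ √n.

## The synthetic chip generator

`simulate_chip()` plants, per anchor, one object drawn as spheroid /
aggregate / cell unit (85% / 9% / 6%, matching the reported composition of
real chips), with spheroid equivalent diameters from a truncated normal
(72.9 ± 18.6 µm), near-circular spheroids (axis ratio 0.88–1) and strongly
elongated aggregates (0.12–0.25, i.e. true ShI ≈ 0.35–0.5). Cells are
placed with a core-dense radial law ($r/R = U^{1/1.4}$) and a 7 µm minimum
nucleus spacing; a 5% dead fraction sits edge-biased at $r/R \sim
\mathrm{Beta}(8,2)$ (mean 0.8); 16% of nuclei are BrdU⁺ with 1.5-fold
enrichment at $r/R \ge 0.8$; ALB amplitudes are flat to $r/R = 0.4$ and
rise towards the rim, on top of a cubic out-of-focus dome. Bright field
renders dark hexagonal rim bands and speckle-textured object interiors —
enough structure for a gradient segmenter without modelling optics.
Fluorescence renders each emitter as a Gaussian spot plus the
channel-specific diffuse components; Gaussian read noise (optional Poisson
shot noise) is applied last. All randomness flows from a single seed:
identical configuration and seed give bit-identical truth tables and
rasters.

`simulate_formation()` adds a median-preserving log-normal spread
(cv 0.08) on τ across traces — real anchors compact at visibly different
rates — plus multiplicative observation noise; the defaults are the
hepatoma condition (τ = 11 h, 3:1 compaction, 20-min sampling over 23 h).
`simulate_perfusion()` plants the drug-response phenomenology as rates:
early-dying spheroid fractions 0.19 / 0.21 / 0.094 in regions I / II / III
(the reported per-region counts of affected spheroids), a fast mechanism
that kills an early dier's cells within a few hours at edge positions, a
small spontaneous trickle everywhere, and a slow mechanism in region I only
that starts at 5 h and kills 0.6 cells/spheroid/h at positions drifting
inward at 0.08 r/R per hour. With ~130 spheroids per region this yields a
~2-fold region II/III dead-cell ratio, a sharp post-onset rate break in
region I, and the characteristic inward drift — the recovery of each being
what the tests assert. `simulate_coculture()` assigns endothelial mixing
ratios in loading blocks and plants cores whose expected count
$1 + \mathrm{Pois}(2.2(1-\rho)^2)$ and mean centre distance
$0.55(1-\rho)$ shrink with the ratio ρ, while total core cross-section
grows with it.

**What the generator does not emulate** — and hence what green tests do not
show about real data: optical PSF physics and depth-dependent blur,
droplet hydrodynamics, cell-scale texture inside nuclei, stain bleed-through
between channels, illumination gradients across the chamber, and focus
drift. Results on real images will degrade gracefully with those effects
(thresholds and filters are per-anchor and robust), but recall/precision
figures measured here are upper bounds.

## Numerical choices and problem sizes

* Coordinates are 1-based pixel centres, `[row, col]`, row 1 at the top;
  physical units are µm via `(index − 0.5) × pixel_size`. Default
  calibration 1.29 µm/px (10× objective), always explicit and configurable.
* Quantiles: type 7. Degenerate fits (constant traces, all-background
  crops, fully-covered anchors) return flagged results, never errors, when
  the input is valid per the contract; contract violations (empty masks,
  non-positive pitch) error early with the offending record named.
* Test problem sizes: unit fixtures use 1–30-anchor chambers at
  1.29 µm/px; the end-to-end property runs the full 500-anchor, 2 cm²
  chamber at 3.2 µm/px (a low-magnification calibration), which keeps the
  whole-chip raster at ~20 Mpx and the complete simulate–render–analyze
  cycle around two minutes on one CPU. The type-I-error simulation uses 5000
  replicates of 3 × 15 samples.

## Known limitations

* The fluorescence Otsu threshold retains a small upward bias when the
  object occupies a few percent of the crop, trimming ~2–3 px of rim;
  equivalent diameters from the fluorescence route read ~5% low, and
  bright-field segmentation is the reference for size statistics.
* Smoothed-contour perimeters over-score sharp-cornered objects (square →
  ShI 0.82 vs π/4); immaterial for the round/straggly discrimination the
  classifier performs.
* Dead-cell counts undercount when deaths cluster within one suppression
  radius; dead-pixel viability is insensitive to this, which is one more
  reason both are reported.
* Peak detection at the default separation merges true neighbours closer
  than ~6 px, so absolute nucleus counts are lower bounds; radial and
  ratio-based quantities, which the biology rides on, are unaffected.
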