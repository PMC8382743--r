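---
title: "Methods: image cytometry and gradient modelling for metabolic microenvironment chambers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: image cytometry and gradient modelling for metabolic microenvironment chambers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memic)
```

## The system being modelled

A metabolic microenvironment chamber (MEMIC) is a culture device in which a
cell monolayer sits in a shallow inner chamber that communicates with a large
reservoir of fresh medium through a single opening along one edge.  Cells
consume oxygen and nutrients faster than diffusion through the opening can
replenish them, so stable concentration gradients form along the chamber:
cells near the opening live in near-physiological conditions while cells at
the sealed end become progressively ischemic.  Because the geometry is
known, position along the chamber is a direct readout of metabolic
condition, and per-cell fluorescence measured as a function of distance from
the opening quantifies how cells respond to that condition.

This package implements the full analysis stack for such experiments:

1. **Synthetic scenes** — a ground-truth-annotated image generator so every
   downstream stage is testable without microscope data.
2. **Image cytometry** — nuclei detection, optional watershed splitting,
   Voronoi-constrained expansion to cell territories, and per-cell
   measurement of position, area and channel intensities.
3. **Spatial profiling** — distance assignment, per-cell normalisation,
   moving median ± interquartile profiles, binned positive fractions, and
   half-maximal signal positions.
4. **Comparison statistics** — proximal-vs-distal rank-sum tests, one-way
   ANOVA on replicate half-max positions, per-bin t-tests against the most
   proximal bin, and a doubled-control-median high-expressor classifier.
5. **A gradient simulator** — a one-dimensional diffusion–consumption model
   with a threshold-type hypoxia-reporter response.

## Synthetic scenes

`scene_params()`/`generate_scene()` emulate the stitched 16-bit grayscale
TIFF exports of tiled chamber imaging: one image per channel, a uniform
nuclear stain plus any number of reporter channels.  Nuclei are rendered as
disks with an optional Gaussian edge profile (a hard disk blurred by a small
Gaussian, computed analytically with the normal CDF), placed uniformly with
a minimum centre spacing by rejection sampling.  Each cell's reporter
intensity is an arbitrary user function of its x position, so the true
spatial signal is known exactly.  Noise is additive Gaussian with optional
Poisson shot noise, applied before quantisation to the bit depth with
saturation clipping.

Conventions the rest of the package relies on:

* the opening edge is at `x = 0`, the image's left border, so a cell's x
  coordinate is its distance from the opening and no registration is needed;
* physical position is 0-based pixel index × pixel size, so the first pixel
  centre sits at 0 µm;
* with `noise_sd = 0` and `edge_sigma = 0`, the mean intensity inside each
  true nucleus mask equals the requested true intensity exactly (integer
  intensities survive quantisation unchanged), which is the fixture for
  measurement-exactness tests.

The pixel size of the emulated microscope is configurable and defaults to
1 µm/px; chamber-scale benchmark scenes in this package use 2 µm/px so a
5 × 2 mm field stays at 2.5 Mpx.  Intensity scales are chosen the way a
real acquisition would be set up: signals sit well above the quantisation
floor, because a channel whose dim plateau is far below the noise standard
deviation would clip at zero and bias means upward — real cameras avoid
exactly this with a bias offset.  What the generator deliberately does
*not* emulate: tile seams and stitching artefacts, illumination shading,
nuclear texture, 3-D structure, or cell shapes beyond disks.  Passing the
recovery tests therefore demonstrates correctness of the measurement
pipeline, not robustness to every artefact of real microscopy.

## Image cytometry

`detect_nuclei()` operates on the uniform-stain channel: Gaussian smoothing
(`smoothing_sigma`, default 1 µm), thresholding (Otsu by default — it is
parameter-free and reproducible; a fixed threshold is available for dim
stains), connected-component labelling, and optionally marker-based
watershed on the Euclidean distance transform to split touching nuclei.
Watershed seeds are merged when the distance-map depth separating them is
below `h_minima_depth` (default 1 µm): deep enough to ignore the pixel-level
roughness of a digitised disk, shallow enough to split nuclei overlapping
by a third of their radius.  Detected regions outside the
`[min_nucleus_area, max_nucleus_area]` filter (defaults 20–400 µm²,
bracketing a 5 µm-radius nucleus at ~79 µm²) are discarded.

`segment_cells()` grows each nucleus into a cell territory: every
background pixel within `cell_expansion_radius` of a nucleus is assigned to
its *nearest* nucleus pixel under exact Euclidean distance (a
Felzenszwalb–Huttenlocher distance transform with nearest-site tracking,
implemented in C++), i.e. nucleus dilation clipped by the Voronoi
diagram.  This is the simplest contract consistent with whole-cell
intensity measurement when no membrane marker is available; the default
radius is 0 (nucleus-only measurement) so any expansion is an explicit
analysis choice.  Ties between equidistant nuclei are resolved
deterministically but arbitrarily; the test suite checks agreement with an
exhaustive per-pixel oracle wherever the nearest nucleus is unique.

`measure_cells()` reports, per label: centroid (µm), area (µm²) and the
mean **raw** pixel value per channel.  No normalisation is applied at this
stage — `normalize_channel()` makes the reporter/nuclear ratio an explicit,
auditable downstream step.  Rows are ordered by ascending label, and an
empty label map yields an empty table with intact chamber metadata.

## Spatial profiling

`assign_distance()` converts centroids to distance from the opening using
an `opening_spec()` (edge axis and offset).  Cells on the reservoir side of
the edge get distance 0 and an `outside_chamber` flag and are excluded from
profiles by default.

`moving_profile()` computes, on a regular grid of window centres covering
`[0, max distance]`, the median and quartiles of a value over cells in the
half-open window `[c − w/2, c + w/2)`.  Defaults: window width 100 µm, step
25 µm, at least 20 cells per window.  These were chosen once so that
millimetre-scale chamber gradients are resolved by well over ten windows
while a window still averages enough cells to stabilise the median at
typical seeding densities; published chamber analyses rarely state their
smoothing windows, so the defaults are configurable and recorded in the
profile's attributes.  Windows below the count threshold are kept in the
grid with `NA` statistics rather than silently interpolated.

`half_max_position()` summarises a profile by the smallest distance at
which the median curve first reaches
`min + 0.5 · (max − min)`, linearly interpolated between window centres.
The profile's own minimum — not zero — is the baseline, which makes the
statistic robust to non-zero background fluorescence and invariant to
positive scaling of the values; translating all distances shifts it
one-for-one.  A flat profile has no gradient and raises an error, mirroring
the practice of excluding no-gradient control chambers from position
comparisons.

`binned_fraction()` bins cells into contiguous half-open intervals
`[lo, hi)` anchored at 0 and reports the fraction of cells whose marker
strictly exceeds a threshold, per replicate and bin — the per-bin
percent-positive representation used for proliferation markers.

## Comparison statistics

* `proximal_distal_test()` — two-sided Wilcoxon rank-sum comparing the
  `n_each` smallest-distance cells against the `n_each` largest-distance
  cells (default 10,000 per group, the scale of full-chamber cytometry;
  clamped with a warning on smaller tables).  "First and last cells" are
  defined by distance order, never table order.  Groups of ≤ 10 are tested
  by exhaustive enumeration of the permutation distribution of the rank sum
  (midranks, so ties are exact); larger groups use the tie-corrected normal
  approximation with continuity correction.
* `compare_half_max()` — fixed-effects one-way ANOVA across treatment
  groups of replicate half-max positions.  Replicates with undefined
  half-max (no gradient) are dropped and counted; identical group means
  degenerate to F = 0, p = 1 by convention.
* `bins_vs_first_bin()` — two-sided unpaired Student's t-test of each bin's
  replicate fractions against the first bin's (the first bin against itself
  is p = 1).  Student, not Welch, is the default because equal-variance
  unpaired t-tests are the convention for such per-bin comparisons; Welch
  is a flag.  No multiple-testing correction is applied by default —
  matching how per-bin tests are conventionally reported — with optional
  Holm adjustment appended as a separate column.
* `classify_high()` — a cell is a high expressor when its value strictly
  exceeds `k` times the control median (default `k = 2`).  The strict
  inequality is a boundary convention made explicit here; the rule is
  invariant to positive rescaling of all values.

Per-cell tests on spatial data ignore spatial autocorrelation; within a
chamber, neighbouring cells share their microenvironment, so p-values from
`proximal_distal_test()` describe the sampled cells, not independent
biological replicates.  This is a known limitation of the approach, which
is why position comparisons across *chambers* (the half-max ANOVA) treat
the chamber, not the cell, as the replicate unit.

## The gradient simulator

The model is a deliberate one-dimensional reduction.  Cells sit on the
chamber floor at areal density $\rho$ (cells/µm²), each consuming at up to
$q$ (amount/cell/s) from a medium column of height $h$; the reservoir
clamps the concentration at the opening.  With Michaelis–Menten
utilisation $u(c) = c/(c + K_m)$:

$$\frac{\partial c}{\partial t} = D\,\frac{\partial^2 c}{\partial x^2}
  - \frac{\rho q}{h}\,u(c), \qquad c(0, t) = c_0, \qquad
  \left.\frac{\partial c}{\partial x}\right|_{x=L} = 0,
  \qquad c(x, 0) = c_0.$$

Two structural consequences drive the chamber's observed behaviour and are
asserted as tests:

* **The opening width does not appear in the equations.**  A well-mixed
  reservoir boundary condition already encodes any opening; sweeping the
  width leaves profiles bit-identical.  Experimentally this is why the
  coverslip edge can be used as the distance reference without precise
  control of the opening.
* **Consumption scales as $1/h$.**  Taller medium columns dilute the areal
  sink, which is why chamber height sets the position and slope of the
  gradient.

For $K_m = 0$ (zeroth-order consumption with a hard floor at $c = 0$) the
steady state has a free boundary — the anoxic front — with the closed form

$$c(x) = c_0 - \frac{\rho q}{2 D h}\, x\,(2x^* - x)
  \quad\text{on } [0, x^*], \qquad
  x^* = \sqrt{\frac{2 D h c_0}{\rho q}},$$

and $c \equiv 0$ beyond $x^*$.  Density and height therefore move the
front as $x^* \propto \rho^{-1/2}$ and $x^* \propto \sqrt{h}$, the
monotone orderings checked by `predict_effects()`: denser cultures steepen
gradients and pull them toward the opening, taller chambers push them in,
and below a critical density the minimum concentration never reaches the
reporter threshold and the reporter stays silent chamber-wide.

### Numerical choices

* **Steady state, $K_m = 0$:** the free-boundary problem is a linear
  complementarity (obstacle) problem.  A damped fixed point on the binary
  utilisation term cycles between active sets and never converges, so
  `steady_state()` uses a primal active-set method instead: solve the
  tridiagonal system on the current oxygenated interval, shrink it where
  the solution would go negative, extend it where an exhausted node would
  receive more diffusive inflow than its cells consume.  On the default
  grid this reproduces the closed-form parabola to machine precision and
  places the front on the correct grid node.
* **Steady state, $K_m > 0$:** Picard iteration with the utilisation
  linearised as $c/(c_{\text{prev}} + K_m)$; each sweep is an exact
  tridiagonal solve and the iteration converges smoothly because the
  source vanishes with $c$.
* **Time course:** Crank–Nicolson for diffusion (unconditionally stable;
  an explicit scheme with the $D\,\Delta t/\Delta x^2 \le 1/2$ guard is
  kept as an independent cross-check), with the consumption term treated
  semi-implicitly as $k(c_m)\,c_{m+1}$, $k = \text{rate}\cdot u(c_m)/c_m$.
  This keeps every update positive without clamping chatter at the anoxic
  front, and its fixed point is exactly the discrete steady state.  The
  linearisation leaves a residual non-monotonicity of order
  $3\times10^{-5}\,c_0$ at the front for the default
  $\Delta t = 60\,\mathrm{s}$ (shrinking with $\Delta t$), so the
  monotone-decrease contract is asserted to $10^{-4} c_0$.
* **Defaults are normalised:** $c_0 = 1$, oxygen-like
  $D = 2000\ \mu m^2/s$, $L = 5\,\mathrm{mm}$, $h = 500\ \mu m$,
  $\rho q$ set so the anoxic front sits mid-chamber at 2 mm.  Absolute
  calibration of $q$ and $\rho$ to a specific cell line is out of scope;
  only profile shapes, orderings and scalings are claimed.  The reporter
  response is a Hill function of concentration around a threshold
  ($n = \infty$, a hard step, models the digital stabilise-or-degrade
  behaviour of oxygen-labile transcription factors), low-pass filtered
  with a maturation time constant using an exact exponential update.

## Problem sizes used by the test suite

Verification scenes were sized to exercise the methods at chamber scale
while keeping the suite quick to run: one 5 × 2 mm scene with ~5,000 cells
at 2 µm/px and nuclear SNR 5 for end-to-end midpoint recovery (recovered
within ±50 µm of the true 2,000 µm); ten 0.8 × 0.8 mm scenes of 120 cells
for detection-rate estimation (≥ 95% matched within 2 px, ≤ 2% spurious);
1,000 simulated null replicates per statistical test for type-I-error
calibration at α = 0.05; and simulator grids of 201–501 nodes.  All
fixtures are generated in code from fixed seeds.

## Known limitations

* No learned or texture-based segmentation; densely overlapping nuclei
  beyond what distance-transform watershed separates will undercount.
* Profiling is strictly one-dimensional (perpendicular to the opening); no
  two-dimensional spatial statistics.
* The simulator couples a single metabolite; secretion/cross-feeding of
  byproducts, cell growth and death feedback on density, and full 3-D
  chamber geometry are out of scope, so quantitative agreement with any
  particular measured gradient is not claimed — only the qualitative
  determinants validated here.
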