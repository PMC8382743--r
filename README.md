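# memic

Image cytometry and gradient modelling for metabolic microenvironment
chambers (MEMICs) — culture devices in which a cell monolayer accesses
fresh medium through a single opening, so that consumption establishes
oxygen and nutrient gradients along the chamber.  Distance from the
opening then encodes metabolic condition, and per-cell fluorescence versus
distance quantifies how cells respond to ischemia.  The package is aimed
at groups running such chamber experiments (tumour microenvironment,
hypoxia reporters, proliferation gradients) who need a reproducible path
from stitched microscope exports to per-cell statistics, and at anyone who
wants to reason about what gradients a chamber geometry will produce
before running it.

It provides, as composable tidyverse-style functions:

* **Single-cell image cytometry** for stitched 16-bit multi-channel TIFFs:
  nuclei detection (Gaussian smoothing + Otsu), watershed splitting of
  touching nuclei on the distance transform with h-minima seed merging,
  Voronoi-constrained expansion of nuclei into cell territories (exact
  Euclidean distance transform in C++), and per-cell measurement of
  centroid, area and raw mean intensity per channel.
* **Distance-resolved profiling**: distance from the opening edge, per-cell
  channel normalisation, moving median ± interquartile profiles, binned
  positive fractions, and the half-maximal signal position

  `x_half = smallest x with median(x) = min + 0.5 (max − min)`.
* **The field's comparison procedures**: a proximal-vs-distal Wilcoxon
  rank-sum test (the n nearest vs the n farthest cells, exact enumeration
  for small groups), one-way ANOVA on replicate half-max positions,
  per-bin unpaired Student's t-tests against the most proximal bin, and a
  strict `value > k · median(control)` high-expressor classifier.
* **A diffusion–consumption simulator** of gradient formation:

  `∂c/∂t = D ∂²c/∂x² − (ρq/h) u(c)`, `c(0) = c0`, `c'(L) = 0`,

  with Michaelis–Menten utilisation `u(c) = c/(c + Km)` (zeroth-order with
  an anoxic free boundary for `Km = 0`, where the steady state is the
  parabola `c0 − (ρq/2Dh) x (2x* − x)` with front `x* = √(2Dhc0/ρq)`), and
  a threshold-type hypoxia-reporter response with maturation filtering.
* **A synthetic scene generator** producing ground-truth-annotated
  chamber images (nuclear stain + reporter channels as known functions of
  distance), so the whole pipeline is testable with no external data.

## Worked example

Simulate a chamber monolayer with a hypoxia-reporter midpoint at 800 µm,
run the cytometry pipeline and recover it:

```r
library(memic)

p <- scene_params(
  field_width = 2000, field_height = 1000, n_cells = 1200,
  reporter_functions = list(
    gfp = function(x) 3000 + 5000 / (1 + exp(-(x - 800) / 150))),
  nuclear_intensity = 10000, background_level = 200, noise_sd = 1000,
  rng_seed = 42)
scene  <- generate_scene(p)
labels <- detect_nuclei(scene$images$nuclear, segmentation_params())
cells  <- measure_cells(labels, scene$images) |>
  assign_distance(opening_spec("left", 0))
head(cells, 3)
#>   cell_id  x_um  y_um area_um2 gfp_mean distance_um
#> 1       1 1311. 266.       142    7766.       1311.
#> 2       2  207.  41.9      138    3102.        207.
#> 3       3 1770. 201.       137    7956.       1770.

prof <- moving_profile(cells, "gfp_mean")  # window 100 um, step 25 um
half_max_position(prof)
#> [1] 807.9814
```

All 1,200 nuclei are detected; the measured per-cell GFP means follow the
programmed logistic, and the half-max position lands 8 µm from the true
midpoint.  `autoplot(prof)` draws the moving median with its IQR band.
The proximal cells differ from the distal cells overwhelmingly:

```r
tidy(proximal_distal_test(cells, "gfp_mean", n_each = 300))
#>   method                                statistic  p_value n_proximal n_distal
#> 1 proximal-distal rank-sum test (norm…          0 1.05e-99        300      300
```

On the modelling side, the default chamber (5 mm long, 500 µm of medium,
oxygen-like D = 2000 µm²/s) goes anoxic exactly where the closed form
says it should, and sweeping the chamber height moves the reporter
half-max deeper:

```r
spec <- chamber_spec()
ss   <- steady_state(spec)
attr(ss, "anoxic_front_um")   # 2000, = analytic anoxic_front(spec)

predict_effects(chamber_spec(dx_um = 25), "medium_height_um",
                c(250, 500, 1000))
#>   param            value half_max_um max_signal
#> 1 medium_height_um   250        962.          1
#> 2 medium_height_um   500       1362.          1
#> 3 medium_height_um  1000       1938.          1
```

Sweeping the *opening width* instead leaves every profile bit-identical —
the width never enters the equations, which is why the coverslip edge is a
valid distance reference regardless of how the chamber was assembled.

A thin command-line front end over the same functions is installed at
`system.file("cli", "memic.R", package = "memic")` with `segment`,
`profile`, `stats` and `simulate` subcommands.

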