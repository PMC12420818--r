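# kinetoquant

Quantification of kinetochore and pericentromere fluorescence signals in
mitotic cells, for cell biologists measuring spindle-checkpoint and
chromosomal-passenger-complex (CPC) biology from multi-channel microscopy
z-stacks.

The package implements three measurement pipelines plus the statistics and
synthetic data needed to validate them:

* **Spot recruitment** — per-kinetochore intensity of a measured protein
  (e.g. MPS1) relative to a reference kinetochore marker (e.g. CENP-C):
  a white top-hat transform of the reference channel is thresholded by the
  iterative-intermeans (isodata) method into a kinetochore mask; 8-px
  circular ROIs (exactly 52 pixels each) are placed at the 20 brightest
  non-overlapping maxima; a 52-px background ROI is accrued radially around
  each spot, skipping masked kinetochore signal; and the readout per
  kinetochore is

  `ratio = max(ROI − BG, 0)_channel / max(ROI − BG, 0)_reference`,

  averaged per cell (the cell is the biological replicate).
* **Region signals** — chromatin-associated CPC/Aurora B and H3pS10 per
  cell: chromatin mask from the DNA channel, cytoplasmic background
  subtraction for CPC-class channels, normalisation by the mean DNA signal,
  and scaling to the control-condition mean.
* **Distances** — inter-kinetochore (KT–KT) and intra-kinetochore distances
  from line profiles with sub-pixel Gaussian peak fits:
  `d = |µ_A − µ_B| × pixel size`.

Statistics follow field convention: pooled-variance two-tailed unpaired
t-tests for distances, Kruskal–Wallis with Dunn's post hoc z-tests
(Bonferroni over planned comparisons) for recruitment, and the usual
`ns/*/**/***/****` star mapping.

A synthetic mitotic-image generator (`scene_spec()`, `render_scene()`,
`make_distance_dataset()`, `make_condition_dataset()`) renders
PSF-blurred spot pairs, pericentric bands, chromatin and cytoplasm with
Poisson + read noise and full ground truth, so every stage of the pipeline
is tested by parameter recovery rather than by eye. See the methods
vignette (`vignettes/methods.Rmd`) for the model and all defaults.

## Worked example

Quantify a synthetic cell in which the `measure_1` channel has the same
kinetochore amplitude as the reference and `measure_2` is a pericentric
band (not a spot):

```r
library(kinetoquant)

sc <- render_scene(scene_spec(), seed = 42)   # 13 pairs = 26 kinetochores
cs <- quantify_cell(sc$stack)
cs$n_kinetochores
#> [1] 20
round(cs$mean_ratio, 3)
#>          dna    measure_1    measure_2 reference_kt
#>        0.043        0.999        0.176        1.000
```

Exactly 20 kinetochores are measured; the recruitment ratio of
`measure_1` recovers its true value of 1 to 0.1%, while the DNA and band
channels show only residual spot-localised signal — the ratios mean
"fraction of the reference marker's corrected spot intensity".

Recover a known 1.37 µm metaphase-like pair separation from 50 noisy
STED-like images (30 nm pixels, 60 nm PSF sigma, peak SNR 10):

```r
ds <- make_distance_dataset(1.37, n_pairs = 50, seed = 1)
m  <- measure_distance_dataset(ds)
round(c(mean = mean(m$measured_um), sd = sd(m$measured_um)), 3)
#>  mean    sd
#> 1.370 0.005
```

## Command line

A thin dispatcher over the same functions lives at
`inst/cli/kinetoquant.R`:

```sh
Rscript inst/cli/kinetoquant.R synth-distances --sep-um 1.37 --n 50 --seed 1 --out out/
Rscript inst/cli/kinetoquant.R spots   --config cfg.yaml --images dir/ --out spots.csv
Rscript inst/cli/kinetoquant.R regions --config cfg.yaml --images dir/ --out regions.csv
Rscript inst/cli/kinetoquant.R stats   --in table.csv --test kruskal-dunn \
    --comparisons "ctrl:icp,ctrl:bor" --out stats.csv
```

The YAML config declares `channel_roles` (role → channel index),
`pixel_size_um`, the TIFF page layout, and optional parameter overrides.

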