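---
title: "Methods: quantifying kinetochore and pericentromere signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying kinetochore and pericentromere signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinetoquant)
```

# Scope and model

kinetoquant quantifies three kinds of signal in mitotic fluorescence
microscopy of human cells:

1. **Kinetochore spot recruitment** — how much of a measured protein (an
   outer-kinetochore kinase such as MPS1, or a checkpoint protein) sits at
   each kinetochore, expressed relative to a reference kinetochore marker
   (CENP-C or NDC80) measured at the same spot.
2. **Region-level chromatin/pericentromere signal** — mean
   chromatin-associated intensity of CPC subunits (Aurora B, INCENP,
   survivin, borealin) or of the Aurora B substrate mark H3pS10, corrected
   and normalised per cell.
3. **Distances** — inter-kinetochore (sister-to-sister, a proxy for
   biorientation tension) and intra-kinetochore (between two markers of one
   kinetochore) distances from line profiles, localised to sub-pixel
   precision with Gaussian peak fits.

All quantification operates on sum projections of the z-stack (typically a
2 µm stack at 0.2 µm steps, 11 slices), so the full axial extent of each
structure contributes; maximum projections are for display only.
Coordinates are `(y, x)` with 1-based pixel centres at integer positions,
and every distance is centre-to-centre; physical distances are pixel
distances multiplied by the image's µm-per-pixel scale.

# Spot pipeline

The reference channel is white top-hat filtered (image minus its grayscale
opening by a flat disc) to isolate structures smaller than the structuring
element, and thresholded with the iterative-intermeans (isodata) fixed
point — the threshold that sits halfway between the means of the two
classes it induces — to produce a binary kinetochore mask. The top-hat
subtracts any constant offset, so the mask is invariant to camera offset by
construction.

Spots are the brightest local maxima of the top-hat image, greedily
selected in descending intensity under a pairwise minimum-separation
constraint (default 8 px, the ROI diameter), so only non-overlapping
kinetochores are measured; by default 20 kinetochores are taken per cell.
Working on the top-hat image means a tilted background cannot create false
maxima; ties are broken in row-major order so the selection is
deterministic.

Each spot gets a circular ROI of diameter 8 px. Even diameters are centred
on the pixel corner nearest the maximum, and the ROI takes the lattice
pixels whose centres fall strictly inside the disc: with diameter 8 this
rasterisation yields **exactly 52 pixels**, which makes the spot ROI and
the 52-pixel background ROI the same size — the spot and background means
are taken over an equivalent number of pixels. The background ROI is
accrued radially: candidate pixels are visited in order of increasing
distance from the ROI centre, pixels inside the spot ROI or flagged in the
kinetochore mask are skipped, and accrual stops at 52 pixels. Distance ties
are broken in row-major order, so the accrued set is platform-independent
and equals a brute-force distance sort (this equivalence is tested
exhaustively on small images).

Per channel, `corrected = max(roi_mean − bg_mean, 0)` (negative values are
set to zero) and the recruitment readout is
`corrected(channel) / corrected(reference)` per kinetochore, averaged per
cell. The ratio is undefined when the corrected reference signal is zero;
such measurements are flagged invalid, excluded from the per-cell mean, and
counted, rather than silently dropped — the division contract is explicit.
Because the background is local, adding a constant to every channel leaves
corrected values unchanged, and scaling the measured channel by a factor
scales the per-cell ratio by exactly that factor on noiseless data; both
properties are tested.

Tunable parameters: ROI diameter (8 px), background size (52 px), spots
per cell (20), and the top-hat disc radius. The radius defaults to 5 px —
slightly larger than a diffraction-limited spot radius at ~0.1 µm pixels —
so spots pass the filter while extended structures are removed; it is a
configuration value because the right choice scales with pixel size.

# Region pipeline

Chromatin is segmented from the DNA (Hoechst) channel: Gaussian smoothing
(σ = 1 px, to suppress pixel noise before thresholding), isodata threshold,
largest connected component. The cytoplasm mask is the cell extent minus a
2-px dilation of the chromatin, making the two masks disjoint and keeping
chromatin edge signal out of the cytoplasmic background estimate. How the
cytoplasm region is defined is genuinely open in this kind of assay; the
default cell extent (crop bounds minus a 10-px border) is a reproducible
approximation, and a whole-cell mask can be supplied instead.

Channels are classed `corrected` (CPC/Aurora B: chromatin mean minus
cytoplasm mean, clamped at zero) or `uncorrected` (H3pS10: chromatin mean
as-is, since the mark is chromatin-intrinsic and a cytoplasmic subtraction
has no meaning for it). The class map is configuration, so either reading
can be run. All values are normalised by the mean DNA signal over the
chromatin mask, and per-cell values are finally scaled to the
control-condition mean, which then maps to exactly 1. Offsets cancel for
corrected-class channels and propagate for uncorrected ones — a documented
asymmetry that follows directly from the two definitions.

Pericentromeric CPC is measured over the whole chromatin mask rather than a
pericentric sub-mask; at widefield resolution the pericentric pool
dominates the chromatin-associated signal, and a sub-mask would require a
second marker the assay does not always include.

# Line profiles and distances

Profiles are sampled by bilinear interpolation at unit spacing along the
segment (`ceil(length) + 1` points, endpoints preserved), with every
channel sampled at identical coordinates so per-channel peak positions are
directly comparable; widths above 1 px average symmetric perpendicular
offsets. For display, groups of profiles are normalised per channel so the
group minimum is 0 and the peak of the group mean curve is 100, and
averaged after linear resampling to the median length. Resampling preserves
endpoints and registers midpoints; this assumes the profiles were drawn
between the same landmarks, which is how the lines are placed — profiles
drawn over different spans would need explicit registration, a recorded
limitation.

Peaks are localised by least-squares Gaussian fits
(`offset + A·exp(−(x−µ)²/2σ²)`, Levenberg–Marquardt, 200 iteration cap,
initialised from the sample extrema and second moment; a Nelder–Mead
fallback on the same objective handles the rare starts the LM step rejects,
and convergence is reported on the result). The intra-kinetochore distance
is the difference of two channels' fitted means along one profile. The
automated pair distance detects the two brightest maxima, fits each half of
the profile along the axis through them, then refines each centre with a
second, perpendicular 1D fit, giving full 2D sub-pixel centres; the
internal fitting profiles are sampled at 0.25 px steps because the
phase-dependent component of the bilinear interpolation error (up to
~0.01 px at 1 px sampling) averages out at finer steps. On noiseless
synthetic pairs the recovered separation is within 0.001 px of truth, and
the Gaussian estimator beats the integer-argmax distance in RMSE on noisy
pairs — the property that justifies fitting at all.

# Statistics

Distances are compared with the classical pooled-variance two-tailed
unpaired t-test (each kinetochore pair, or each kinetochore for
intra-kinetochore distances, is a replicate). Recruitment and region
measurements are aggregated to per-cell means first — the cell is the
biological replicate — then compared with a Kruskal–Wallis test (mid-ranks,
tie correction) and Dunn's z-tests on rank means for the planned
comparisons, Bonferroni-adjusted over the requested comparisons only.
Adjusting over planned comparisons rather than all pairs matches how such
experiments report adjusted p-values for the comparisons drawn on the
graphs; the Dunn variance uses the standard tie-corrected factor
`N(N+1)/12 − Σ(t³−t)/12(N−1)`. Significance labels: p > 0.05 `ns`,
p < 0.05 `*`, < 0.01 `**`, < 0.001 `***`, < 0.0001 `****`; boundary values
take the weaker label. Degenerate t-test inputs follow explicit
conventions (zero variance, equal means → p = 1; unequal means → p = 0,
flagged).

Hierarchical (mixed-effects) modelling of the kinetochore-within-cell
nesting is deliberately out of scope: the per-cell aggregation already
makes replicates exchangeable at the tested level.

# Synthetic scenes and what they do (and do not) show

The generator renders, per channel, an expected-photon field — uniform
cytoplasm, an elliptical chromatin region, isotropic Gaussian spots
(σ = PSF sigma) at controlled pair separations, an optional inner marker
offset inward along the pair axis, and an anisotropic Gaussian pericentric
band centred between pair members — then applies Poisson shot noise,
additive zero-mean read noise, and a constant camera offset. Amplitudes
are in expected photons so that "SNR 10" is well defined: peak amplitude
over the noise SD at the peak, `A/√(A + background + read_sd²)`, inverted
in closed form by `amplitude_for_snr()`. Out-of-focus slices broaden the
PSF as `σ(z) = σ₀√(1 + (z/z_R)²)` with the 2D integral conserved — a
simple documented stand-in, not an optics simulation.

Default study conditions: 250-px cells, 0.1075 µm pixels (a 6.45 µm camera
pixel behind a 60× objective), 11 slices at 0.2 µm, PSF σ 0.1 µm, 13
kinetochore pairs at 1.0 µm separation, spot SNR 10, read noise SD 2,
offset 100. STED-like distance scenes use 0.03 µm pixels and PSF σ
0.06 µm, one pair per image at a fixed true separation with uniform random
orientation and 1-px Gaussian midpoint jitter; separations are *not*
jittered, so recovery targets are crisp. Condition datasets multiply the
spot/band amplitudes of the measured channels by a per-condition factor
(e.g. 0.2 for a strong depletion) and render 20 cells per condition, the
sample size at which the end-to-end tests recover the factors within 10%
and detect the depletion by Kruskal–Wallis/Dunn.

Ground truth records every spot centre, pair separation, condition factor
and the true chromatin/cytoplasm masks, so each pipeline stage can be
checked against what was rendered. With a fixed seed the output is
byte-identical between runs.

What the synthetic scenes do **not** emulate: chromosome texture,
photobleaching, stage drift, spectral bleed-through, clustered or touching
kinetochores, and mitotic-stage heterogeneity. Passing tests therefore
demonstrate that the estimators are correct and well calibrated under the
assumed image-formation model — not that segmentation or spot detection is
robust to every artefact of real data. Cell crops are inputs: cell
segmentation and mitotic staging are out of scope.

# Numerical choices

* Morphology is computed with explicit border semantics (min/max over the
  in-image part of the disc), which keeps the opening ≤ the input and the
  top-hat ≥ 0 everywhere including borders, and makes the implementation
  exactly reproducible by a brute-force oracle.
* Isodata convergence: 0.5 intensity units for integer images, 10⁻⁶ of the
  intensity range for float images.
* All tie-breaks (maxima ordering, background accrual) are row-major and
  documented, so results are platform-independent.
* Problem sizes in the test-suite recovery studies — 50 pairs per
  separation, 20 cells per condition, 200 Monte-Carlo fit replicates,
  10,000 null simulations for the t-test calibration — were chosen as the
  smallest sizes at which the checked quantities are stable to well within
  their tolerances.

# Known limitations

Spot quantification is 2D (on projections); volumetric quantification and
spot tracking are out of scope. The automated maxima picker takes the
brightest 20 kinetochores, which need not match a human's choice of
"non-overlapping kinetochores" when dim or clustered spots are present.
Background candidates are enumerated per spot, so two background ROIs may
share pixels. Profile group averaging assumes landmark-registered lines.
The slice-selection step that sometimes precedes STED line profiling is
subjective; the projection choice is an explicit input here.
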