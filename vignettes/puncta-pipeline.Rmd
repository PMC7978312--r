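---
title: "Detecting and quantifying presynaptic puncta in two-channel micrographs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and quantifying presynaptic puncta in two-channel micrographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synpuncta)
```

## The problem

In cultured cortical neurons, presynaptic terminals appear as bright,
spot-like *puncta* when stained for the synaptic-vesicle protein
synaptophysin. A second channel images SNAP29, a SNARE protein whose
abundance at presynaptic sites drops after ischemia-reperfusion or shRNA
knockdown. The analysis question is quantitative: given a two-channel
micrograph and a manual trace of the neuronal processes, find the
presynaptic sites, measure SNAP29 at each site, and decide whether two
experimental conditions differ in their per-punctum SNAP29 intensity
distributions.

`synpuncta` implements that pipeline end to end, plus a ground-truthed
synthetic image generator so that every stage can be verified without
access to raw micrographs.

## The detection model

Detection runs on the marker (synaptophysin) channel only; the signal
(SNAP29) channel is measured afterwards at the detected sites.

1. **Normalization.** The image is linearly rescaled so its minimum maps
   to 0 and its maximum to 255. A constant image maps to all zeros: it
   carries no detectable structure, and this convention avoids a division
   by zero.
2. **Global threshold.** Foreground is every pixel strictly above a
   global threshold. In `auto` mode the threshold maximizes the
   inter-class variance of the 256-bin histogram (Otsu's criterion, ties
   broken toward the lowest candidate); a `fixed` value on the 0–255
   scale may be supplied instead and is recorded in the run log either
   way. Strict inequality makes an all-background image produce an empty
   mask at any threshold ≥ 0.
3. **8-connected labeling.** Two foreground pixels belong to the same
   object if they adjoin horizontally, vertically, or diagonally.
   Components are numbered by the raster-scan order of their first pixel,
   so labels are deterministic.
4. **Filters.** A component is kept iff its area lies in
   [`min_area`, `max_area`] (defaults 0.35 and 10 µm²; area =
   pixel count × `pixel_size`²) **and** its distance to the traced
   processes is at most `max_distance` (default 1 µm). All bounds are
   inclusive — the removal rules are phrased as "smaller than" /
   "larger than" / "farther than", so equality survives. Because areas
   are products of an integer pixel count and a squared calibration, a
   boundary case like 1000 px × (0.1 µm)² can land one float ulp above
   10 µm²; the comparisons therefore carry a 1e-9 *relative* guard so
   exact boundary components are never lost to round-off. Per-rule
   removal counts are reported in the detection log.

Component-to-process distance is, by default, the minimum Euclidean
distance from any pixel centre of the component to any point of any
trace polyline ("site within 1 µm" read as site proximity); a
`centroid` mode is available. The coordinate convention is fixed
package-wide: pixel `[r, c]` (1-based) has its centre at
`((c − 0.5)·pixel_size, (r − 0.5)·pixel_size)` µm, x along columns, y
increasing down rows.

Kept components are measured on the **raw** channels: `mean_marker` and
`mean_signal` are mean raw intensities over the component's pixels. The
0–255 normalization exists for thresholding only; applying a per-image
min–max rescale to the signal channel would cancel exactly the
multiplicative condition effect the downstream distribution comparison
is meant to detect.

## Quantification

* **Density**: kept puncta per micron of traced process, overall and per
  process.
* **Colocalization** (for two independently detected channels): a signal
  punctum colocalizes iff its pixel set overlaps a marker punctum by at
  least one pixel — the weakest criterion consistent with
  "colocalizing", stated explicitly so stricter fractional-overlap rules
  can be layered on. Each signal punctum matches at most one marker
  punctum (largest overlap, ties to the lowest label).
* **Marker-normalized ratio**: `mean_signal / mean_marker` per punctum.
  Puncta with non-positive marker intensity are flagged and excluded
  (impossible for marker-detected components, possible for external
  tables).
* **Accumulation index**: the cited index has no published formula, so
  the package adopts the bounded enrichment ratio
  `AI = I / (I + B)`, where `I` is the mean signal intensity over a
  punctum's arc-length span and `B` the mean over the shaft
  (non-punctum) positions of the same process. It is dimensionless,
  bounded in [0, 1], invariant to rescaling the whole profile, monotone
  in enrichment, and equals 0.5 on a uniform profile — adequate for the
  relative comparisons the index serves. Absolute values are **not**
  comparable to other accumulation-index definitions; the formula is
  recorded in the run log. Profiles are sampled every
  `pixel_size / 2` (below-Nyquist for the pixel grid) with bilinear
  interpolation; a position belongs to a punctum when its containing
  pixel does.

## Distribution comparison

Per-punctum SNAP29 intensities are pooled per condition (per-image means
are a pooling option) and compared pairwise with the two-sample
Kolmogorov–Smirnov test: `D = sup |F1 − F2|` over the pooled sample
points, p-value from the asymptotic Kolmogorov distribution
`Q(λ) = 2 Σ (−1)^{k−1} e^{−2k²λ²}` at
`λ = D(√n_e + 0.12 + 0.11/√n_e)`, `n_e = n1·n2/(n1+n2)`. At the
hundreds-of-puncta sample sizes this analysis produces, the asymptotic
form is accurate; an exact-distribution option is provided for
`n1·n2 ≤ 10⁴`. The test is two-sided, α defaults to 0.05, and the
pairwise matrix is reported without multiplicity correction (matching
the form in which such comparisons are conventionally tabulated); both
choices are recorded in the output metadata.

One practical note on `auto` thresholding: when two intensity modes are
far apart and heavily unbalanced, the inter-class-variance curve is
nearly flat across the whole inter-mode valley, so two correct Otsu
implementations can return thresholds tens of grey levels apart with
criterion values differing in the fourth digit. The package therefore
reports the chosen threshold in the log, and the synthetic study below
uses a fixed threshold for exact reproducibility.

## What the simulator emulates — and what it does not

`simulation_config()` + `make_process_traces()` + `render_image_pair()`
produce two-channel images with known ground truth:

* **Processes** are direction-correlated random walks (correlation
  length `process_smoothness`, default 5 µm) kept inside the image.
* **Puncta** are isotropic Gaussian spots centred on points drawn along
  the processes as a homogeneous Poisson process on arc length (default
  0.4 /µm — the sparse-to-moderate range of synaptophysin puncta along
  neurites). Each spot appears in both channels with independent
  log-normal amplitudes; `condition_factor` scales the signal-channel
  amplitude only, and the RNG stream is arranged so the marker channel
  is bit-identical across factors.
* **Spot width**: `psf_sigma` (default 0.3 µm) is an *effective* width —
  the optical PSF convolved with the physical extent of a synaptic
  bouton — chosen so detected component areas fall inside the
  0.35–10 µm² analysis window at the default 0.1 µm/px calibration (a
  bare confocal PSF of ~0.15 µm would yield component areas *below*
  0.35 µm² and no detectable puncta at all, which is why detected puncta
  must be object-plus-PSF sized).
* **Amplitudes** are log-normal truncated at ±2 log-sd. Truncation keeps
  the dimmest puncta above any sensible global threshold — labeling so
  weak that it falls below the background separation would not be scored
  by a human annotator either — and bounds the bright tail.
* **Distractors** (off-process spots) are rejection-sampled with centres
  farther than 2 µm from every process. The margin is deliberately
  larger than the 1 µm distance cutoff: with min-pixel distances, a spot
  of radius ~0.7 µm centred at 1.5 µm would still have foreground pixels
  within 1 µm, and the distractors' purpose is to give the distance
  filter a removable target.
* **Speckles** use a narrow width (0.09 µm) so their detected areas stay
  below 0.35 µm², exercising the small-area filter.
* **Noise** is additive Gaussian (default sd 7.5 au ≈ 5% of the median
  punctum amplitude), clipped at 0.

Not modeled: 3-D structure, photobleaching, chromatic shift, shot/camera
noise, spatially varying background, and biological punctum substructure.
Passing tests on this simulator therefore demonstrate that the *pipeline*
is correct and well calibrated under its stated assumptions — not that
those assumptions exhaust real micrographs.

Because placement is Poisson, nearby puncta can blur into a single
connected component, and the pipeline (like the published analysis)
performs no watershed splitting. Detection fidelity is therefore scored
by **centre coverage**: a true punctum is recalled iff the pixel
containing its centre belongs to a kept component, and a detection is a
true positive iff it covers at least one true centre; many-to-one
matches are allowed. On well-separated fixtures this coincides with 1:1
nearest-centroid matching. It also means the detected *component*
density runs slightly below the placement rate (approximately
`λ·e^{−λδ}` for merge distance δ), which is a property of
connected-component counting, not a detector defect.

## Study conditions and problem sizes

The packaged synthetic study (analysis scripts, tests, and the
acceptance script) uses the generator defaults above with 512×512 images
at 0.1 µm/px, three processes per image, and four conditions — two
controls at `condition_factor = 1.0` and two reduced conditions at 0.6
(the factor is not published; 0.6 is a mid-range knockdown adopted once
for both ischemia-like and shRNA-like conditions). Detection in the
study uses a fixed threshold of 25 — about 2 sd of the default
background noise after normalization — so every run is exactly
reproducible. Simulation sizes (5 noiseless + 20 noisy seeds for
fidelity, 9 images per arm for factor recovery, 500 null replicates at
n = 500/arm for type-I calibration, 100 replicates at n = 300/arm for
power) were chosen as the smallest designs whose Monte-Carlo error is
well inside the property bands being checked.

## Worked example

```{r example, eval = FALSE}
cfg_ctrl <- simulation_config(seed = 1L)                       # control
cfg_kd <- simulation_config(seed = 101L, condition_factor = 0.6)

params <- detection_params(threshold_mode = "fixed", fixed_threshold = 25)
run <- function(cfg) {
  tr <- make_process_traces(cfg)
  im <- render_image_pair(tr, cfg)
  detect_puncta(im$marker, im$signal, tr, params)
}
tab_ctrl <- run(cfg_ctrl)
tab_kd <- run(cfg_kd)

signal_over_marker(tab_kd)$mean / signal_over_marker(tab_ctrl)$mean
ks_two_sample(tab_ctrl$mean_signal, tab_kd$mean_signal)
```

## Known limitations

* Touching puncta are counted once (no splitting), biasing density
  downward at high punctum rates.
* The accumulation index is one member of a family of enrichment
  measures; only relative comparisons within a fixed definition are
  meaningful.
* Mask-only traces (binary TIFF input) support distance filtering but
  not arc-length quantities (density per micron, profiles).
* The asymptotic K-S p-value is slightly conservative at small samples;
  use `method = "exact"` below `n1·n2 = 10⁴` if that matters.
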