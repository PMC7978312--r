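# synpuncta

Detection and quantification of presynaptic puncta in two-channel
fluorescence micrographs, with distribution-level comparison across
experimental conditions.

Cultured-neuron experiments commonly image a presynaptic marker
(synaptophysin) in one channel and a protein of interest (here SNAP29, a
SNARE protein depleted by ischemia-reperfusion or shRNA knockdown) in a
second channel, alongside a manual trace of the neuronal processes. This
package is for analysts who need to turn such image pairs into
per-punctum measurements and condition-level statistics, and for anyone
who wants to validate that style of analysis on simulated data with
known ground truth.

## Method

Detection runs on the normalized marker channel
(min → 0, max → 255):

1. binarize with a global threshold *t* (Otsu's inter-class-variance
   criterion, or a fixed value); foreground is intensity > *t*;
2. label 8-connected components (horizontal, vertical, or diagonal
   adjacency);
3. keep a component iff its area *A* satisfies
   0.35 µm² ≤ *A* ≤ 10 µm² **and** its minimum distance to a traced
   process is ≤ 1 µm (inclusive bounds; per-rule removal counts are
   logged).

Each kept punctum is measured on both raw channels; quantification
reports puncta per micron of process, pixel-overlap colocalization
between independently detected channels, the marker-normalized ratio
`mean_signal / mean_marker`, and a bounded accumulation index
`AI = I/(I + B)` (punctum vs. shaft mean intensity along the same
process; 0.5 for a uniform profile). Conditions are compared by the
two-sample Kolmogorov–Smirnov test,
`D = sup_x |F₁(x) − F₂(x)|`, with the asymptotic p-value
`Q(λ) = 2 Σₖ (−1)^(k−1) e^(−2k²λ²)` at
`λ = D(√nₑ + 0.12 + 0.11/√nₑ)`, `nₑ = n₁n₂/(n₁+n₂)`.

A synthetic-data module generates ground-truthed image pairs (smooth
simulated processes, Gaussian puncta placed along them as a Poisson
process, off-process distractors, sub-threshold speckle, additive
background noise, and a multiplicative condition factor on the signal
channel), so recall/precision, parameter recovery, and statistical
calibration are all testable. See `vignettes/puncta-pipeline.Rmd` for
the full model description and design rationale.

## Worked example

Simulate a control and a knockdown-like image (signal amplitudes scaled
by 0.6), detect puncta, and compare:

```r
library(synpuncta)

cfg_ctrl <- simulation_config(seed = 1L)
cfg_kd   <- simulation_config(seed = 101L, condition_factor = 0.6)

params <- detection_params(threshold_mode = "fixed", fixed_threshold = 25)
run <- function(cfg) {
  tr <- make_process_traces(cfg)
  im <- render_image_pair(tr, cfg)
  detect_puncta(im$marker, im$signal, tr, params)
}
tab_ctrl <- run(cfg_ctrl)   # 30 puncta
tab_kd   <- run(cfg_kd)     # 27 puncta

head(tab_ctrl[, c("area_um2", "distance_um", "mean_signal",
                  "signal_over_marker")], 3)
#>   area_um2  distance_um mean_signal signal_over_marker
#> 1     0.97 0.0005003961    49.17180          0.4394698
#> 2     4.37 0.0002590770    76.16999          0.6895980
#> 3     0.63 0.0002602455   118.37700          1.5244173

signal_over_marker(tab_kd)$mean / signal_over_marker(tab_ctrl)$mean
#> [1] 0.557234      # recovers the simulated 0.6x reduction

ks_two_sample(tab_ctrl$mean_signal, tab_kd$mean_signal)
#> Two-sample Kolmogorov-Smirnov: D = 0.7259, p = 1.869e-07
#>   (n1 = 30, n2 = 27)  [significant at 0.05]
```

The per-punctum areas sit inside the 0.35–10 µm² window, distances are
essentially zero (the simulator centres puncta on the traces), and the
knockdown separates decisively while the ratio of mean normalized
intensities recovers the simulated reduction.

## Analysis workflow

The `analysis/` scripts run the packaged four-condition synthetic study
(two controls, two reduced conditions at factor 0.6; three 512×512
images each) and write tables under `results/`:

```sh
Rscript analysis/01_simulate.R   # images + ground truth (scratch/)
Rscript analysis/02_detect.R     # puncta tables, recall/precision
Rscript analysis/03_quantify.R   # densities, ratios, accumulation index
Rscript analysis/04_stats.R      # ECDFs + pairwise K-S matrix
```

The final stage prints the pairwise comparison matrix; on the packaged
seeds, both same-level pairs fail to separate (e.g. WT vs. NC
p = 0.448) while all four control-vs-reduced pairs reject at
p < 1e-8 — the qualitative pattern expected when only the reduced
conditions share a lowered SNAP29 distribution.

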