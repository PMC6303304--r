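---
title: "Micro-trench time-lapse analysis: models, parameters and design choices"
author: "trenchlapse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Micro-trench time-lapse analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trenchlapse)
```

## The problem

Micro-trench arrays confine single non-adherent cells (for instance
leukemia cell lines) and their progeny in rod-shaped hydrogel wells of
30 x 120 um, so that a slightly defocused phase-contrast movie shows each
cell as a bright, peaked blob that can be detected and tracked
trench-by-trench. Together with a fluorescent death marker imaged at a
coarser cadence, this yields per-cell division times, cell-cycle
durations, sister-cell correlations and — after adding a chemotherapeutic
drug — the time-to-death (TTD) of each cell as a function of its
cell-cycle position at drug addition, and dose-response curves.

`trenchlapse` implements the entire chain as testable components: a
ground-truth simulator and movie renderer, the image-processing and
LAP-tracking layers, event extraction, and the statistics layer. Because
every stage can be run against synthetic ground truth, each guarantee of
the pipeline (detection precision/recall, division-time accuracy, TTD
accuracy, parameter recovery) is checked quantitatively in the test
suite.

## The simulator

### Lineages

Each trench starts with one cell. Cycle durations are log-normal,
parameterized by their arithmetic mean and SD (defaults 19.7 h and
2.6 h). Unsynchronized starting cells begin at a uniformly random point
of their cycle; synchronized ones at the G1/S boundary (cycle fraction
`g1_end`, default 0.4) advanced by `release_offset` = 3 h, emulating
release from a double-thymidine block 3 h before imaging starts.

Sister dependence supports two parameterizations, selected by the
configuration:

* **Gaussian copula** on log-durations with correlation `sister_rho`
  (default 0.85). The Pearson correlation of the durations themselves is
  slightly attenuated relative to the copula parameter (for CV = 0.13 the
  attenuation is below 0.003), which is why recovery tests compare
  against the configured value with a tolerance rather than exactly.
* **Shared draw plus exponential difference** (`sister_diff_mean`): both
  sisters share one log-normal draw and an exponential absolute
  difference (mean 2.3 h by default calibration) is split between them
  with a random sign. The two parameterizations express the two published
  summaries of sister similarity — a pair correlation and an exponential
  difference distribution — which are not jointly consistent with a
  single bivariate Gaussian; each analysis uses the matching one.

### Drug-induced death

Every cell present at or after `drug_add_time` (default 20 h) is selected
to die with Hill probability
`p(c) = floor + (ceiling - floor) c^h / (IC50^h + c^h)`.

* **Vincristine** (M-phase blocker): death occurs at the cell's next
  M-phase entry — its scheduled division time — plus a log-normal
  apoptosis delay (default mean 6 h, SD 2 h). Cells reaching M but not
  selected to die divide normally. A parallel phase-independent
  exponential hazard with rate
  `phase_independent_death_rate * max(0, c/IC50 - 1)` models the loss of
  phase specificity at very high dose; the earlier channel wins. This
  reproduces the mechanism signatures: progression-TTD correlation is
  strongly negative at intermediate dose and washes out at 1000 nM.
* **Daunorubicin** (topoisomerase-II inhibitor): death at drug addition
  plus the log-normal delay, independent of phase; progression and TTD
  are uncorrelated.
* **Control**: each at-risk cell dies with the background probability
  `death_floor` at a uniform time.

Sister cells draw their delay and hazard quantiles from a Gaussian
copula. `death_sister_rho` is the Pearson correlation of the delay draws
themselves: a Gaussian copula attenuates the correlation of skewed
margins (for exponential margins, by about 9% at 0.54), so the copula
parameter is obtained by inverting the margin attenuation with
Gauss-Hermite quadrature and bisection. A dying cell never divides; its
scheduled division and descendants are removed. When a daunorubicin- or
background-death draw falls after the scheduled division we let death
override the division rather than modelling marker hand-off to daughters;
this is a deliberate simplification of an undefined corner case.

A note on recovering `death_sister_rho` from sister TTDs: in an
unsynchronized population killed through the mitotic channel, sister TTDs
share the trench's first-division time, whose variance (~33 h² when
divisions spread over 20 h) dwarfs both the cycle-duration variance
(~6.8 h²) and any delay variance. Sister TTD correlation is then ~0.9
regardless of the delay copula. The calibration scenario for the TTD
correlation therefore uses 1000 nM vincristine, where the
phase-independent hazard dominates and the measured sister correlation
tracks the configured delay correlation.

### Rendering

The movie geometry is fixed at 1 um/px. Trenches are drawn as static dark
rod outlines (2 px walls at intensity 120) on a uniform background (300);
live cells are isotropic Gaussian blobs (sigma = 5 px, amplitude 900)
with additive Gaussian pixel noise (default SD 40, i.e. blob SNR ~ 22).
The published trench-width-to-cell-diameter ratio of ~2 implies ~15 um
cells; cells therefore perform reflected Brownian motion (default step SD
3 um/frame) with a pairwise excluded-volume separation of 15 px enforced
by a few relaxation sweeps. This matters for division detection: freshly
divided daughters are placed 15 px apart and are resolvable by the
Laplacian-of-Gaussian detector from the first frame after division.
Fluorescence frames (every 30 min vs 10 min for phase) show a blob only
for cells at or past their death time, frozen at the death position —
the marker onset is instantaneous, because TTD is read from the first
frame of the fluorescent track.

What the simulator does *not* emulate: optics-accurate defocus PSFs,
photobleaching, intensity variation between cells, cell shape, debris,
focus drift, or trench-wall imperfections. Passing tests therefore
demonstrate the internal consistency of the chain under the stated image
model, not performance on real microscopy data; the published real-data
tracking yield (~50%) is far below the >90% achieved here on clean
synthetic movies.

## Image processing

The phase-contrast chain follows the order: Gaussian-blur background
correction, local contrast normalization, minimum-error thresholding,
temporal mean correction, then LoG detection.

* `background_correct()` subtracts a sigma = 50 px smoothed version of the
  frame. The smoothing uses three iterated box filters (summed-area
  tables), the standard O(1)-per-pixel approximation of a wide Gaussian.
* `local_contrast_normalize()` computes `(x - mean) / (sd + 1e-6)` over a
  64 px window.
* `minimum_error_threshold()` minimizes the two-Gaussian
  classification-error criterion over a 256-bin histogram, with class
  variances floored at 0.25 bin² to guard `log(0)` on spiky histograms.
  The criterion is constant across an empty gap between two separated
  modes, so tied minima resolve to the middle of the tied range; for two
  symmetric modes this is their midpoint. The resulting per-frame
  foreground mask gates which LoG maxima are accepted — the published
  pipeline does not state how mask and detector combine, and this is our
  resolution.
* `temporal_mean_correct()` subtracts the pixel-wise temporal mean
  (clamping at zero), suppressing the static trench walls at the cost of
  a 1/N amplitude bias on moving cells.
* `detect_log()` computes the scale-normalized LoG response at
  sigma = 5 px (the cell radius) and collects local maxima above the
  threshold with greedy non-maximum suppression at 8 px, ties broken by
  response then (y, x).

When no explicit response threshold is given, it is set per stack from
the minimum-error threshold of the pooled response histogram, floored at
median + 5 MAD-sigmas. Because any finite data-derived threshold admits
the global maximum of a signal-free stack, auto mode first requires at
least one response above median + 10 MAD-sigmas (a matched-filter
response to a real cell sits two orders of magnitude above the noise
floor; pure-noise maxima reach ~5); otherwise the stack is declared
signal-free and yields no detections.

The fluorescence chain applies one min-max brightness/contrast setting
for the whole movie (per-frame rescaling would amplify signal-free frames
to full range), then temporal mean correction and the same detector.

## Tracking

Detections are partitioned by trench (nearest label within 5 px), and
each trench is tracked independently: frame-to-frame linear assignment
with squared-distance costs (forbidden above `max_link_distance` = 20 px)
and a birth/death alternative cost of 1.05 x the 90th percentile of
admissible costs; a gap-closing pass over (track end, track start) pairs
within `gap_max` frames; then division detection, which attaches a
remaining track start at frame f+1 to a track with points at f and f+1
within `split_radius` = 15 px, cutting the parent there so both
continuations become children. Division candidates are processed
chronologically (then by distance, then id): ordering purely by distance
would let a second-generation division consume the root's two child
slots before the first division is resolved, corrupting multi-generation
lineages. The assignment subproblem is solved exactly as a maximum-weight
perfect matching on the standard augmented square matrix; a brute-force
enumeration oracle verifies optimality on all instances with up to six
detections per frame in the test suite.

The per-trench accounting classifies each single starting cell as
divided, not-divided (tracked to the end, or terminated by an assigned
death) or lost, and the identity N0 = N_divided + N_not_divided +
N_losses is asserted rather than assumed. A root whose track ends early
with an assigned death counts as tracked, not lost.

## Events

Division times are read off the lineage tree as the first frame at which
both daughters exist; with daughters resolvable from the division frame
this is accurate to one frame (10 min). Deaths are matched per trench
from fluorescence-track onsets to the nearest phase track alive at (or
just before, within 6 phase frames of) the onset, one death per track;
TTD = onset time - drug addition time, with negative values flagged as
pre-drug and excluded from drug analyses (but still counted in
dose-response denominators). Cycle progression at drug addition divides
elapsed time since the last division by the *population mean* cycle
(19.7 h reference), clipped to [0, 1]; phase boundaries default to
G1 ending at 0.4 and S at 0.8 of the cycle, configurable because the
published per-phase durations are cited from external sources without
values. Sister pairs are formed per trench with the within-pair order
randomized under the analysis seed.

## Statistics

* Distribution fits: log-normal by closed-form log-moment MLE, gamma by
  numerical MLE (moment start), exponential by `rate = 1/mean`. At
  CV ~ 0.13 and n ~ 320, gamma and log-normal log-likelihoods agree
  within 1% — both describe such data equally well.
* `pearson_with_p()`: sample r, two-sided t-test p (n - 2 df), and a
  seeded 1000-replicate pair bootstrap SE. The bootstrap choice for the
  uncertainty is ours; the published +/-0.04-style uncertainties come
  with no stated method, and published p-values for r at the reported n
  are not reproduced by the standard t formula — we implement the
  standard formula and leave the discrepancy documented rather than
  reverse-engineering.
* `random_pairing_baseline()` pairs values across trenches uniformly at
  random; for exchangeable values the mean r is ~0. A positive baseline
  (as reported for real data) can only arise from unpaired structure
  combined with *local* pairing, so the op accepts a `neighborhood`
  (trench-rank window) argument; it is unrestricted by default and the
  drift mechanism is off by default in the simulator.
* `ttd_density()`: Gaussian KDE with Silverman bandwidth on a stated
  grid; the grid integral is checked to 1e-3.
* `fit_dose_response()`: per-dose Clopper-Pearson 95% intervals and a
  four-parameter logistic fitted by weighted least squares on fractions
  (weights n, zero dose anchoring the floor, fitted on log10
  concentration). The 4PL surface is shallow when no dose reaches
  saturation, so the fit is multi-start (a 4 x 3 grid over hill and
  log-IC50); bootstrap refits (seeded parametric bootstrap, 500
  replicates) start from the point estimate. Noiseless fractions are
  recovered exactly; note that with a top plateau far above the largest
  dose, even 1e-4 perturbations of the fractions legitimately move the
  IC50 by ~1%, which is a property of the design, not the optimizer.

## Problem sizes and numerical choices

The test suite and the acceptance script use 30-trench/24 h and
100-trench/40 h movies (about 0.6 Mpx per frame at 1 um/px, 241 phase
frames for the larger one), which keep a full pipeline run in the
minutes range on a single core while leaving hundreds of completed
divisions for the statistics. Event-level calibrations use 320-450
trenches. Intensities are processed as floating point regardless of
input bit depth; 16-bit input is binned to 256 histogram levels for
thresholding. All randomness derives from one seed fanned out into named
substreams (lineages, drug, render, pairing, bootstraps), so stages can
be rerun independently and full runs are bit-reproducible.

## Known limitations

* The image model is deliberately simple (see above); detection
  parameters are scaled to the simulated cell size and would need
  retuning for real movies.
* Point detections only: no segmentation, areas, or sub-pixel refinement.
* No fusion events and no recovery of cells that leave their trench.
* Censored cells (alive at movie end) are reported as counts, not
  modelled with survival methods.
* Phase is inferred from elapsed time only, not from molecular markers.
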