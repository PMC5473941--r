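---
title: "Quantifying dynein auto-inhibition: models, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dynein auto-inhibition: models, parameters, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phiquant)
```

Cytoplasmic dynein-1 spends much of its life auto-inhibited. The motor can
fold into the *phi particle*, in which its two motor domains dimerize with
each other, or sit in an *open* conformation in which the motor domains are
separated but still poorly processive; binding of dynactin and a cargo
adaptor such as BICD2N (forming the DDB complex) reorients the motors and
activates transport. phiquant implements the quantitative assays used to
characterise this equilibrium: single-molecule microtubule binding kinetics,
processivity and gliding motility, conformational-population statistics from
2D class averages, size-exclusion chromatography (SEC) complex quantification,
and ROI-based fluorescence quantification in cells. Every assay has a seeded
synthetic-data generator with the statistical structure the analysis assumes,
so the full pipeline is testable without any raw microscopy data.

## Single-molecule binding kinetics

### The model

Binding events of fluorescent dynein on surface-anchored microtubules are
scored from kymographs. Arrivals on a microtubule of length $L$ (µm) at motor
concentration $c$ (nM) over time $T$ (s) are Poisson with mean
$k_{on}^{site} \cdot \sigma \cdot L \cdot c \cdot T$, where $\sigma$ is the
lattice-site density. A 13-protofilament microtubule with an 8.1 nm axial
repeat presents $13 \times 1000/8.1 = 1604.9$ dimer sites per µm; with half
blocked by the immobilization surface, `lattice_sites()` gives the 802
sites/µm used throughout.

Dwell times follow a two-phase exponential mixture. The survival curve — the
percentage of molecules still attached $t$ seconds after binding, evaluated
on a grid with one bin per camera frame (0.125 s at 100 ms exposure + 25 ms
delay, 8 fps) — is fitted by least squares to

$$S(t) = 100\left[w\,e^{-t/\tau_f} + (1-w)\,e^{-t/\tau_s}\right],
\qquad 0 < w \le 1,\; 0 < \tau_f \le \tau_s,$$

with the *fast* phase defined as the smaller time constant. The off-rate is
the reciprocal of the fast time constant, $k_{off} = 1/\tau_f$, and the
microtubule affinity is the lattice-scaled ratio

$$K_d\,[\mathrm{nM}] = \frac{k_{off}}{k_{on}} \times 802 .$$

### Event scoring and the truncation problem

Events must span at least two frames (0.25 s) to be scored; shorter blips are
indistinguishable from noise in a kymograph. We read "greater than 2 frames
(0.25 s)" inclusively (duration ≥ 0.25 s); `filter_events(strict = TRUE)`
gives the exclusive reading. Right-censored events (still bound at the movie
end) are excluded from dwell analysis by default, since their duration is
unknown.

Thresholding truncates the dwell distribution from the left, and with a fast
phase of a few hundred milliseconds the truncation is severe: at
$w = 0.8,\ \tau_f = 0.3\ \mathrm{s},\ \tau_s = 3\ \mathrm{s}$ roughly 40% of
genuine events never reach two frames. Two corrections follow from the model
itself:

* **Fit truncation.** `fit_two_phase(curve, truncation_s = 0.25)` fits
  $S(t) = 100\,g(t)/g(t_0)$ over $t \ge t_0$, where
  $g(t) = w e^{-t/\tau_f} + (1-w)e^{-t/\tau_s}$. With this normalisation $w$
  estimates the weight of the *untruncated* mixture; the naive fit would
  instead estimate the (much smaller) weight among detected events.
* **Rate correction.** The observed binding rate counts only detected
  events. `kinetics_summary()` divides it by the fitted detection
  probability $g\!\left((m - \tfrac12)\,\Delta\right)$ with $m$ the minimum
  frame count and $\Delta$ the frame cycle — the half frame accounts for
  dwell quantization to the nearest whole frame, under which an event is
  kept exactly when its true dwell exceeds $(m-\tfrac12)\Delta$.

Both corrections are on by default in `kinetics_summary()` and switchable;
`binding_rate()` itself always reports the raw detected-event rate. On
synthetic data at the reference conditions the chain recovers $w$ within
±0.05, $\tau_f$ within ±10% and $K_d$ within a few percent; without the
corrections $K_d$ would be overestimated nearly two-fold.

The fit uses `minpack.lm::nlsLM` under box constraints with multi-start
initialisation: $\tau_f = 0.5\,\bar d$, $\tau_s = 2\,\bar d$, $w = 0.8$
(where $\bar d$ is the mean dwell estimated from the curve by trapezoidal
integration of $S/100$), plus four jittered restarts drawn with a fixed
internal seed; ties are broken by the lowest residual sum of squares. There
is no plateau term — unbinding is eventually certain, so the curve decays to
zero. Replicate experiments can either be fitted independently and their
fast time constants averaged (the default convention for $k_{off}$) or pooled
into one fit; both are available because averaging per-repeat fits weights
experiments equally while pooling weights events equally.

```{r kinetics-example, eval = FALSE}
assay <- simulate_binding_assay(
  kon_per_site = 1e-4, fast_fraction = 0.8, tau_fast_s = 0.3, tau_slow_s = 3,
  mt_lengths_um = rep(10, 50), duration_s = 100, conc_nM = 0.5, seed = 1
)
ks <- kinetics_summary(assay$events, assay$microtubules)
tidy(ks)
autoplot(ks$fit)
```

## Motility

A run is **processive** when it lasts longer than 0.625 s (five frames) and
shows unidirectional displacement greater than 500 nm. "Unidirectional" has
no standard numeric definition, so it is operationalized as: the direction
is that of the net displacement, and no excursion against it may exceed a
reversal tolerance of two pixels (0.32 µm at the 0.16 µm pixel). Both
thresholds are strict inequalities by default, matching "longer than" /
"greater than", and the comparators are configurable. Displacement is 1D,
along the microtubule-axis coordinate of the track.

Processive-event rates are normalized by microtubule length, observation
time, and motor amount (`n / (µm × s × pM)`); because published figure
legends sometimes omit the per-second term, the length-and-concentration
normalization is reported alongside rather than guessed between.

Gliding velocity is the mean of per-interval speeds for each microtubule's
leading-edge track, then the mean ± SEM over tracks. At a 3 s sampling
interval and 0.16 µm pixels, pixel quantization bounds the per-track error
by one pixel per interval (±0.053 µm/s).

## EM population statistics

Class proportions (phi / open / ambiguous) are estimated by micrograph
resampling: each round draws 25 micrographs uniformly *without replacement*
(drawn micrographs leave the pool, so no micrograph is ever reused), class
counts are summed over the round's micrographs, and the round's proportions
are class counts over the total — ambiguous particles stay in the
denominator. After 9 rounds the mean and SEM are taken *across rounds*
(n = 9), which is how the scheme was described; an SEM over micrographs
would be an equally defensible but different estimator. The plan is
infeasible for fewer than 225 micrographs and says so.

Inter-motor distances are binned at 2.5 nm with left-closed, right-open bins
anchored at 0 — the anchoring is a package choice, as no origin convention
accompanies the published histograms; a distance exactly on an edge goes to
the upper bin. Per-class particle counts are summed per bin and the total is
conserved exactly.

Orientation summaries (inverted / parallel / ambiguous stalk orientations)
pool particle counts over classes. `classify_pair_orientation()` provides a
geometric surrogate for the visual assignment: *inverted* when both stalk
vectors point at the opposite motor within an angular tolerance (default
20°), *parallel* when the two stalks are mutually aligned within it,
*ambiguous* otherwise. The inverted test runs first, since antiparallel
inward-pointing stalks would otherwise never be reached.

## SEC quantification

Chromatograms are normalized by subtracting the (linearly interpolated) A280
reading at 5 mL — a pre-void reference volume — making the result invariant
to constant offsets. The fraction of protein in the DDB complex is the
trapezoidal AUC of an explicit elution window divided by the AUC of the
whole trace. The integration windows are user inputs: the complex peak was
identified biochemically, which no trace-only analysis can reproduce, so
auto-detection is deliberately out of scope. Integration stays on the native
volume grid (window endpoints are interpolated); negative post-normalization
values are clipped to zero before integrating, because negative protein
amounts are unphysical — a no-clip mode exists, and clipping is reported.
Groups of per-replicate fractions are compared with an unpaired two-tailed
Student's t test (Welch form optional); identical zero-variance groups
return p = 1 with a warning rather than an error.

## Cell-imaging quantification

Fixed-cell intensities are measured on a SUM projection of the 11 z-slices
around the structure of interest, in 12×12-pixel ROIs. The ROI statistic is
the **mean** rather than the sum: background correction is only
dimensionally coherent when signal and background use the same per-pixel
statistic, and the choice is switchable. An even window cannot centre on a
pixel, so the named centre sits at 1-based index `size/2` of the window
(window start = centre − floor((size−1)/2)); odd windows are symmetric.
Two background conventions coexist deliberately, as both are standard:
centrosome signals subtract the *mean* of exactly three cytoplasmic ROIs,
spindle-pole signals divide by their *median*. Negative corrected values
pass through — clamping them would bias condition means upward.

Live-cell foci are quantified on per-timepoint MAX projections with 3×3
ROIs placed on the final frame and tracked backwards, moving each ROI to
the brightest pixel within a 1-pixel radius per step; when a focus's
background-subtracted value falls to zero or below it is deemed disappeared
and its ROI frozen in place for all earlier timepoints. The summary is the
mean ± SD across foci at each timepoint.

The comparison workflow mirrors common fixed-cell practice: per experiment,
Shapiro-Wilk normality per condition and Bartlett variance homogeneity
across conditions justify (or not) parametric analysis; a Kruskal-Wallis
omnibus test is followed by pairwise *paired* Wilcoxon tests, pairing by
within-experiment observation order (the pairing unit is the user's to
define; unequal lengths skip that comparison with a warning). The reported
p value per comparison is the **maximum** across the independent
experiments — the most conservative replicate.

## The synthetic-data generators

Each generator emulates exactly the statistical structure its analysis
assumes, with a ground-truth sidecar for parameter-recovery tests: Poisson
arrivals with mixture dwells quantized to the frame cycle (start snapped to
the next frame boundary, dwell rounded to the nearest whole frame, sub-frame
events dropped and counted, movie-end events flagged censored);
static/diffusive/processive tracks on a pixel grid; Poisson per-micrograph
particle counts with multinomial labels; uniform inter-motor distances over
the conformational state's range (10–45 nm open, 15–25 nm DDB) with
multinomial orientations (52/15/33% open, 4/47/49% DDB); Gaussian peaks on
a constant chromatogram baseline; and Gaussian foci on flat backgrounds
with optional Poisson or Gaussian noise. Defaults are the study conditions
(0.75/0.22/0.03 class probabilities, 8 fps, 0.16 µm pixels, 802 sites/µm);
noise defaults to zero so analytic oracles apply exactly.

What the generators do **not** emulate bounds what passing tests show:
kymograph scoring is error-free (no merging or crossing tracks, no missed
detections beyond the duration threshold), localization noise is Gaussian
and stationary, chromatogram peaks are perfectly Gaussian with a flat
baseline, and cell images have no illumination gradients, bleaching, or
focus drift. Recovery on synthetic data therefore validates the estimators,
not the upstream manual scoring.

## Determinism and problem sizes

A single pipeline seed fans out to per-stage seeds through a stable integer
hash of the stage name (`derive_seed()`), so any stage can be reproduced in
isolation and stage order is irrelevant. Fixed seeds give byte-identical
metrics, tables, and config snapshots; the run log's data checksums are
likewise identical, with only its wall-clock timestamps varying between
runs.

The test and demonstration scales — 50 microtubules × ~2000 events and 20
seeds for kinetics recovery, 300 micrographs × ~40 particles for the 25×9
resampling, 10,000 classes for orientation recovery, 0.02 mL chromatogram
grids — were chosen to sit near the corresponding experimental scales while
keeping every analytic recovery criterion well-powered.

## Known limitations

* Dwell fitting is least squares on the survival curve, not a censored
  maximum-likelihood fit; censored events are dropped rather than modelled.
* The processivity reversal tolerance, the orientation angular tolerance,
  and the live-cell disappearance rule are operationalizations of manual
  judgements; their defaults are sensible but not canonical.
* SEC windows are user inputs; overlapping species are integrated, not
  deconvolved.
* No spot detection, kymograph tracing, or image registration: tracks,
  events, class labels, and ROI centres are inputs.
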