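# phiquant

Quantification pipeline for studies of cytoplasmic dynein auto-inhibition.

Dynein-1 switches between an auto-inhibited **phi particle** — its two motor
domains dimerized with each other — and an **open** conformation, and is
activated for processive transport by dynactin and a cargo adaptor (the DDB
complex). Characterising that equilibrium takes a battery of quantitative
assays, and phiquant implements all of them as a tidyverse-style R package:

* **Single-molecule binding kinetics** — microtubule binding rates
  (events·µm⁻¹·nM⁻¹·s⁻¹), dwell-time survival curves at the camera frame
  resolution, two-phase exponential decay fits
  `S(t) = 100[w·e^(−t/τf) + (1−w)·e^(−t/τs)]`, and the lattice-scaled
  affinity `Kd = (koff / kon) × 802` using the 802 accessible dynein sites
  per µm of a 13-protofilament microtubule (8.1 nm repeat, half blocked by
  the surface).
* **Motility** — processivity classification (runs longer than 0.625 s with
  unidirectional displacement greater than 500 nm), normalized
  processive-event rates, and gliding velocimetry.
* **EM population statistics** — phi/open/ambiguous proportions with SEM by
  25-micrograph × 9-round resampling without replacement, 2.5 nm inter-motor
  distance histograms, and inverted/parallel/ambiguous stalk-orientation
  summaries.
* **SEC quantification** — baseline normalization at 5 mL, AUC fractions of
  explicit elution windows, and unpaired two-tailed t tests between
  conditions.
* **Cell-imaging quantification** — 11-slice SUM projections, 12×12-pixel
  ROIs with mean-of-3 (subtract) or median-of-3 (ratio) cytoplasmic
  background correction, live-cell 3×3 focus time courses with backward
  tracking, and the Shapiro-Wilk / Bartlett / Kruskal-Wallis / paired
  Wilcoxon workflow with max-p aggregation across experiments.
* **Synthetic data** — seeded generators for every input (binding events,
  tracks, particle tables, chromatograms, image stacks) with ground-truth
  sidecars, so the whole pipeline is testable without raw data.

Functions take data frames and return tibbles; fitted objects have
`tidy()` / `glance()` methods and `autoplot()` visualizations.

## Worked example

Simulate a binding assay at known kinetics (per-site on-rate 10⁻⁴
nM⁻¹s⁻¹ ⇒ true Kd = koff/kon = 33.3 µM; 80% fast phase with τf = 0.3 s,
τs = 3 s; 50 microtubules of 10 µm filmed 100 s at 0.5 nM and 8 fps), then
run the full analysis chain — 2-frame event filter, per-microtubule rates,
survival curve, truncation-corrected two-phase fit, detection-corrected
kon, and the lattice-scaled Kd:

```r
library(phiquant)

assay <- simulate_binding_assay(
  kon_per_site = 1e-4, fast_fraction = 0.8, tau_fast_s = 0.3, tau_slow_s = 3,
  mt_lengths_um = rep(10, 50), duration_s = 100, conc_nM = 0.5, seed = 1
)
assay
#> <binding_assay> 1713 events on 50 microtubules (286 sub-frame events dropped)

ks <- kinetics_summary(assay$events, assay$microtubules)
ks
#> <kinetics_summary> kon = 0.0819 +/- 0.0021 um^-1 nM^-1 s^-1, koff = 3.4 s^-1, Kd = 33.4 uM (1220 events, 50 MTs)

tidy(ks$fit)
#> # A tibble: 3 × 2
#>   term       estimate
#>   <chr>         <dbl>
#> 1 w_fast        0.837
#> 2 tau_fast_s    0.294
#> 3 tau_slow_s    3.16
```

The fitted fast-phase weight (0.837 vs the true 0.8) and time constant
(0.294 s vs 0.3 s) come from the survival-curve fit with left-truncation at
the 0.25 s scoring threshold; `koff = 1/τf = 3.4 s⁻¹`; and the recovered
Kd of 33.4 µM matches the generating 33.3 µM because the binding rate is
corrected for the ~40% of events too short to score
(`glance(ks)$detection_fraction` ≈ 0.60). `autoplot(ks$fit)` draws the
survival histogram with the fitted decay.

The same pattern runs the EM population estimator:

```r
pop <- simulate_particle_population(300, 40, seed = 1) # 75/22/3% truth
rs  <- class_proportions_resampled(pop, resampling_plan(25, 9, seed = 1))
tidy(rs)
#> # A tibble: 3 × 4
#>   label     mean_proportion     sem mean_particles_per_micrograph
#>   <chr>               <dbl>   <dbl>                         <dbl>
#> 1 phi                0.747  0.00344                         29.6
#> 2 open               0.223  0.00415                          8.83
#> 3 ambiguous          0.0307 0.00138                          1.22
```

— phi and open proportions recovered within an SEM or two of the
generating 0.75 / 0.22 / 0.03, from nine disjoint rounds of 25 micrographs.

`run_pipeline(seed = ..., out_dir = ...)` chains every stage on synthetic
data and writes a deterministic report bundle (metrics JSON, per-stage CSV
tables, resolved config, checksummed run log).

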