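---
title: "Methods: tendon mechanical-augmentation analysis with tendonmech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tendon mechanical-augmentation analysis with tendonmech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`tendonmech` re-implements, as a tested pipeline, the computational analysis
of an ex vivo tendon mechanical-augmentation experiment: bovine superficial
digital flexor tendons, healthy or collagenase-degenerated, injected with the
collagen crosslinker genipin or a buffer control, tensile-tested to failure,
and assayed optically for crosslink distribution. This vignette documents the
models, the tunable parameters, the numerical choices, and what the
synthetic-data generator does and does not emulate.

## The measurement model

Each specimen undergoes a fixed machine schedule (`loading_protocol()`):

* preload at 0.1 MPa held for 60 s,
* 500 strain cycles, 0 to 5%, at ~1 Hz,
* ramp to failure at 15% strain/s,

sampled at 100 Hz over a 45 mm clamp-to-clamp gauge length. From the raw
force–displacement–time trace the pipeline extracts seven properties:

* **ultimate force / stress / strain** at the global force maximum (ties:
  earliest index). Stress divides by the specimen cross-sectional area (CSA);
  strain divides displacement by the gauge length.
* **stiffness**: the maximum slope over all sliding-window OLS fits
  `force = a + b * displacement`; the **elastic modulus** rescales it by
  gauge length / CSA.
* **work to failure**: trapezoidal integral of force over displacement up to
  the ultimate point (N·mm = mJ).
* **relative stress relaxation**: `(Fpeak_last − Fpeak_first)/Fpeak_first`
  over the cyclic block, negative when peak force relaxes.

### Analysis range for stiffness and work

The verbal definition "from the end of preload up to maximum load" would
sweep the regressions and the integral across the 500-cycle block, where
both are physically meaningless (the displacement retraces itself 500
times). The default is therefore `range_mode = "ramp_only"` — from the first
ramp sample to the ultimate index — with `"from_preload_end"` available as a
switch for strict literalism. Displacement is integrated as recorded, with
no re-zeroing at ramp start.

### Window choice

No window width is prescribed for the sliding regression; the default is
`max(5 samples, 10%` of the analysis range`)`, configurable via `window`.
For an exactly linear ramp the estimate is window-invariant (a property the
tests assert); for curved ramps a wider window biases the slope low and a
narrower one amplifies noise. The implementation uses centered cumulative
sums (O(n)); the test suite holds it equal, to 1e-8 relative, to an
exhaustive oracle that fits every window independently.

### Cycle peaks

Cycle boundaries are successive displacement minima inside the cyclic block,
found by refining the protocol's cycle grid to local minima (displacement is
the commanded machine position and carries no noise, so no smoothing is
needed; smoothing is deliberately not applied). The "last tested cycle" is
the last complete detected cycle.

## Group statistics

Because normality is not guaranteed for the mechanical variables (a
Shapiro–Wilk gate, `normality_test()`, is computed per group), group
comparison uses the Kruskal–Wallis omnibus (`kruskal_wallis()`, mid-ranks
with tie correction, chi-square reference) followed by Dunn's pairwise
z-tests (`dunn_pairwise()`) with pooled ranking over the whole family.
No multiplicity adjustment is applied by default — matching the unadjusted
pairwise style of the reported p-values — with Holm available
(`adjustment = "holm"`). Which pairs form the adjustment family is
configurable because the original family is not knowable; the pipeline uses
the four reported pairings. Treatment effects are reported as percent
differences of group medians with a signed denominator
(`median_percent_difference()`), rounded to integer percent in printed
summaries. `required_sample_size()` reproduces the a-priori two-sample
t-test power computation; it takes the coefficient of variation explicitly
since the variability input behind the published 23/43 figures came from an
unpublished preliminary experiment.

## Spatial model of crosslink signal

Fluorescence (590/645 nm) and absorption (590 nm), dry-weight-normalized,
are analyzed with two OLS designs:

1. **Injection site** (`fit_injection_site_model()`): cell-means coding,
   one dummy per group and no intercept, so coefficients are the group means
   and contrasts come from the coefficient covariance. Plain OLS standard
   errors are used throughout; nothing in the source analysis indicates
   robust errors.
2. **Distance profile** (`fit_spatial_model()`): treated groups only, with
   the injection site as baseline and group-by-distance interaction dummies.
   The printed model uses distances {9, 15} mm, yet 3 mm contrasts are also
   reported in the text; the default design is therefore {3, 9, 15} mm with
   the strict {9, 15} set available via `distances`. Percent drops divide
   each interaction coefficient by the group's own injection-site mean.
   Empty non-baseline cells yield `NA` coefficients, never extrapolation.

Paired ±d biopsies enter as independent replicates at |d|: the biopsy layout
shows sites on both sides of the injection but results are reported by
distance only, and whether paired sites were averaged first is unknown;
independent replicates is the convention adopted (and the generator draws
them independently).

## Calibration and concentration estimation

The incubation experiment (8 levels, 0–40 mM; 10 samples per positive level,
5 controls; 75 total) is fit by OLS of fluorescence on `ln(C)` using the
positive-concentration rows (`fit_calibration()`); `ln 0` is undefined, so
zero-concentration controls are kept out of the regression and summarized as
the detection background. Sensitivity is reported per +1% concentration,
`beta1 * ln(1.01)` (`slope_per_percent()`). Inversion
(`estimate_concentration()`) maps fluorescence to `exp((F − beta0)/beta1)`;
readings at or below the background mean are flagged below-detection rather
than mapped to vanishing concentrations. Concentrations are estimated
per sample and then summarized (means with standard errors per group and
distance) — whether the original analysis averaged fluorescence first is
unstated; per-sample-then-summarize is the convention chosen. The 1:7
dilution of the digests is constant across samples and is absorbed into the
arbitrary fluorescence unit. Absorption-based estimation reuses the same
machinery but is exercised on synthetic data only, as no absorption
calibration data exist.

## The synthetic-data generator

The generator is the test surface: it emulates the study design with known
ground truth so every extractor has a recovery oracle.

**Constitutive law.** No constitutive model is given for the source data, so
the generator uses the simplest law that reproduces the headline property
set: an exponential toe blending into a linear region,
`F(x) = k (x − x_t (1 − e^{−x/x_t}))`, with brittle failure at a normally
drawn strain (truncated just above the cyclic amplitude so no specimen fails
during cycling). The rupture sample is recorded at the drawn failure strain
itself, so the configured ultimate force is realized at any sampling rate.
Cyclic viscoelasticity is modelled on peak forces only —
`peak(n) = p_∞ + (p_1 − p_∞) e^{−(n−1)/τ}` with
`p_∞ = relaxation_fraction · p_1` — because the relaxation metric uses only
first and last peaks; full hysteresis loops are not simulated. Additive
Gaussian force noise (default SD 2 N) is floored at zero force.

**Calibration of the defaults.** Degeneration and genipin effects are
multiplicative on the material parameters, with per-group defaults tied to
the published group medians: `linear_stiffness` is the published stiffness
median; the failure-strain mean is solved so the noise-free ultimate force
equals the published ultimate-force median; `relaxation_fraction` is one
plus the published relative stress relaxation; CSA means are the published
CSA medians. A bilinear brittle law cannot *also* match the published
strain-at-failure and work medians — real tendon curves soften before
ultimate, so work and failure strain are determined once ultimate force and
stiffness are fixed. Ultimate force (the headline outcome, and the
acceptance-bound ratio) takes priority; simulated strain-at-failure medians
are consequently lower (~0.10–0.12) and work medians smaller than the
published ones, with all between-group ratios of force, stiffness, modulus,
relaxation and CSA preserved. Spreads (failure strain SD 0.02, CSA SD
3 mm², noise 2 N) are chosen once as realistic for bovine SDFT explants and
give ultimate-force ranges comparable to the published ones.

**Spatial profiles.** Intensity decays as
`center · e^{−|d|/λ} + background + noise`; controls emit background only
(default 0). A single exponential is deliberately minimal: the published
drop pairs (−32%/−69% healthy, −11%/−44% degenerated at 9/15 mm) are convex
in distance and cannot be matched exactly by any concave `1 − e^{−d/λ}`
profile. The default decay lengths (14.5 mm healthy, 31.4 mm degenerated)
are the through-origin least-squares fits of `ln(relative intensity)` on
distance through those printed drops; recovery tests compare against the
generator's own configured truth. Center intensities are set so that,
through the default calibration curve, the injection-site concentrations
are 7.9 mM (healthy) and 2.3 mM (degenerated) — the published estimates.
Note these published figures are not mutually consistent with the published
+45% fluorescence contrast under the published calibration curve itself;
the concentrations were prioritized. Fluorescence noise SD defaults to
1.5 a.u./mg (4–7% CV at treated-group signal levels, a realistic
plate-reader spread).

**Calibration samples.** `F = β0 + β1 ln C + noise` with defaults
`β0 = 12`, `β1 = 0.12/ln(1.01) ≈ 12.06` (so the sensitivity is exactly the
published 0.12 a.u. per +1%), and noise SD 14 a.u., chosen so the design's
adjusted R² is ≈ 0.61, the published fit quality.

**What the generator does not emulate.** No fiber-level mechanics, no
hysteresis within cycles, no grip slippage or compliance, no collagenase or
genipin transport kinetics, no full absorption spectra (one 590 nm channel),
and no inter-operator or machine drift. Passing recovery tests therefore
demonstrates correctness of the *computational* pipeline under a plausible
data-generating law, not fidelity of that law to real tendon.

## Determinism and problem sizes

All generators take explicit seeds and never rely on ambient RNG state
(cohort draws derive per-specimen streams from one seed; the pipeline uses
`seed`, `seed + 1`, `seed + 2` for traces, spectra and calibration).
`run_pipeline()` generates and extracts one specimen at a time so large
cohorts do not hold 50 000-sample traces in memory, and its CSV outputs are
byte-identical across reruns of the same configuration.

The package's own Monte Carlo checks use: 500 specimens per group for the
cohort effect-size check, with the cyclic block sampled at 25 Hz (a protocol
setting; the loading schedule and material parameters are untouched, and
cycle-peak extraction is exact at any rate that samples the peak);
10 000 replicates for the rank-test null calibration; 1 000 replicates for
spatial-drop recovery and calibration slope bias. These sizes give
comfortably stable estimates for the tolerances asserted.

## Known limitations

* The bilinear brittle law under-reproduces work-to-failure and
  strain-at-failure levels (see above); comparisons of those two properties
  against published *levels* should use real traces.
* Dunn p-values use the normal approximation; exact permutation p-values
  are out of scope.
* The spatial model assumes homoskedastic errors across cells.
* Concentrations are point inversions of a noisy calibration line; their
  uncertainty is dominated by the calibration slope error (~9% SE under the
  default design), which the per-sample summaries do not propagate.
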