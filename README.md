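# tendonmech

Analysis pipeline for ex vivo tendon mechanical-augmentation experiments:
healthy and collagenase-degenerated bovine superficial digital flexor
tendons, injected with the collagen crosslinker genipin (GP) or a buffer
control, cyclically conditioned, ramp-loaded to failure, and assayed
optically for crosslink distribution. The package is aimed at tissue
biomechanics labs that need the full computational chain — from raw
tensile-test traces to publishable group tables — reproducible and testable
without access to the original machine exports.

## What it computes

**Mechanics.** From each force–displacement–time trace (0.1 MPa preload for
60 s; 500 cycles, 0–5% strain at 1 Hz; ramp at 15% strain/s; 100 Hz;
45 mm gauge): ultimate force *F\** and stress *F\*/A*, strain at failure
*x\*/L*, stiffness as the maximum sliding-window OLS slope
*max_w b̂(w)* of *F = a + b·x*, elastic modulus *k·L/A*, work to failure
*∫F dx* (trapezoid, mJ), and relative stress relaxation
*(F̂_last − F̂_first)/F̂_first* over the cyclic peaks.

**Statistics.** Shapiro–Wilk normality gate; Kruskal–Wallis omnibus with tie
correction; Dunn's pairwise z-tests on pooled mid-ranks
(optionally Holm-adjusted); median percent differences; a-priori two-sample
t-test sample sizes.

**Spatial distribution.** OLS group-dummy model at the injection site and a
baseline-coded interaction model over distance,
*Y = β0 + β1·D_ColGP + Σ_d [β_d,GP·D_d(1−D_ColGP) + β_d,ColGP·D_d·D_ColGP]*,
with percent drops *100·β_d,g / baseline_g*.

**Calibration.** OLS of fluorescence on ln(concentration), sensitivity per
+1% concentration (*β1·ln 1.01*), and inversion
*Ĉ = exp((F − β0)/β1)* with below-detection flagging.

A synthetic-data generator (toe-then-linear material law with brittle
failure, exponentially decaying cyclic peaks, exponential spatial decay,
log-linear calibration response) emulates the study design with known ground
truth; its defaults are calibrated to the published group medians, so every
stage has a parameter-recovery test.

## Worked example

```r
library(tendonmech)
proto <- loading_protocol(sampling_rate = 25)   # lighter sampling for a demo
cfg <- pipeline_config(seed = 1,
                       n_per_group = c(C = 25L, GP = 25L, Col = 45L, ColGP = 45L),
                       protocol = proto,
                       material = default_material_params(proto))
rep <- run_pipeline(cfg)
print(rep)
```

```
[tendonmech] simulate+extract: 140 specimens
[tendonmech] stats: 32 summary rows
[tendonmech] spatial: 252 biopsies, 16 coefficients
[tendonmech] calibrate: 75 calibration samples, slope/%=0.1037, adj R^2=0.581
Study report
  specimens: 140 (C=25, GP=25, Col=45, ColGP=45)
  ultimate force, degenerated: 555 -> 630 N (+14%, Dunn p = 0.0108)
  calibration: slope 0.104 a.u./+1%, adj R^2 = 0.58
  concentration summary rows: 8; spatial drops: 12
```

At study-size groups the treated degenerated tendons rupture at a ~14–19%
higher median force than their controls (the generator's configured effect
is +19%; a 140-specimen draw wobbles around it), the Dunn test flags the
degenerated contrast (p ≈ 0.01) but not the healthy one, and the simulated
calibration experiment recovers a sensitivity near the configured
0.12 a.u. per +1% concentration. Group-level tables:

```r
gs <- rep$group_summary
gs[gs$property == "ultimate_force_N" & gs$control %in% c("C", "Col"), ]
#  control treated median_control median_treated percent_difference p_dunn
#        C      GP            748            907               21.2 0.1064
#      Col   ColGP            555            630               13.6 0.0108

head(rep$concentration_summary)
#  group distance_mm mean_concentration_mM se_concentration_mM
#  ColGP           0                  2.34               0.105
#  ColGP           3                  1.90               0.068
#  ...
#     GP           0                  9.79               0.491
```

Estimated injection-site concentrations (here ≈ 9.8 mM healthy, 2.3 mM
degenerated at this seed) fall away with distance — the healthy profile
steeply, the degenerated one shallowly — mirroring the confinement contrast
the assay is designed to show. Single traces are handled the same way:

```r
sim <- generate_load_trace(default_material_params()$GP, loading_protocol(), seed = 42)
sp  <- specimen("T1", "GP", csa = sim$truth$csa)
extract_all(sim$trace, sp, loading_protocol())
```

CSV readers/writers (`read_trace_csv()`, `read_spectral_csv()`,
`read_calibration_csv()`, …) use a fixed dialect (comma separator, dot
decimal, header required) so pipeline outputs are byte-stable across reruns.
See the methods vignette (`vignettes/tendon-augmentation-pipeline.Rmd`) for
the models, defaults and design decisions.

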