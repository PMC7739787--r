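# skikin

Joint kinematics of alpine ski turns from wearable sensors.

`skikin` is an R package for analysing knee and hip angle recordings made
during real alpine ski runs with electrogoniometers and a trunk-mounted
tri-axial accelerometer (the typical wireless racing set-up, sampled at
148.15 Hz). It targets the question a strength-and-conditioning coach or
sports scientist actually asks of such data: *during a turn, how long does
the knee work eccentrically, concentrically, and quasi-isometrically, at
what angles and angular velocities, and how does that differ between the
inside leg (IL), the outside leg (OL) and the four disciplines (SL, GS, SG,
DH)?*

## What the pipeline does

1. **Filtering** — zero-phase 4th-order Butterworth low-pass at 1 Hz
   (`filter_spec()`, `apply_filter()`). Discipline natural frequencies are
   0.21–0.54 Hz; ski/slope vibration lives above 2 Hz. The single-pass
   transfer function is −3 dB at 1 Hz, ~94 % amplitude reduction at 2 Hz,
   and rolls off at −80 dB/decade; the forward–backward application doubles
   the attenuation and cancels all phase (no temporal distortion).
   `spectrum_report()` reproduces the FFT/amplitude-spectral-density
   inspection used to choose the cut-off.
2. **Turn segmentation** — the resultant acceleration
   AccR = √(x² + y² + z²) is low-pass filtered and its local minima mark the
   turn switches (the edge change unloads the skier);
   `detect_turn_switches()` applies prominence and separation rules,
   `segment_cycles()` cuts the run into IL/OL half-cycles,
   `trim_cycles()` discards the first/last cycle, course figures and
   missing-data cycles, and `time_normalize()` maps a half-cycle onto
   0–100 %.
3. **Contraction-mode analysis** — the angular velocity ω (central
   differences of the filtered angle) classifies every sample as eccentric
   (ω < −20 °/s, flexion under load), concentric (ω > +20 °/s) or
   quasi-isometric (|ω| ≤ 20 °/s, closed window); the legacy bipartition
   (max→min angle = eccentric, min→max = concentric) is computed alongside
   for comparison with the older literature. `summarize_cycle()` /
   `summarize_run()` produce per-cycle phase durations (ms and % cycle),
   angle extrema and mean/max velocity magnitudes per mode under both
   partitions.
4. **Density maps** — `density_grid()` builds the bivariate angle×velocity
   occurrence histograms ("at which knee angle does a given angular velocity
   mainly occur"), normalized to the per-(leg, discipline) maximum and
   rendered as blue→red panels.
5. **Statistics** — `fit_mixed()` fits
   `Y ~ Discipline + Leg + Discipline:Leg + (1 | skier-session)` by REML
   (lme4), with an automatic log transform for clearly non-normal responses;
   Type-III-style F tests and Tukey-adjusted pairwise contrasts of estimated
   marginal means use Satterthwaite degrees of freedom computed from the
   closed-form REML surface of the random-intercept model. Effect sizes are
   mixed-model Cohen's d = |Δ| / √(τ² + σ²), labelled
   small/medium/large at 0.20/0.50/0.80.
6. **Synthetic runs** — real recordings of elite athletes are not publicly
   deposited, so `simulate_run()` generates complete runs (knee, hip,
   tri-axial acceleration) with exported ground truth (switch times, leg
   labels, clean signals, per-sample phase labels) from per-discipline
   profiles calibrated to the published turn durations, angle extrema,
   natural frequencies and quasi-isometric fractions. Every downstream stage
   is tested against this ground truth.

## Worked example

```r
library(skikin)

## a simulated giant-slalom run: 20 half-cycles, everything seeded
sim <- simulate_run(default_profiles()$GS, n_turns = 20, seed = 7)
sim$run
#> <ski_run> GS | skier SIM | session SIM-GS-7 | 4714 samples @ 148.2 Hz

metrics <- summarize_run(sim$run)       # filter -> detect -> segment -> phases
knee <- subset(metrics, joint == "knee")
aggregate(cbind(tri_ecc_pct, tri_iso_pct, tri_con_pct, duration_ms) ~ leg,
          knee, function(x) round(mean(x), 1))
#>   leg tri_ecc_pct tri_iso_pct tri_con_pct duration_ms
#> 1  IL        44.5        11.2        44.3      1452.9
#> 2  OL        35.8        27.8        36.3      1469.8
```

The outside leg spends ~28 % of its half-cycle quasi-isometric (holding the
extended carving position) while the flexed inside leg works dynamically —
the signature GS asymmetry.

```r
## multi-session dataset through the full pipeline, then the mixed model
md  <- simulate_metrics_dataset(n_ids = 8, cycles_per_id = 8, seed = 42)
fit <- fit_mixed(md, "tri_iso_pct")     # log-transformed automatically
fit
#> <ski_mixed> tri_iso_pct (transform: log) | tau2 = 0.01638, sigma2 = 0.04411
#>            term     F ndf ddf         p
#>      discipline 20.83   3   4 6.649e-03
#>             leg 37.89   1 116 1.103e-08
#>  discipline:leg 27.79   3 116 1.288e-13

tukey_contrasts(fit, "leg", by = "discipline")[,
    c("family", "contrast", "estimate", "p_adj", "cohens_d", "effect")]
#>                family contrast estimate    p_adj cohens_d effect
#> 1 leg | discipline=SL  IL - OL   0.0799 2.84e-01    0.325  small
#> 2 leg | discipline=GS  IL - OL  -0.7521 9.33e-14    3.058  large
#> 3 leg | discipline=SG  IL - OL  -0.3046 7.63e-05    1.239  large
#> 4 leg | discipline=DH  IL - OL   0.0625 4.01e-01    0.254  small
```

The discipline × leg interaction is strong: GS and SG hold the outside leg
quasi-isometric far longer than the inside leg (large effects, log-scale
estimates), DH is symmetric, and SL shows a small reversal — the pattern the
mixed model is designed to expose. (Estimates are on the log scale here
because the automatic normality rule transformed the response.)

A command-line front end covers the same pipeline:

```sh
Rscript inst/cli/skikin simulate --discipline GS --turns 20 --seed 7 \
        --out run.csv --truth truth.json
Rscript inst/cli/skikin analyze --run run.csv --out metrics.csv
Rscript inst/cli/skikin density --run run.csv --out fig.png
Rscript inst/cli/skikin stats --metrics metrics.csv --response tri_iso_pct \
        --out model.json
```

## Documentation

The methods vignette (`vignettes/ski-joint-kinematics.Rmd`) describes the
model and its assumptions, the synthetic-data generator and its calibration,
the numerical choices (filtering, edge handling, degrees of freedom), and
what a green test does and does not establish.
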