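# emgkin

Analysis of synchronized multi-channel electromyography (EMG) and midline
pose recordings from undulatory swimmers (koi/carp-type carangiform fish),
built around one timing question: **does muscle activation precede body
motion, or follow it?**

In steady laminar flow, axial muscle drives the body wave, so EMG bursts
should lead the local bending they produce. Swimming among Kármán vortices
shed by an upstream cylinder, the body can also be bent *by the flow*, with
muscle responding afterwards through proprioceptive feedback. The package
measures this as a signed delay per event,

```
Δt = t(LD extremum) − t(EMG onset peak)        [ms]
```

where LD is a midline point's lateral displacement perpendicular to the flow
axis. Positive Δt: EMG leads (actuation). Negative Δt: kinematics lead
(flow-driven). The headline statistic of a trial is the percentage of
negative Δt.

## What the package does

* **Signal conditioning** — mean adjustment, zero-phase 50 Hz notch,
  zero-phase 20–450 Hz Butterworth bandpass, downsampling from 2.5 kHz to a
  1 kHz working rate; rectified moving-average activation envelopes; SNR and
  crosstalk quality metrics (`condition_emg()`, `emg_envelope()`,
  `qc_metrics()`).
* **Feature/segment input matrix** — 18 features (time, frequency and
  wavelet domain) plus a causal 20-sample signal window per channel: 38
  columns per channel, 456 for a full 12-channel recording
  (`build_input_matrix()`).
* **Kinematics** — DeepLabCut-dialect pose ingestion, likelihood filtering
  with modified-Akima gap filling, reduction of 12 midline landmarks to four
  signed joint angles, planar forward kinematics back to body pose, lateral
  displacement, tail-beat frequency/amplitude and the Strouhal number
  `St = f·A/U` (`clean_pose()`, `pose_to_joint_angles()`,
  `forward_kinematics()`, `kinematic_summary()`).
* **EMG→kinematics mapping** — dense, recurrent and convolutional
  regressors (own matrix-algebra engine, Adam + early stopping,
  deterministic under a seed), subject-wise splits, per-joint RMSE / pose
  RMSE / phase-difference evaluation, and a channel-count ablation study
  (`fit_emg_mapping()`, `evaluate_mapping()`, `channel_ablation()`).
* **Delay analysis** — prominence-based EMG onset peaks and LD extrema,
  matching by the piecewise nearest-before/after rule with an ε = 10 ms
  ambiguity band, and sign-fraction summaries with an optional
  location-scale F density fit (`detect_onset_peaks()`,
  `detect_ld_extrema()`, `match_delays()`, `summarize_delays()`).
* **Synthetic trials** — a travelling-wave body with side-alternating,
  amplitude-varying EMG bursts of known per-burst lead/lag, noise, mains and
  crosstalk; `laminar`, `cyl5` and `cyl7` condition presets
  (`generate_trial()`, `simulate_trial()`).
* **Pipeline and reporting** — manifest-driven end-to-end runs with
  per-stage error isolation, config hashing, condition comparison tables and
  ggplot2 `autoplot()` methods (`run_pipeline()`, `compare_conditions()`).

## Worked example

Two synthetic trials — laminar flow and the 5 cm-cylinder vortex preset —
through the full pipeline:

```r
library(emgkin)

dir <- tempfile("trials")
m1 <- simulate_trial("laminar", seed = 1, out_dir = dir)
#> laminar seed 1: 386 bursts, 0.0% lagging, tau = 50 ms
m2 <- simulate_trial("cyl5", seed = 2, out_dir = dir)
#> cyl5 seed 2: 504 bursts, 48.0% lagging, tau = 50 ms

report <- run_pipeline(dplyr::bind_rows(m1, m2))
report$trials[, c("trial_id", "f_hz", "amp_cm", "strouhal",
                  "n_delays", "percent_negative")]
#> # A tibble: 2 × 6
#>   trial_id       f_hz amp_cm strouhal n_delays percent_negative
#>   <chr>         <dbl>  <dbl>    <dbl>    <int>            <dbl>
#> 1 laminar_seed1  1.63   6.00    0.357      385              0
#> 2 cyl5_seed2     1.63   6.00    0.357      502             48.2

glance(report$summaries$laminar)
#> # A tibble: 1 × 4
#>       n percent_negative median_ms f_fit_ks
#>   <int>            <dbl>     <dbl>    <dbl>
#> 1   385                0      50.0   0.0444
```

Reading the numbers: the tail beats at 1.63 Hz with a 6 cm peak-to-peak
excursion (Strouhal 0.357 at 0.274 m/s). In the laminar trial every one of
the 385 matched events has positive Δt with median exactly the generator's
+50 ms muscle lead — muscle precedes motion. In the vortex preset, where the
generator flips the lead sign on 48% of bursts, the pipeline recovers 48.2%
negative delays. `compare_conditions(report)` tabulates the same contrast
per channel, and `autoplot(report$summaries$cyl5)` draws the delay density.

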