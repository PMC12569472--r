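---
title: "From multi-channel EMG to swimming kinematics and sensorimotor delays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From multi-channel EMG to swimming kinematics and sensorimotor delays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In undulatory swimmers such as koi and carp, axial muscle serves two roles at
once: it drives the body wave, and it deforms with the body, so its afferents
can report flow-induced bending. Telling these roles apart in a freely
swimming fish comes down to timing. If muscle is driving, its electrical
activation (EMG) must precede the body's motion; if the body is being pushed
around by the flow — for example by vortices shed from an upstream bluff body
— local bending can precede the EMG burst that responds to it.

`emgkin` implements the full analysis chain for that question: condition
multi-channel EMG recorded along both sides of the body, reduce tracked
midline poses to a small set of joint angles, map EMG to kinematics with
neural-network regressors (a platform-validation step), and compute the
signed delay

\[
\Delta t = t_{\mathrm{LD\ extremum}} - t_{\mathrm{EMG\ onset\ peak}}
\]

between each lateral-displacement (LD) extremum and its matched EMG onset
peak. Positive \(\Delta t\): muscle leads (actuation). Negative: body leads
(consistent with proprioceptive, flow-driven activation). The headline
statistic is simply the fraction of negative \(\Delta t\).

Because the package is developed and tested without access to any animal
data, it ships a synthetic-trial generator whose every stage has known ground
truth. All quantitative statements below are computed by the test suite or
the acceptance script, never asserted from memory.

## Signal conditioning

Raw EMG (nominally 2.5 kHz, mV) is processed per channel, in order:

1. mean subtraction;
2. zero-phase 50 Hz biquad notch (RBJ design, `Q = 30`);
3. zero-phase Butterworth bandpass, 20–450 Hz, order-4 design;
4. resampling to the 1 kHz working rate by modified-Akima interpolation
   (the 450 Hz cutoff already anti-aliases the 1 kHz target), followed by a
   final mean re-adjustment.

Zero phase matters more than any other property here: the delay statistic is
a timing measurement, and a causal filter's group delay would bias every
\(\Delta t\). Both filters are applied forward–backward with odd-reflection
edge padding; without the padding a high-Q notch rings for tens of
milliseconds at the trace edges. The conditioning chain is verified to
introduce `0 ± 1` samples of lag on a burst train and to attenuate a pure
50 Hz tone by more than 40 dB.

The activation envelope is full-wave rectification followed by a centred
moving average (default 50 ms, roughly a tenth of a tail-beat period at the
observed beat frequencies). Edges use shrinking windows rather than zero
padding, so envelope peaks near the trace ends are not pulled down.

Quality metrics follow the conventional definitions: per-channel SNR is the
ratio of mean power in burst epochs to mean power in quiescent epochs
(reported linear and as \(10\log_{10}\) dB), and crosstalk is the signed
pairwise Pearson correlation between conditioned channels over burst epochs.
The two conventions are reported side by side because they are not redundant:
a linear SNR of 172 corresponds to 22.4 dB, not to any smaller printed value,
and the package makes no attempt to reconcile inconsistent conventions.

## The feature/segment input matrix

Each conditioned channel contributes 38 columns to the model input: an
18-feature block and a 20-sample signal block.

The 18 features per time index (computed on a centred 256-sample window,
stride 1) are:

* time domain — mean absolute value, RMS, variance, waveform length, zero
  crossings, slope-sign changes, Willison amplitude (threshold 0.01 mV,
  configurable), integrated EMG;
* frequency domain — mean, median and peak frequency, total power,
  normalised spectral entropy, and the 20–100 Hz / 100–450 Hz band-power
  ratio, all from a Hann-windowed FFT of the window;
* time–frequency — relative energies of the D1, D2, D3 and A3 bands of a
  three-level Daubechies-4 wavelet cascade.

Implementation notes that affect numbers: time-domain features use true
shrinking windows at the trace edges, while spectral windows are
edge-replicated so that every FFT has identical resolution (about 3.9 Hz per
bin at 1 kHz). The wavelet cascade is the undecimated (stationary) variant,
which keeps coefficients aligned to samples; windowed band energies are then
rolling sums of squared coefficients, and every energy ratio defines
\(0/0 = 0\) so silent traces produce zero features rather than NaN. The
window length of 256 samples trades ~1 Hz-class spectral resolution against
temporal smearing of about a quarter tail-beat; it is configurable.

The signal block is a trailing (causal) 20-sample window of the conditioned
trace, stride 1, with the first 19 rows edge-replicated. A causal window is
used so that no model input contains future EMG relative to the pose it
predicts.

Channels are stacked in the fixed order `L1..L6, R1..R6` (restricted to
channels present), giving \(n \times 456\) for 12 channels. Column names
carry channel and feature provenance, and slicing a channel subset out of the
full matrix is verified to equal assembling the matrix from that subset.

## Kinematics

Pose tracks are 12 midline landmarks at 100 fps with per-landmark tracking
likelihoods. Samples at or below likelihood 0.9 are dropped per landmark and
gap-filled by modified-Akima interpolation, which preserves retained samples
exactly and is idempotent. The cleaned track is upsampled to 1 kHz the same
way to share a clock with the EMG.

Six landmarks (default indices 1, 4, 6, 8, 10, 12 — head, mid-body, then
posterior-dense, matching the electrode region at 0.5–1.0 body lengths)
define five rigid segments. The four joint angles are the signed planar
angles between consecutive segments, counter-clockwise positive, in degrees;
segment lengths are per-trial medians of the inter-landmark distances.
Forward kinematics re-chains these as planar rigid transforms from a
head-attached frame. The two directions round-trip to \(10^{-9}\) relative
error on noiseless input, and reconstruction preserves link lengths exactly;
a displayed midline is additionally smoothed through the six anchors by
modified-Akima interpolation without moving the anchors.

Lateral displacement of a landmark is its signed perpendicular coordinate
relative to the flow axis through its trial-mean position. From the tail LD
the package computes the tail-beat frequency (dominant Welch-spectrum peak
with parabolic refinement), period, amplitude (mean peak-to-peak excursion
over detected half-cycles — the peak-to-peak convention is recorded because
it changes the Strouhal number by a factor of two), and
\(\mathrm{St} = f A / U\).

Prediction quality is measured by per-joint RMSE (degrees), the x-coordinate
RMSE of the six reconstructed anchors (cm), and the instantaneous phase
difference between predicted and measured angles from the analytic signal,
wrapped to \((-180^\circ, 180^\circ]\) with a circular mean. The analytic
signal is computed by FFT half-spectrum doubling; the first and last 5% of
samples are excluded from the mean to avoid edge transients.

## The EMG-to-kinematics regressors

Three model families map the input matrix to the four joint angles, all
trained with Adam on mean-squared error, early stopping on a
held-out-within-train validation split, and full determinism under a fixed
seed:

* `dense` — a multilayer perceptron (default plan 512–256–128);
* `recurrent` — stacked simple recurrent (Elman) layers over a trailing
  20-step window (default 64–16). Gated cells would add capacity the
  desk-scale datasets cannot use; the stacked Elman design keeps the family
  sequential while remaining trainable in seconds;
* `convolutional` — the 20-step window treated as an image, two 3×3
  convolution blocks (default 32 and 64 filters) with max-pooling, then a
  dense head.

The engine is written in plain R matrix algebra; analytic gradients for all
three families are pinned against numerical differentiation in the test
suite. Inputs are standardised per column and targets per angle using
statistics from training rows only; validation is the last 10% of each
training subject's rows, time-ordered, so no temporal or subject leakage
enters model selection. A fitted model rejects prediction inputs whose width
is not 38 × (its channel count).

Subject-wise splitting mirrors the design in which eight subjects train the
models and a ninth tests them: train and test subjects are disjoint by
construction and verified by recomputation.

The channel-count study retrains the model on declared symmetric subsets —
4 = {L1, L6, R1, R6}, then adding {L3, R3}, {L4, R4}, {L2, R2}, and finally
{L5, R5} — on a fixed seed schedule, reporting mean ± SD of test RMSE per
count.

## Delay analysis

EMG onset peaks are local envelope maxima with topographic prominence at
least `prominence_k` (default 3) times the channel envelope's median absolute
deviation, separated by at least 0.4 tail-beat periods (the higher of two
conflicting candidates wins). LD extrema use the same mechanism on the
series and its negation, with alternation enforced by dropping the lesser of
two same-kind neighbours.

Matching follows the piecewise rule with \(\varepsilon = 10\) ms: for each
LD extremum the nearest peaks before and after are located, and "before" is
chosen iff

\[
|t_k - t_{\mathrm{before}}| - |t_k - t_{\mathrm{after}}| < \varepsilon,
\]

otherwise "after". Note the asymmetry: within the \(\varepsilon\) band the
rule prefers "before" even when "after" is marginally closer. The rule is
implemented exactly as stated, and the test suite fixes this behaviour with
an explicit case (before at 50 ms, after at 45 ms — before wins). Left-side
channels pair with LD minima and right-side with LD maxima; because which
side's contraction produces an LD minimum depends on camera orientation, a
`flip_sides` flag is exposed (default off). Extrema with no peak within one
period yield no record. Growing \(\varepsilon\) can only switch choices from
"after" to "before", a property the suite checks over randomised event sets.

Summaries report the percentage of negative delays — always computed from
the raw records — plus an empirical density and an optional maximum-
likelihood location-scale F fit. The F distribution has non-negative
support, so a location-scale extension is the only way to fit signed delays;
it is descriptive only, and no headline number depends on it.

## The synthetic-trial generator

The generator produces coupled pose and EMG with the statistical structure
the analysis assumes, not a hydrodynamic simulation:

* **Kinematics** — a carangiform travelling wave
  \(y(s, t) = A(s)\,\mathrm{BL}\,\sin(2\pi(f t - s/\lambda))\) with
  \(A(s) = c_1 s + c_2 s^2\); defaults \(c_1 = 0.02\), \(c_2 = 0.08\) put the
  tail excursion at 10% of body length, amplitude growing toward the tail.
  Twelve landmarks sit at fixed arclength fractions, denser over the
  posterior half so that every electrode station (0.5–1.0 BL) has a
  coincident landmark. Default tail-beat period 0.612 s, flow 0.274 m/s,
  body length 30 cm, wavelength one body length.
* **EMG** — each channel bursts once per cycle, phase-locked to its own
  midline point's LD extremum (left to minima, right to maxima; the two
  sides' raised-cosine half-wave envelopes never overlap). The burst apex
  leads the extremum by \(\tau\) (default +50 ms, chosen larger than the
  envelope smoothing window so sign recovery is unambiguous). Under each
  envelope sits a band-limited (20–450 Hz) unit-variance carrier; baseline
  white noise (0.05 mV), 50 Hz mains (0.02 mV) and linear crosstalk (0.05
  from the mean of the other channels) are added on top.
* **Burst-to-burst variability** — every burst carries a lognormal amplitude
  gain (CV 0.25, mean 1). This mirrors the well-known cycle-to-cycle
  variability of EMG burst intensity, and it is load-bearing: on a perfectly
  periodic trial every feature is a function of cycle phase alone, so the
  columns of the input matrix would be collinear and no channel would carry
  information the others lack. The gain variability is what makes "more
  channels, better mapping" true in the synthetic world, as it is in real
  recordings.
* **Vortex conditions** — per burst, the lead flips sign with probability
  `neg_lag_fraction`. Presets: `laminar` 0, `cyl5` 0.48, `cyl7` 0.29
  (presets chosen to mirror the observed fractions in the two cylinder
  conditions; they are inputs to the generator, not predictions of it).
  Preset durations (20 s laminar, 26 s vortex) give roughly 500 matched
  events per vortex trial.

Because the lag is randomised per burst, every matched event has a
well-defined true sign, and recovery can be scored exactly. The generator
does **not** emulate: electrode motion artefacts, non-stationary beat
frequency, amplitude drift, tracking outliers beyond simple dropouts, or any
actual vortex hydrodynamics. Passing tests therefore demonstrate that the
pipeline measures what it claims on data with known structure — not that the
biological conclusions transfer to any particular real recording.

## Numerical choices and degenerate inputs

* Modified-Akima interpolation is used everywhere a track is resampled
  (published modified-Akima slope weights, cubic Hermite evaluation); it
  reproduces linear data exactly, preserves knots, and does not overshoot
  flat runs.
* Peak plateaus resolve to the plateau midpoint.
* Zero traces propagate to zero features via the \(0/0 = 0\) rule; flat LD
  series, empty envelopes, empty quiescent epochs, degenerate (zero-length)
  body segments, misaligned clocks beyond one sample, and channel counts
  exceeding availability are all hard errors with informative messages.
* Joint angles beyond 120° trigger an anatomical-plausibility warning, not
  an error, since transient tracking glitches should not kill a batch run.
* All randomness is seeded; sub-seeds are derived with a fixed integer
  recurrence kept below \(2^{31}\).

## Problem sizes

The test suite and acceptance script run everything at desk scale, chosen so
the full chain (not a toy of it) executes in minutes on one CPU: delay
recovery uses ten 20-second laminar trials (about 3 900 matched events) and
one trial of each vortex preset (about 500 events each); the mapping
validation uses one 60-second trial (60 001 samples × 456 columns) with
five pseudo-subjects, a 64-unit dense plan for the recovery check, and a
32-unit plan on a four-fold temporal subsample for the 25-fit channel-count
study. The declared default layer plans (512–256–128 dense, 64–16 recurrent,
32/64-filter convolutional) remain the package defaults for full-scale use.

## Known limitations

* The 18-feature set is a declared, documented choice; other feature
  catalogues exist, and column provenance is recorded precisely so
  substitutions stay localised.
* Whether spectral features should be computed on the filtered signal or its
  envelope is a genuine fork; the package uses the filtered signal and
  records the choice.
* The recurrent family is Elman, not LSTM; at these data sizes gating has
  nothing to gate, but the engine's layer plans are configurable if that
  changes.
* The delay-matching rule's \(\varepsilon\)-band asymmetry is implemented as
  printed; users who want a strictly-nearest rule can set
  `epsilon_ms = 0`.
* Percent-negative is a pooled statistic; per-channel and per-extremum-kind
  breakdowns are emitted alongside it, since pooling hides the
  posterior-body concentration of negative delays that motivates the
  analysis.
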