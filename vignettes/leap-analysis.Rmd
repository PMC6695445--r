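---
title: "Quantifying action potential morphology from multiwell MEA recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying action potential morphology from multiwell MEA recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leapmea)
```

## The measurement problem

Cardiomyocyte monolayers cultured on multiwell microelectrode array (MEA)
plates normally present a *field potential* (FP) on each electrode: a
sharp biphasic depolarization spike followed, hundreds of milliseconds
later, by a low, slow repolarization wave, much like a miniature ECG
complex. When the coupling between the syncytium and an electrode is
strongly enhanced, the same electrode instead reports a signal shaped
like the transmembrane *action potential* (AP) itself — a local
extracellular action potential (LEAP) — with amplitudes from a few
hundred microvolts up to ~10 mV, against the sub-350 µV FP scale.

`leapmea` implements the analysis chain for such plates: band filtering,
per-electrode classification (LEAP / FP / quiescent), beat detection and
segmentation, amplitude-normalized beat averaging, AP morphology metrics
(APD30/50/90, rise time, beat period and its variability, the
triangulation ratio APD50/APD90, automated EAD detection), FP endpoints
(spike amplitude, FPD, Fridericia-corrected FPDc), and well/plate-level
aggregation (stability time courses, dose-response summaries, pacing
analysis, rank-sum group comparison). A synthetic plate simulator
generates coupled AP/FP recordings with analytically known morphology so
that every stage is testable against closed-form ground truth.

## Metric definitions

All durations are reported in ms; voltages in µV; time is 0-based
seconds.

* **Beat start** — the max-slope fiducial of the rising edge. Because a
  near-linear upstroke has essentially constant slope, the sample of
  maximum smoothed derivative is ill-determined under noise; the
  implementation therefore pins the fiducial to the (sub-sample
  interpolated) half-amplitude crossing of the rising edge, which
  coincides with the midpoint of the max-slope region and has jitter of
  roughly `noise SD / upstroke slope` — far below one sample at any
  usable signal-to-noise ratio.
* **APD~x~** — from beat start to the first post-peak time at which the
  repolarization fraction `r(t) = (V_peak − V(t)) / (V_peak − V_trough)`
  reaches `x/100`, with linear interpolation between samples. Full
  repolarization is defined peak-to-trough of the beat window.
* **Rise time** — take-off point to peak. The take-off point is the last
  time before the max-slope sample at which the smoothed derivative is
  below 10% of the beat's maximum slope (configurable). The peak
  fiducial is the first sample within 1% of the beat maximum, so noise
  on a flat-topped AP cannot drag the apparent peak into the plateau.
* **Beat period (BP)** and **CoV** — intervals between consecutive beat
  starts; CoV uses the sample SD (n−1).
* **Triangulation ratio** — APD50/APD90. A perfectly square AP gives
  1.00; a strictly linear peak-to-trough decay gives 5/9 ≈ 0.56 (often
  quoted as 0.55); for the Hill repolarization family below the ratio is
  exactly `9^(−1/h)`.
* **EADs** — local maxima strictly between the depolarization peak and
  the time of 90% repolarization whose topographic prominence (height
  above the greater of the two flanking minima within the repolarization
  limb) is at least 20 µV *and* more than 2.5% of the LEAP amplitude.
  Prominence, not height above the trough, is used because the plateau
  itself sits far above the trough. The window ends at 90%
  repolarization to separate early from delayed afterdepolarizations.
* **FP endpoints** — spike amplitude (peak-to-trough within ±10 ms of
  the spike extremum), FPD (spike extremum to the extremum of the
  repolarization feature: the largest absolute deflection between
  100 ms after the spike and 90% of the beat period, polarity-agnostic,
  ties to the earlier time), and FPDc = FPD / (BP in s)^(1/3)
  (Fridericia). A feature below the noise floor is reported as not
  detectable ("ND") rather than guessed — broad repolarization waves
  under strong triangulation genuinely disappear into the noise.

## Classification and detection

An electrode is **LEAP**-class when its (LEAP-band filtered) trace has a
standard deviation above 100 µV and a beat amplitude — the median
per-beat peak-to-trough — above 350 µV; an electrode with beats failing
either threshold is **FP**; an electrode with no detectable beats is
**quiescent**. Within a well, the LEAP electrode with the largest median
beat amplitude is selected for morphology analysis (ties to the lowest
electrode index), mirroring common practice of analyzing the largest,
most robust AP signal per well.

Beat detection is slope-based for AP-shaped signals: candidates are
regions where the smoothed derivative exceeds 30% of the 95th percentile
of per-block maximum slopes (blocks of one refractory period, default
250 ms), floored at six robust SDs of the slope trace so that pure noise
yields no beats. FP beats are detected analogously on the absolute
deflection, with a higher fraction (50%) because the spike dominates the
repolarization wave. Both detectors discard a trailing partial beat
(window shorter than 75% of the median beat period), since morphology
metrics need a complete repolarization.

## Numerical choices

* **Filtering.** The acquisition bands are 1–2000 Hz (FP) and
  0.01–2000 Hz (LEAP). The low edge is implemented as subtraction of a
  zero-phase running-mean baseline with window `1/low_hz` seconds: this
  removes DC exactly, has unity passband gain, and avoids the numerical
  fragility of an IIR high-pass with a normalized cutoff of 10^-4^. When
  the window exceeds the trace, a constant mean is subtracted — a
  sliding window that large can only resolve edge-shrinkage tilt, which
  was observed to bias slow APD90 crossings by ~10 ms. The high edge is
  a zero-phase 2nd-order Butterworth low-pass (4th-order magnitude via
  forward–backward filtering), skipped when the edge lies at ≥80% of
  Nyquist where it would only add ringing.
* **Smoothing.** Slopes use a Savitzky–Golay filter (cubic, ~2 ms
  window). Peak/trough *levels* use a running median (~5 ms window)
  instead: a polynomial filter overshoots at waveform corners by a few
  percent of the amplitude, while the median filter is exact on
  monotone segments and unbiased on flat ones. Averaged templates are
  median-filtered before APD threshold crossing for the same reason —
  the residual noise floor otherwise biases the trough estimate
  downward and the slow APD90 crossing late.
* **Averaging.** AP metrics are computed on the amplitude-normalized
  waveform template averaged over 5 beats (configurable), aligned at
  the beat-start fiducial with a 20 ms pre-roll so the take-off point is
  retained; beats whose pre-roll would fall off the trace edge are not
  averaged. The averaged template is renormalized to exactly [0, 1].
* **Interpolation.** All level crossings (APD, beat-start fiducial) are
  linearly interpolated between samples, giving sub-sample resolution at
  12.5 kHz and deterministic tie-breaks.

## The synthetic plate simulator

The simulator emulates the study conditions of a multiwell MEA
experiment: 12.5 kHz sampling (configurable), plates of 24/48/96 wells,
spontaneous beating with beat-period CoV from below 1% (typical of
hiPSC-CM lines) to ~40% (pacemaker-reprogrammed cultures), paced trains,
LEAP amplitudes of 350 µV–10 mV against FP amplitudes below 350 µV,
electroporation-style exponential amplitude decay (default time constant
30 s, which takes a 2 mV signal below the FP scale within two minutes)
versus stable LEAP coupling, injected EADs, and additive white noise
plus sinusoidal baseline wander.

AP templates are phenomenological, not biophysical. Three families
cover the morphology space, each with closed-form APDs:

* `hill` — repolarization `V(t) = 1/(1 + (t/θ)^h)` from the end of the
  upstroke, so `APD_x = θ (x/(100−x))^{1/h}` and the triangulation ratio
  is `9^{−1/h}`; `h` sweeps from triangular (~1) to square (large).
  The slow tail is truncated where repolarization reaches `tail_cut`
  (default 99%), giving finite support without touching any APD up to
  that level.
* `linear` — optional plateau then straight-line decay
  (`APD_x = plateau + (x/100)·repol`); with no plateau this is the
  canonical perfect triangle.
* `square` — plateau and a one-sample drop; every APD equals the
  plateau duration.

Restitution is modeled as a monotone steady-state map
`APD90_ss(BP) = APD90_max − k·exp(−BP/τ)` with per-beat relaxation
toward the steady state over `adaptation_beats` (95% adaptation,
default 25 beats): beat period follows a rate change immediately while
APD adjusts slowly, and steady-state APD90 is shorter at faster rates.

**The FP model.** The depolarization spike is the band-limited negative
time derivative of the AP upstroke — the classical source of the
QRS-like complex. The repolarization wave, however, is *not* modeled as
the derivative of the single-cell repolarization limb: for the Hill
family the derivative extremum sits at `θ((h−1)/(h+1))^{1/h}`, which is
strictly *before* APD50 for every `h > 1` (and at repolarization onset
for `h = 1`), whereas measured FPDs consistently fall between APD50 and
APD90. The wave recorded extracellularly reflects repolarization
dispersion across the syncytium rather than the local derivative, so
the simulator models it explicitly: a raised-cosine wave spanning the
APD50–APD90 interval, peaking at its midpoint, with duration bounded at
0.5 s (the dispersion scale, which also keeps the wave inside the 1 Hz
acquisition band) and height inversely proportional to duration, down
to a floor of 5% of the spike. Triangulated APs thus produce the broad,
low, hard-to-detect repolarization features seen in real recordings,
while FPD tracks APD90 tightly across morphologies (rank correlation
≈ 0.98 over a 48-condition sweep). FP amplitude is calibrated on the
analysis-filtered view of the trace, because a band-limited spike has
no unique amplitude independent of the measurement bandwidth.

EAD injection adds a raised-cosine bump of stated height (µV above the
local repolarization trend) at a stated time fraction of the
repolarization interval, with a per-beat Bernoulli probability. Note
that the *measured* topographic prominence of a bump on a sloped limb is
smaller than the injected height by roughly `slope × half-width`;
boundary-exact tests therefore inject on flat plateau segments, and
simulated EAD studies site the bump on the slow late limb.

What the generator does **not** emulate: ionic-current dynamics (no
Hodgkin–Huxley-type model), conduction and propagation across
electrodes, electrode impedance spectra, measured noise or drift spectra
of real hardware (white noise plus a sinusoid is a placeholder; both are
config-exposed), FP-visible EAD counterparts, and cell-biological
variability beyond log-normal coupling-amplitude jitter. Tests passing
on synthetic plates therefore validate the *measurement chain* — not the
biology of any particular cell line.

## Aggregation conventions

* FP endpoints are averaged across the FP-class electrodes of a well
  (the mean, matching mean ± SD reporting conventions); LEAP metrics
  come from the single best electrode.
* Stability time courses choose the best LEAP electrode per well on the
  first checkpoint and ask whether *that same electrode* still passes
  the LEAP rule later — per-well persistence, not any-electrode
  persistence.
* Dose-response summaries report mean ± SD (n−1) over non-quiescent
  wells per group and tally quiescent wells separately; the default
  workflow is endpoint-style (dosed wells vs. vehicle group), with
  `percent_change()` supporting baseline-vs-post designs.
* Pacing analysis segments the stimulus train into constant-interval
  blocks; capture means a beat start within ±100 ms of a stimulus, and
  steady-state BP/APD90 are averaged over the final third of each block,
  after the slow APD adaptation has settled.
* Group comparison wraps the two-sided Mann–Whitney rank-sum test
  (exact when sizes allow and ties are absent, midrank normal
  approximation otherwise).

## Problem sizes used in the test-suite

Verification runs at desk scale: closed-form template checks at
12.5 kHz; simulated plates at 2 kHz with 6–24 wells, 1–2 electrodes per
well and 8–14 s of recording; the morphology sweep uses 48 random Hill
conditions; beat-period variability recovery uses 500-beat trains; the
EAD operating point uses 200 simulated beats with prominences
log-uniform on 5–100 µV. These sizes were chosen so the full suite runs
in well under a minute while every tolerance is dominated by the method,
not the sample size.

## Known limitations

* The beat-start fiducial sits at the upstroke midpoint, so APDs are
  measured ~half a rise time short relative to an onset-referenced
  convention; with 1–10 ms rise times this is within a few ms and
  cancels entirely in within-well comparisons.
* APD90 crossings on slow tails have an irreducible noise sensitivity
  of `σ_eff / |slope|`; beat averaging and median filtering reduce
  `σ_eff` but cannot beat that floor.
* FPD on strongly triangulated syncytia is frequently "ND" by design;
  downstream summaries must expect missing FPD values.
* The classification thresholds (100 µV SD, 350 µV amplitude) are
  applied to the LEAP-band filtered trace; raw-trace thresholds would
  differ only through baseline wander.
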