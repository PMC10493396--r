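---
title: "Methods: SKNA and HRV analysis around autonomic dysreflexia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SKNA and HRV analysis around autonomic dysreflexia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(sknahrv)
```

This vignette documents the models, parameters and numerical choices behind
`sknahrv`. The package analyses two synchronized signal streams around
autonomic dysreflexia (AD) episodes in a rat model: skin sympathetic nerve
activity (SKNA) read from high-rate ECG electrodes, and heart rate
variability (HRV) plus systolic blood pressure (SBP) from telemetry. A
stimulus marker channel carries the onset of each colorectal distension
(CRD) trial, which anchors all timing analysis.

## The SKNA measurement model

Ordinary ECG electrodes record both the cardiac signal (below a few hundred
Hz) and sympathetic nerve traffic, which is broadband and survives above
the cardiac band. The extraction chain is therefore:

1. **Downsampling** 10 kHz → 2 kHz (`downsample_ecg()`), with a zero-phase
   8th-order Butterworth anti-alias low-pass at 80 % of the target Nyquist.
2. **High-pass at 500 Hz** (`highpass_skna()`). The filter family and order
   are not pinned down by the measurement convention, only the cutoff; we
   use a Butterworth high-pass applied forward–backward, because zero
   group delay is what keeps burst *onsets* undistorted — the whole delay
   analysis depends on that. The single-pass order (default 6) was chosen
   so that the two-pass response attenuates less than 1 dB at 1.25× the
   cutoff while rejecting more than 20 dB at half the cutoff. At the 2 kHz
   working rate the surviving band is effectively 500–995 Hz, which is
   also the burst-detection band.
3. **ISKNA** (`integrate_skna()`): the rectified signal integrated over
   consecutive non-overlapping 100 ms windows, `sum(|x|)/fs` in µV·s,
   giving a 10 Hz sympathetic-tone envelope. Rectangular integration was
   chosen over trapezoidal; at 200 samples per window the difference is
   below one part in 10⁴ and far below any other uncertainty. Windows are
   non-overlapping so that the series is a partition of the signal (the
   sum of ISKNA values equals the integral of |x| over the covered span —
   a conservation property the tests assert). A trailing partial window is
   dropped rather than rescaled.

### Burst detection

`amplitude_envelope()` band-passes to 500–995 Hz, takes the magnitude of
the analytic signal (FFT construction), smooths with a 10 ms moving
average, and divides by the mean of the whole series. Normalizing by the
mean — not the median — makes the envelope dimensionless with mean exactly
1 and the detector invariant to any uniform amplitude scaling of the raw
signal (electrode gain, units).

`detect_bursts()` applies the dual-threshold rule: a burst exists wherever
the envelope has a contiguous run above the low threshold containing at
least one sample above the high threshold; the run's edges are the burst's
onset and offset. The threshold values are a free choice of the method —
they are defined in normalized units but not prescribed — so they are
exposed as parameters with defaults `thresh_hi = 2.0`, `thresh_lo = 1.0`
(i.e. twice the mean amplitude to open a burst, back to the mean to close
it). Two hygiene parameters suppress sampling chatter: bursts closer than
`merge_gap = 10` ms are fused and bursts shorter than
`min_duration = 20` ms are discarded; both are configurable. A burst
straddling an interval edge is attributed to the interval containing its
onset.

On planted synthetic bursts the detector's sensitivity and precision are
both above 0.9 at in-band SNR ≈ 3.6 (the acceptance suite measures this);
precision degrades toward ~0.88 as SNR approaches 3 with the default
thresholds, which is why they, and `min_duration`, remain user-facing.

## HRV features

`detect_r_peaks()` is a Pan–Tompkins-style detector (8–50 Hz band-pass,
squared derivative, 30 ms integration window) with the decision threshold
set at a fixed fraction of a high quantile of the integrated energy, so it
is scale-invariant; the refractory period defaults to 60 ms, the
physiological RR floor for rat heart rates up to ~600 beats/min.
`rr_intervals()` flags intervals outside 60–400 ms as artifacts;
successive-difference pairs spanning a rejected interval are excluded from
RMSSD. RMSSD is `sqrt(mean(diff(nn)^2))`; `median_nn()` is the plain
sample median of the NN intervals in ms (the literature occasionally
describes this feature in other terms; the quantity computed and compared
between conditions is the median). Sliding-window feature series
(`hrv_sliding_features()`, default 10 s windows hopping 1 s) are stamped
at the **window end**: a causal stamp, so a feature can never appear to
rise before the physiology that caused it — with center stamping every
onset-delay estimate would be biased early by half a window.

## Frequency domain

`lomb_psd()` implements the classic least-squares Lomb–Scargle
periodogram on the NN tachogram (value vs. beat time — no resampling to a
uniform grid), after removing a least-squares linear trend and applying a
Hann data window (switchable; the window is normalized to preserve total
power on average). For uniformly sampled data the estimator reduces to the
standard FFT periodogram `|X(f)|²/N`, and the test suite asserts agreement
within 2 % as well as a Parseval-style total-power check. The default
evaluation grid is 0.002–2.5 Hz in 0.002 Hz steps — fine enough to resolve
the 0–0.2 Hz VLF band with 100 points.

`band_powers()` integrates the PSD over the rat bands (VLF 0–0.2, LF
0.2–0.75, HF 0.75–2.5 Hz) by the trapezoidal rule. Percentages are defined
over the VLF+LF+HF total, so they sum to 100 by construction; the LF/HF
ratio is computed from absolute powers, and absolute powers are also
reported because published per-subject percentage tables are not always
normalized to a stated base. A flat spectrum therefore yields the
width-proportional split 8 % / 22 % / 70 %.

`fft_spectrogram()` computes Hann-windowed overlapping FFT segments with
explicit segmentation (`n_segments = floor((len − nfft)/hop) + 1`,
`hop = nfft·(1 − overlap)`); defaults are 128 000-point segments with
93.75 % overlap (hop = nfft/16) restricted to 0–10 Hz. Each segment is
demeaned before windowing: ISKNA-like signals are non-negative with a
large mean, and without demeaning the DC pedestal leaks through the Hann
mainlobe into the lowest bins and masks exactly the slow (< 0.1 Hz)
rhythms of interest. `dominant_frequency()` returns the argmax of power
(averaged over segments for a spectrogram), resolves ties to the lowest
frequency, and can exclude the sub-resolution bins next to DC.

For the 0–10 Hz SKNA spectrum the raw SKNA signal itself (500–995 Hz) has
no content; the analysis uses the 10 Hz ISKNA series for slow ISKNA
rhythms, whose 5 Hz Nyquist covers the dominant frequencies of interest.
This is the largest interpretive decision in the spectral module.

## Event timing

`detect_ad_events()` is marker-anchored: it emits exactly one row per
stimulus pulse and never invents an event without one. For each marker the
pre-marker baseline (default 60 s) gives an SBP mean and SD; a trial is an
accepted AD event iff SBP exceeds the baseline mean by more than 15 mmHg
(the rat criterion; the 20 mmHg clinical human criterion is a parameter
away) within the 120 s search window **and** heart rate subsequently stays
at least 10 % below its pre-marker mean for at least 2 s. The original
procedure confirmed bradycardia visually; software needs an explicit rule,
and the 10 %/2 s default is that rule. A rise without bradycardia is
reported but flagged unaccepted.

Onset estimation uses a 20 % significance rule
(`detect_feature_rise()`): local maxima exceeding the baseline mean by
20 % are significant, and the rise time is read by walking back from the
peak to the last sample within one baseline SD of the baseline mean. Two
robustness choices matter here, both adopted after studying failure modes
on simulated cohorts:

* **Largest peak, not first.** `feature_delays()` anchors each feature's
  delay on its largest significant peak in the post-marker window. The AD
  response dominates every feature it affects; anchoring on the first
  significant peak instead lets a single chance resting burst shortly
  after the marker masquerade as the response and collapse the estimated
  delay toward zero.
* **One-SD walk-back margin.** With a noisy baseline the series crosses
  its own baseline mean constantly, so a pure mean-crossing rule drags
  rise times arbitrarily far back; stopping within one baseline SD of the
  mean makes the estimator insensitive to ordinary baseline fluctuation
  while reducing exactly to the mean-crossing rule on clean baselines.
  The same margin is used for the SBP rise onset.
* The ISKNA feature entering the delay analysis is a 10 s sliding mean of
  the ISKNA series (`iskna_sliding_mean()`, causal stamp), not the raw
  10 Hz series, so "significant rise" means sustained sympathetic
  elevation rather than one resting burst.

Delays are reported per feature (ISKNA, burst rate, RMSSD, HR-fall, SBP);
a feature with no significant excursion yields a missing delay, never
zero. `lead_time()` is the SBP delay minus the earlier of the ISKNA and
burst-rate delays. Whether published latencies are rise onsets or peak
times is not always explicit, so both are exported (`delay` and
`peak_time`).

## Statistics

`minmax_normalize()` rescales each (subject, day, feature) group to
`[0, 1]`, storing the group extremes so the mapping is invertible;
constant groups map to missing with a warning. `anova_oneway()` is the
classic equal-variance F test (via `oneway.test`), `tukey_kramer()`
reports studentized-range statistics with the unequal-n Tukey–Kramer
standard error (p-values from `TukeyHSD`), and `manova_wilks()` uses
Wilks' lambda (the most common default; other MANOVA statistics are out
of scope), reducing to the one-way ANOVA for a single feature. Analyses
are run on normalized values by design, with raw values a flag away.
Repeated trials across days are pooled per condition; a mixed-effects
treatment of the rat/day structure is a known limitation, not an option.
The ANOVA's type-I error rate is checked by simulation in the acceptance
suite (2000 null replicates, two groups of 10).

## The synthetic-data generator

`simulate_recording()` emulates the acquisition the analysis assumes —
not rat physiology in general:

* **ECG**: each beat is a sum of Gaussian bumps (P, Q, R, S, T; R ≈ 500 µV
  with 3 ms width). This is sufficient for R-peak detection and leaves
  nothing above 500 Hz (the R-bump's spectrum at 500 Hz is attenuated by
  ~e⁻⁴⁴), so QRS leakage into the SKNA band is negligible by
  construction — which is also why the chain needs no extra QRS-artifact
  suppression.
* **Beats**: RR intervals follow the instantaneous heart rate (baseline
  400 beats/min, per-beat HR noise 5 beats/min) plus Gaussian RR jitter
  (2 ms at rest). During an episode the jitter SD rises (10 ms default)
  from `crd_onset + rmssd_delay` — this is what elevates RMSSD — and HR
  drops by `hr_drop` (60 beats/min default) from
  `crd_onset + hr_drop_delay`, with short cosine ramps.
* **SKNA bursts**: band-limited (500–995 Hz) Gaussian noise scaled to the
  target RMS amplitude (10 µV default) and gated by a cosine-tapered
  envelope, which avoids spectral splatter outside the carrier band.
  Resting bursts arrive at 0.2 bursts/s, episode bursts at 2 bursts/s
  from `crd_onset + skna_delay`; trains are kept disjoint. The resting
  burst rate and the broadband noise amplitude are free parameters — the
  resting SKNA noise floor is not characterized anywhere we could anchor
  it — so they are exposed in `sim_config()`.
* **SBP**: an envelope only (baseline 120 mmHg), no pulsatile waveform,
  because the analysis consumes systolic values; the noise is a slow
  vasomotor-style wander (spline through 5 s knots, marginal SD
  2 mmHg) and each episode adds a smooth 30 mmHg ramp (5 s smoothstep)
  from `crd_onset + sbp_delay`.
* **Marker**: a single-sample pulse at each CRD onset.
* One seeded generator drives every channel; identical configurations give
  bit-identical recordings, and the planted truth (burst times, scenario
  delays, beat times) is attached to the recording.

`simulate_cohort()` draws per-subject SKNA and SBP latencies from normal
distributions truncated at zero — Normal(5.6, 4.5) s and
Normal(23.4, 18.0) s by default, matching the latency spread reported for
conscious rat CRD experiments — and `recover_cohort_delays()` pairs the
pipeline's estimates with the planted values.

What the generator does **not** emulate: real telemetry noise spectra,
electrode motion artifacts, ectopy and arrhythmia, pulsatile pressure, or
any neural/hemodynamic dynamics (the delays are planted, not produced by a
baroreflex model). Passing tests therefore demonstrate that the chain
recovers the structure it assumes — planted bursts, ramps and delays under
Gaussian noise — not that it is robust to every artifact of real
recordings.

## Problem sizes and numerical choices

The test and acceptance runs use recordings of 1–4 minutes at the full
10 kHz ECG rate and cohorts of nine subjects (~110–160 s each), sizes at
which the complete suite runs in about a minute on one core while still
exercising every stage at the real sampling rates. Zero-phase filtering
mirror-pads the signal (up to 1000 samples) before `filtfilt`, because
forward–backward filtering with zero initial conditions otherwise leaves
edge transients — on a constant input the unpadded error is O(1), the
padded error O(10⁻¹²). Degenerate inputs fail loudly and specifically:
an all-zero envelope cannot be normalized, a constant NN series has no
spectrum after detrending, a flat-line ECG yields zero peaks with a
warning, a signal shorter than one FFT segment names the remedy, and a
recording missing a channel names the channel and (in the pipeline) the
stage that needed it.

Recordings travel as one plain-text CSV per channel (`time_s,value`) with
a JSON sidecar for sampling rates, metadata and planted truth; this keeps
the container human-readable and dependency-free.

## Known limitations

* Burst-detection precision sits near 0.9 at in-band SNR 3 with the
  default thresholds; noisy recordings may need a higher `thresh_hi` or
  longer `min_duration`.
* Delay estimates inherit the 1 s hop and 10 s window of the sliding
  feature series; sub-second latency differences are not resolvable.
* The Lomb grid treats the NN tachogram as a point process sampled at
  beat times; very low frequencies (below ~2/segment length) are
  extrapolation.
* Band-power percentages are defined over VLF+LF+HF; comparisons against
  tables normalized to another base need the exported absolute powers.
* Statistics pool repeated trials; no mixed-effects modeling of the
  subject/day hierarchy.
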