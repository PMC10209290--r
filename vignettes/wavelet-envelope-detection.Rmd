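---
title: "Wavelet-envelope heartbeat detection: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelet-envelope heartbeat detection: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(webeat)
```

## The detection model

`webeat` locates heartbeats in single-channel ECG and PPG recordings. The
pipeline has three stages.

**Preprocessing.** ECG passes through untouched. PPG is first differenced
(`dPPG`), which converts each pulse's systolic upstroke into a concave
QRS-like bell, then low-pass filtered at 30 Hz to remove differentiation
noise. The derivative is the forward difference with the last value
replicated, so lengths are preserved; the filter is a 4th-order Butterworth
applied forward and backward, so it has unit DC gain and zero phase —
beat positions are not shifted. When the sampling rate is at or below
60 Hz the 30 Hz cutoff meets Nyquist and the filter stage is skipped with
a warning.

**Wavelet enhancement.** The prepared signal is decomposed with a
maximal-overlap (undecimated) discrete wavelet transform using the
Symlet-4 wavelet, whose nearly symmetric, biphasic shape resembles a QRS
complex. The depth adapts to the sampling rate, `N = ⌊log₂ Fs⌋`, so the
coarsest detail always reaches below the QRS band. Detail level `j` is
nominally associated with the octave `(Fs/2^(j+1), Fs/2^j)` Hz; levels
whose open octave intersects the open interval (5, 20) Hz are kept and the
rest — including the smooth, which carries DC and baseline wander — are
discarded. The modulus of the partial reconstruction, `|cQRS|`, is the
nonnegative detection signal. Strict containment of [5, 20] Hz in one
dyadic octave is impossible in general, so intersection is the selection
rule; it guarantees a nonempty, contiguous run of levels for every
`Fs ≥ 40` Hz.

**Candidate selection and envelope thresholding.** All local maxima of
`|cQRS|` form the pool `P_A`. A greedy rule — repeatedly take the highest
remaining peak and delete every peak less than 300 ms from it — thins the
pool to the candidate set `P_C`, whose members are pairwise at least
`round(0.3·Fs)` samples apart. The candidate set is then augmented three
times: the candidates are removed from the pool, the remaining maxima are
interpolated into an intermediate signal (*midSig*) with a piecewise cubic
Hermite polynomial (PCHIP), and midSig's spaced maxima join the candidate
set. Because PCHIP is monotone between knots, each round's midSig maxima
sit exactly on the locally highest remaining pool peaks, so the rounds
peel successive amplitude layers off the non-candidate maxima.

Two full-length upper envelopes are then interpolated (PCHIP again, held
constant beyond the outermost anchor):

* envelope 1 through the local maxima of the *augmented* candidate
  amplitude sequence — it passes through or above every candidate and
  follows the QRS amplitude regime;
* envelope 2 through the local maxima of the *first* augmentation round's
  midSig maxima — the layer just under the candidates (QRS shoulders and
  the largest inter-beat structure), which bridges high across the gaps
  between beats.

A candidate is classified as a heartbeat exactly when its amplitude
strictly exceeds the pointwise mean of the two envelopes. The mean sits
roughly halfway between the QRS amplitude profile and the strongest
sub-candidate structure: true beats clear it even when their amplitude
drops, while locally prominent noise peaks between beats fall below it.

Several readings of the envelope construction are textually possible; the
package's choice is empirical. Building envelope 2 from the *final*
augmentation round's maxima anchors it on the lowest residual layer; it
then collapses toward the noise floor between beats, and prominent noise
candidates exceed the mean threshold (measured on the synthetic grid
below: positive predictivity drops to 96–98%). With the first round's
layer the same grid yields 100% positive predictivity at unchanged
sensitivity, so that construction is the package default. Classification
is likewise restricted to the original, pre-augmentation candidates —
the augmented set may contain peaks closer than 300 ms across rounds,
and classifying only `P_C` keeps the output spacing guarantee. Both
choices are fixed, not configuration switches, except that
`detector_config(classify_on = "augmented")` exposes the alternative
classification basis for experimentation.

## Parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `min_sep_s` | 0.3 | s | minimum peak separation; bounds the detectable rate at 200 BPM |
| `n_iter` | 3 | – | augmentation rounds |
| `qrs_band` | (5, 20) | Hz | detail-level selection band; implies `Fs ≥ 40` Hz |
| `wavelet` | sym4 | – | mother wavelet (fixed) |
| `tol_s` | 0.15 | s | beat-matching tolerance for evaluation |
| `window_s` | 7.5 | s | online buffer length (≥ 5 beats at 40 BPM) |
| `shift_s`, `active_s` | 0.75 | s | online advance and confirmation zone |

Analytic consequences of these choices are computed by
`design_limits()`: a 40 Hz minimum sampling rate (Nyquist for the band
top), a 200 ms minimum record for 5 Hz spectral resolution, a 300 BPM
rate at which that minimum record would hold a full beat (i.e.
ventricular fibrillation — in practice records simply need to be longer
than 200 ms), a 200 BPM ceiling from the 300 ms separation, and 5 beats
per buffer at 40 BPM.

The evaluation tolerance of 150 ms is the established beat-by-beat
comparison convention; it is configurable for sensitivity analysis.

## The online detector

The buffer is divided, oldest to newest, into *processed* (6 s), *active*
(0.75 s) and *shift* (0.75 s) zones. Each time 0.75 s of new data has
arrived (data-driven, so results are independent of chunking), the
offline pipeline runs on the whole buffer and only beats falling in the
active zone are confirmed; the processed and shift zones exist so the
envelope fit is anchored on both sides of the confirmation region.
Consecutive active zones tile the time axis, duplicates across windows
are suppressed by a 300 ms proximity rule, and `online_flush()` processes
the final partial window. Beats inside the very first window's processed
zone are never confirmed — a live stream starts reporting only once the
buffer has filled — which is why offline and online outputs are compared
from 6 s onward; within that span they agree to within one sample on
stationary records.

## The synthetic generator

`synth_ecg()` and `synth_ppg()` produce records with exact
ground truth so the whole pipeline is testable without external data.
They emulate: quasi-periodic beats (Gaussian inter-beat jitter, SD
`hr_sd_s = 0.02` s, floored at 0.3 s to stay inside the method's design
range), beat-to-beat amplitude variability (`amp_cv = 0.10`), P/T-like
low-frequency waves (ECG), an asymmetric pulse with a fast logistic
upstroke and slow diastolic decay whose first derivative has one dominant
bell per beat (PPG), sinusoidal baseline wander (`wander_amp = 0.2` of
the beat amplitude at 0.3 Hz), and additive white noise. `noise_sd`
(default 0.05) is expressed relative to the QRS-like amplitude — for PPG
that is the dPPG bell height, not the raw pulse, so the raw-domain noise
is scaled accordingly. PPG pulse phases compress with the instantaneous
cycle length (fall onset `min(0.25 s, 0.38·RR)`, decay constant
`min(0.12 s, 0.18·RR)`), as systole shortens at high heart rates; with a
fixed systole the pulses of a 180 BPM rhythm would pile up without
returning to baseline. The PPG truth convention is the steepest-ascent
sample of each pulse, which is where dPPG peaks and the detector fires.

What the generator does **not** emulate: motion artefacts, electrode
noise and muscle artefact, ectopic morphologies, rhythm changes, power-line
interference, or the dicrotic notch. Passing the synthetic grid therefore
demonstrates the mechanics of the method — amplitude adaptation, band
selection, streaming equivalence — not clinical-grade performance on
pathological recordings.

All generation is deterministic given `seed` (R's Mersenne-Twister;
interval, amplitude and noise draws use seed, seed+1 and seed+2 so truth
times are reusable independently), and the session RNG state is left
untouched.

## Numerical choices

* **Transform boundaries.** The record is reflection-padded to twice its
  length before the circular MODWT pyramid and trimmed after inversion,
  suppressing wrap-around spikes at the edges. Perfect reconstruction
  (all levels + smooth) holds to better than 1e-8 relative error.
* **Filter edges.** The Butterworth stage odd-reflects ~100 samples at
  each end before the forward-backward pass so the filter's zero initial
  state decays inside the padding.
* **Depth clamping.** When a record is too short for `⌊log₂ Fs⌋` levels,
  the depth is clamped with a warning; records shorter than one filter
  length (8 samples) are an error.
* **Ties and plateaus.** Equal-height peaks resolve to the earlier index;
  a plateau reports its first sample; endpoints are never maxima.
* **Strictness.** "Less than 300 ms" is a strict comparison against
  `round(0.3·Fs)` samples (survivors may be exactly 300 ms apart), and
  "above the average" is a strict inequality.
* **Degenerate inputs.** An envelope with fewer than two anchor maxima
  degrades to a constant at the largest available magnitude (logged)
  rather than failing, so short online windows never crash; undefined
  metric ratios are reported as `NA`, never as zero.
* **Beat timestamps** are the `|cQRS|` peak locations. `detect(...,
  refine_s = w)` optionally snaps each beat to the raw-signal maximum
  within ±`w` seconds, off by default.

## Verification problem sizes

The test suite exercises 60 s records on the grid fs ∈ {128, 250, 360} Hz
× heart rate ∈ {45, 70, 120, 180} BPM for both modalities at the default
noise levels (fixed seeds), 1,000 randomized instances of the greedy
selection against an exhaustive reference, reconstruction and anchor
tolerances of 1e-8/1e-9, and streaming runs chunked three different ways.
`scripts/acceptance.R` re-runs the grid and the analytic derivations from
a caller-supplied seed.

## Known limitations

* **High-rate PPG.** At 180 BPM with physiological jitter, a few percent
  of inter-beat intervals sit at the generator's 0.3 s floor — exactly
  the method's 300 ms separation limit (instantaneous 200 BPM). PPG peak
  localisation jitters by 1–3 samples (differentiation, filtering and
  band-limited reconstruction of overlapping pulses), pushing such pairs
  below `round(0.3·Fs)` samples, where the greedy rule must drop one beat
  of the pair. Per-cell sensitivity at 180 BPM PPG is 95.5–99.4%
  depending on fs, against 100% everywhere else on the grid; the ECG
  branch is unaffected because its peaks localise exactly. This is a
  resolution limit of the 300 ms design parameter, not a tunable defect.
* **Record edges.** The envelopes are held constant beyond their
  outermost anchors, so the first and last beat of a record are
  classified against a less-informed threshold; errors concentrate there
  on real recordings.
* **Sampling rate.** Below 40 Hz the QRS band cannot be represented and
  the detector refuses to run.
* **Scope.** The detector marks beat locations only: no QRS on/offset
  delineation, P/T-wave detection, arrhythmia classification or
  multi-lead fusion, and the evaluation module scores beat-level matches
  only.
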