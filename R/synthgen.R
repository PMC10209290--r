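# Synthetic ECG and PPG generator with exact beat ground truth. The signals
# emulate the structural features the detector relies on: quasi-periodic
# QRS-like spikes with beat-to-beat amplitude variability, slower P/T-like
# waves, sinusoidal baseline wander, additive white noise, and a PPG pulse
# whose first derivative shows one dominant concave bell per beat.

# run expr with a private RNG stream; never disturbs the caller's RNG
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Configuration for the synthetic signal generator
#'
#' @param fs Sampling rate in Hz (>= 40, the detector's minimum).
#' @param duration_s Record length in seconds.
#' @param hr_bpm Mean heart rate, beats per minute (30-240).
#' @param hr_sd_s Standard deviation of the inter-beat interval, seconds
#'   (default 0.02, mild sinus variability).
#' @param amp_cv Coefficient of variation of per-beat amplitudes
#'   (default 0.10).
#' @param noise_sd Additive white-noise SD relative to the unit beat
#'   amplitude (default 0.05).
#' @param wander_amp Baseline-wander amplitude relative to the unit beat
#'   amplitude (default 0.2).
#' @param wander_hz Baseline-wander frequency in Hz (default 0.3,
#'   respiratory range).
#' @param seed Integer random seed; generation is fully deterministic given
#'   the seed (R's default Mersenne-Twister stream).
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(fs = 250, duration_s = 60, hr_bpm = 70,
                         hr_sd_s = 0.02, amp_cv = 0.10, noise_sd = 0.05,
                         wander_amp = 0.2, wander_hz = 0.3, seed = 1L) {
  if (fs < 40) stop("fs must be >= 40 Hz (minimum sampling rate for the 5-20 Hz QRS band)")
  stopifnot(duration_s > 0, hr_bpm >= 30, hr_bpm <= 240, hr_sd_s >= 0,
            amp_cv >= 0, noise_sd >= 0, wander_amp >= 0, wander_hz >= 0)
  structure(list(fs = fs, duration_s = duration_s, hr_bpm = hr_bpm,
                 hr_sd_s = hr_sd_s, amp_cv = amp_cv, noise_sd = noise_sd,
                 wander_amp = wander_amp, wander_hz = wander_hz,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Ground-truth beat times for a synthetic record
#'
#' Inter-beat intervals are drawn as `max(0.3, Normal(60/hr_bpm, hr_sd_s))`
#' seconds -- the 0.3 s floor keeps the truth compatible with the detector's
#' minimum-separation assumption (heart rates above 200 BPM are outside the
#' method's intended range). The first beat sits 0.5 s into the record, and
#' beats closer than 0.3 s to the record end are dropped so every beat's
#' waveform fits inside the record.
#'
#' @param cfg A [synth_config()].
#' @return A [beat_annotations] object (deterministic given `cfg$seed`).
#' @export
beat_times <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  mean_rr <- 60 / cfg$hr_bpm
  n_max <- ceiling(cfg$duration_s / 0.3) + 2L
  iv <- .with_seed(cfg$seed, pmax(0.3, stats::rnorm(n_max, mean_rr, cfg$hr_sd_s)))
  tt <- 0.5 + cumsum(c(0, iv))
  tt <- tt[tt <= cfg$duration_s - 0.3]
  beat_annotations(round(tt * cfg$fs), cfg$fs)
}

# per-beat amplitudes: 1 with coefficient of variation amp_cv, floored away
# from zero; drawn from the seed+1 stream so beat_times() stays reusable
.beat_amplitudes <- function(cfg, nbeats) {
  .with_seed(cfg$seed + 1L,
             pmax(0.3, 1 + cfg$amp_cv * stats::rnorm(nbeats)))
}

.wander_noise <- function(cfg, n, t, noise_scale = 1) {
  w <- cfg$wander_amp * sin(2 * pi * cfg$wander_hz * t)
  z <- .with_seed(cfg$seed + 2L,
                  stats::rnorm(n, sd = cfg$noise_sd * noise_scale))
  w + z
}

#' Synthesize an ECG-like record with ground truth
#'
#' Each beat contributes a unit-amplitude Ricker (Mexican-hat) QRS spike of
#' roughly 90 ms support -- sharp central peak with small negative side
#' lobes -- preceded by a low, broad P-like bump and followed by a T-like
#' bump; baseline wander and white noise are added on top. The ground truth
#' is the QRS template centre of each beat.
#'
#' @param cfg A [synth_config()].
#' @return List with `record` (a [signal_record], modality `"ecg"`) and
#'   `annotations` (the ground-truth [beat_annotations]).
#' @export
#' @examples
#' sim <- synth_ecg(synth_config(fs = 250, duration_s = 20, seed = 42))
#' length(sim$annotations)
synth_ecg <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  truth <- beat_times(cfg)
  n <- round(cfg$duration_s * cfg$fs)
  t <- (0:(n - 1)) / cfg$fs
  amps <- .beat_amplitudes(cfg, length(truth$indices))
  x <- numeric(n)
  sig_q <- 0.015                       # QRS width parameter (s)
  add_bump <- function(x, centre, amp, sd, shape = c("gauss", "ricker")) {
    shape <- match.arg(shape)
    lo <- max(1L, floor((centre - 5 * sd) * cfg$fs) + 1L)
    hi <- min(n, ceiling((centre + 5 * sd) * cfg$fs) + 1L)
    if (lo > hi) return(x)
    u <- (t[lo:hi] - centre) / sd
    x[lo:hi] <- x[lo:hi] + amp *
      if (shape == "ricker") (1 - u^2) * exp(-u^2 / 2) else exp(-u^2 / 2)
    x
  }
  for (k in seq_along(truth$indices)) {
    c_k <- truth$indices[k] / cfg$fs
    x <- add_bump(x, c_k, amps[k], sig_q, "ricker")       # QRS
    x <- add_bump(x, c_k - 0.18, 0.12 * amps[k], 0.025)   # P wave
    x <- add_bump(x, c_k + 0.28, 0.25 * amps[k], 0.060)   # T wave
  }
  x <- x + .wander_noise(cfg, n, t)
  list(record = signal_record(x, fs = cfg$fs, modality = "ecg",
                              label = sprintf("synth-ecg-seed%d", cfg$seed)),
       annotations = truth)
}

#' Synthesize a PPG-like record with ground truth
#'
#' Each beat contributes an asymmetric pulse: a fast systolic upstroke
#' (logistic rise, ~150 ms) followed by a slow diastolic fall, so the first
#' derivative shows exactly one dominant positive bell per beat. The ground
#' truth is the steepest-ascent sample of each pulse, which is where the
#' differentiated signal (and hence the detector) peaks.
#'
#' @param cfg A [synth_config()].
#' @return List with `record` (a [signal_record], modality `"ppg"`) and
#'   `annotations` (the ground-truth [beat_annotations]).
#' @export
synth_ppg <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  truth <- beat_times(cfg)
  n <- round(cfg$duration_s * cfg$fs)
  t <- (0:(n - 1)) / cfg$fs
  amps <- .beat_amplitudes(cfg, length(truth$indices))
  tau_r <- 0.025   # systolic rise time constant (s); upstroke ~150 ms
  x <- numeric(n)
  cc <- truth$indices / cfg$fs
  # pulse phases compress with the instantaneous cycle length, as systole
  # shortens at high heart rate; at resting rates the caps dominate
  rr <- c(diff(cc), 60 / cfg$hr_bpm)
  for (k in seq_along(cc)) {
    c_k <- cc[k]
    w_fall <- min(0.25, 0.38 * rr[k])  # onset of diastolic fall (s)
    tau_f <- min(0.12, 0.18 * rr[k])   # diastolic fall time constant (s)
    lo <- max(1L, floor((c_k - 0.3) * cfg$fs) + 1L)
    hi <- min(n, ceiling((c_k + w_fall + 5 * tau_f) * cfg$fs) + 1L)
    u <- t[lo:hi] - c_k
    x[lo:hi] <- x[lo:hi] + amps[k] *
      (stats::plogis(u / tau_r) - stats::plogis((u - w_fall) / tau_f))
  }
  # noise_sd is specified relative to the QRS-like amplitude, which for PPG
  # is the height of the dPPG bell (the first difference of a unit pulse),
  # not the pulse itself: max slope 1/(4*tau_r) per second = h per sample.
  # White noise of SD s on the raw PPG has SD s*sqrt(2) after differencing,
  # so s = noise_sd * h / sqrt(2) realises the requested dPPG noise level.
  h_bell <- 1 / (4 * tau_r) / cfg$fs
  x <- x + .wander_noise(cfg, n, t, noise_scale = h_bell / sqrt(2))
  list(record = signal_record(x, fs = cfg$fs, modality = "ppg",
                              label = sprintf("synth-ppg-seed%d", cfg$seed)),
       annotations = truth)
}
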