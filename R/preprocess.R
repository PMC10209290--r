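#' First difference of a PPG record
#'
#' The first derivative of a PPG pulse train (dPPG) exhibits one dominant
#' concave bell per heartbeat, structurally similar to the ECG's QRS complex,
#' which is what makes QRS detectors applicable to PPG. The forward
#' difference `x[n+1] - x[n]` is used, with the last value replicated so the
#' output length equals the input length.
#'
#' @param rec A [signal_record] with modality `"ppg"`.
#' @return A [signal_record] with modality `"dppg"`, same length and fs.
#' @export
first_difference <- function(rec) {
  stopifnot(inherits(rec, "signal_record"))
  if (rec$modality != "ppg")
    stop("first_difference expects a 'ppg' record, got '", rec$modality, "'")
  d <- diff(rec$samples)
  signal_record(c(d, d[length(d)]), fs = rec$fs, modality = "dppg",
                label = rec$label)
}

#' Zero-phase 30 Hz low-pass filter
#'
#' Band-limits the differentiated PPG before QRS enhancement. Realised as a
#' 4th-order Butterworth filter applied forward and backward
#' ([signal::filtfilt()]), so the pass band has unit DC gain and beat
#' locations are not shifted. When `fs <= 60` Hz the 30 Hz cutoff is at or
#' above Nyquist, the signal is already band-limited, and the stage is
#' skipped with a warning.
#'
#' @param rec A [signal_record].
#' @param cutoff_hz Cutoff frequency in Hz (default 30).
#' @param order Butterworth order (default 4).
#' @return A filtered [signal_record]; length, fs and modality preserved.
#' @export
lowpass_30hz <- function(rec, cutoff_hz = 30, order = 4) {
  stopifnot(inherits(rec, "signal_record"))
  if (rec$fs <= 2 * cutoff_hz) {
    warning(sprintf(
      "fs = %g Hz: %g Hz cutoff is at/above Nyquist; low-pass stage skipped",
      rec$fs, cutoff_hz))
    return(rec)
  }
  bf <- signal::butter(order, 2 * cutoff_hz / rec$fs, type = "low")
  # odd-reflection padding before the forward-backward pass, so the filter's
  # zero initial state decays inside the padding instead of distorting the
  # record edges
  x <- rec$samples
  n <- length(x)
  k <- min(n - 1L, 100L)
  left <- 2 * x[1] - x[(k + 1):2]
  right <- 2 * x[n] - x[(n - 1):(n - k)]
  y <- signal::filtfilt(bf, c(left, x, right))[k + seq_len(n)]
  signal_record(y, fs = rec$fs, modality = rec$modality, label = rec$label)
}

#' Prepare a raw record for QRS enhancement
#'
#' ECG records pass through unchanged. PPG records are converted to the
#' QRS-like dPPG form: first difference, then 30 Hz low-pass.
#'
#' @param rec A [signal_record] with modality `"ecg"` or `"ppg"`.
#' @return A [signal_record] ready for [enhance()].
#' @export
prepare_input <- function(rec) {
  stopifnot(inherits(rec, "signal_record"))
  switch(rec$modality,
    ecg = rec,
    ppg = lowpass_30hz(first_difference(rec)),
    stop("prepare_input expects modality 'ecg' or 'ppg', got '",
         rec$modality, "'")
  )
}
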