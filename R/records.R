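#' Construct a single-channel physiological signal record
#'
#' A `signal_record` is the container every stage of the pipeline consumes:
#' a uniformly sampled real-valued series, its sampling rate, and a modality
#' tag that decides how preprocessing treats it.
#'
#' @param samples Numeric vector of samples (arbitrary amplitude units,
#'   e.g. mV). Must be finite and of length >= 2.
#' @param fs Sampling rate in Hz (> 0).
#' @param modality One of `"ecg"`, `"ppg"`, `"dppg"`. ECG passes through
#'   preprocessing unchanged; PPG is differentiated and low-pass filtered;
#'   `"dppg"` marks an already-differentiated PPG.
#' @param label Free-text identifier carried along for reporting.
#'
#' @return An object of class `signal_record` with fields `samples`, `fs`,
#'   `modality`, `label`.
#' @export
#' @examples
#' rec <- signal_record(sin(2 * pi * 1.2 * seq(0, 10, by = 1 / 250)), fs = 250)
#' rec
signal_record <- function(samples, fs, modality = "ecg", label = "") {
  samples <- as.numeric(samples)
  if (length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a single positive number (Hz)")
  if (length(samples) < 2L)
    stop("a signal record needs at least 2 samples")
  if (!all(is.finite(samples)))
    stop("all samples must be finite")
  modality <- match.arg(modality, c("ecg", "ppg", "dppg"))
  structure(
    list(samples = samples, fs = as.numeric(fs), modality = modality,
         label = as.character(label)[1]),
    class = "signal_record"
  )
}

#' @export
print.signal_record <- function(x, ...) {
  cat(sprintf("<signal_record> %s: %d samples @ %g Hz (%.2f s)%s\n",
              x$modality, length(x$samples), x$fs,
              length(x$samples) / x$fs,
              if (nzchar(x$label)) paste0(" [", x$label, "]") else ""))
  invisible(x)
}

#' @export
length.signal_record <- function(x) length(x$samples)

#' Construct a set of beat annotations
#'
#' Beat locations are 0-based sample indices into the signal they annotate;
#' times in seconds are always `indices / fs`. Used both for detector output
#' and for reference (ground-truth or expert) annotations.
#'
#' @param indices Integer-valued vector of 0-based sample positions, strictly
#'   increasing, no duplicates.
#' @param fs Sampling rate in Hz of the annotated signal.
#'
#' @return An object of class `beat_annotations` with fields `indices`
#'   (integer) and `fs`.
#' @export
beat_annotations <- function(indices, fs) {
  if (length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a single positive number (Hz)")
  indices <- as.numeric(indices)
  if (length(indices) && (any(!is.finite(indices)) || any(indices < 0)))
    stop("beat indices must be finite and >= 0")
  if (length(indices) && any(indices != floor(indices)))
    stop("beat indices must be whole sample positions")
  if (is.unsorted(indices, strictly = TRUE))
    stop("beat indices must be strictly increasing (no duplicates)")
  structure(list(indices = as.integer(round(indices)), fs = as.numeric(fs)),
            class = "beat_annotations")
}

#' @export
print.beat_annotations <- function(x, ...) {
  cat(sprintf("<beat_annotations> %d beats @ %g Hz", length(x$indices), x$fs))
  if (length(x$indices) > 1) {
    rr <- diff(x$indices) / x$fs
    cat(sprintf(" (mean RR %.3f s, ~%.0f BPM)", mean(rr), 60 / mean(rr)))
  }
  cat("\n")
  invisible(x)
}

#' @export
length.beat_annotations <- function(x) length(x$indices)

#' Times of annotated beats in seconds
#'
#' @param ann A [beat_annotations] object.
#' @return Numeric vector, `indices / fs`.
#' @export
beat_times_s <- function(ann) {
  stopifnot(inherits(ann, "beat_annotations"))
  ann$indices / ann$fs
}

# internal: peak set -- parallel magnitudes P and 0-based locations L
peak_set <- function(P, L, fs) {
  P <- as.numeric(P); L <- as.integer(L)
  stopifnot(length(P) == length(L))
  if (length(L) > 1 && is.unsorted(L, strictly = TRUE))
    stop("peak locations must be strictly increasing")
  structure(list(P = P, L = L, fs = as.numeric(fs)), class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set> %d peaks @ %g Hz\n", length(x$P), x$fs))
  invisible(x)
}
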