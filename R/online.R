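# Online (streaming) variant: the offline detector runs over a sliding
# buffer, but only beats confirmed in the buffer's *active* zone are
# emitted. The buffer is split, oldest to newest, into processed | active |
# shift zones; the processed zone gives the envelopes left context, the
# shift zone right context, so envelope fits are stable where beats are
# confirmed. Processing is data-driven (every shift worth of new samples),
# which makes the output independent of how the stream is chunked.

#' Online buffer configuration
#'
#' Defaults follow the detector's streaming design: a 7.5 s buffer advanced
#' by 750 ms, with a 750 ms active zone (so the processed zone is 6 s). At
#' 40 BPM the buffer then always holds at least 5 beats, enough for the
#' envelopes to track QRS amplitude. The first confirmed beats appear once
#' the buffer first fills (7.5 s of data), and thereafter confirmation lags
#' the newest sample by the active + shift lookback (1.5 s).
#'
#' @param window_s Buffer length in seconds.
#' @param shift_s Advance between processing runs, seconds.
#' @param active_s Active-zone length, seconds.
#' @return A list of class `online_config`.
#' @export
online_config <- function(window_s = 7.5, shift_s = 0.75, active_s = 0.75) {
  stopifnot(window_s > 0, shift_s > 0, active_s > 0)
  if (window_s < active_s + shift_s)
    stop("window_s must be at least active_s + shift_s")
  structure(list(window_s = window_s, shift_s = shift_s, active_s = active_s),
            class = "online_config")
}

#' Create an online heartbeat detector session
#'
#' @param fs Sampling rate of the stream in Hz.
#' @param modality `"ecg"` or `"ppg"`.
#' @param config A [detector_config()].
#' @param online An [online_config()].
#' @return An object of class `online_detector`; feed it with
#'   [online_push()] and finish with [online_flush()].
#' @export
#' @examples
#' sim <- synth_ecg(synth_config(fs = 250, duration_s = 20, seed = 3))
#' det <- online_detector(250)
#' got <- integer(0)
#' for (chunk in split(sim$record$samples,
#'                     ceiling(seq_along(sim$record$samples) / 250))) {
#'   got <- c(got, online_push(det, chunk))
#' }
#' got <- c(got, online_flush(det))
online_detector <- function(fs, modality = "ecg",
                            config = detector_config(),
                            online = online_config()) {
  stopifnot(fs > 0)
  modality <- match.arg(modality, c("ecg", "ppg"))
  e <- new.env(parent = emptyenv())
  e$fs <- fs
  e$modality <- modality
  e$config <- config
  e$online <- online
  e$W <- round(online$window_s * fs)
  e$S <- round(online$shift_s * fs)
  e$A <- round(online$active_s * fs)
  e$buf <- numeric(0)
  e$buf_start <- 0L        # absolute 0-based index of buf[1]
  e$total <- 0L            # total samples received
  e$next_end <- e$W        # absolute end (exclusive) of the next window
  e$emitted <- integer(0)
  e$covered_to <- 0L       # absolute index up to which beats were confirmed
  e$flushed <- FALSE
  class(e) <- "online_detector"
  e
}

#' @export
print.online_detector <- function(x, ...) {
  cat(sprintf("<online_detector> %s @ %g Hz: %d samples seen, %d beats emitted\n",
              x$modality, x$fs, x$total, length(x$emitted)))
  invisible(x)
}

# run detect() on a window of the buffer; returns absolute beat indices
.window_beats <- function(state, from_abs, to_abs) {
  i0 <- from_abs - state$buf_start
  seg <- state$buf[(i0 + 1L):(to_abs - state$buf_start)]
  rec <- signal_record(seg, fs = state$fs, modality = state$modality)
  beats <- detect(rec, config = state$config)
  beats$indices + from_abs
}

# emit beats falling in [lo, hi), skipping any within min_sep of an
# already-emitted beat
.emit <- function(state, beats_abs, lo, hi) {
  m <- round(state$config$min_sep_s * state$fs)
  cand <- beats_abs[beats_abs >= lo & beats_abs < hi]
  out <- integer(0)
  for (b in cand) {
    recent <- c(state$emitted, out)
    if (!length(recent) || min(abs(recent - b)) >= m) out <- c(out, b)
  }
  state$emitted <- c(state$emitted, out)
  out
}

#' Push a chunk of samples into an online detector
#'
#' Samples accumulate until the buffer first holds a full window; from then
#' on the offline pipeline runs once per `shift_s` of new data and beats
#' confirmed in the active zone are returned as absolute 0-based sample
#' indices. Chunk size does not affect the emitted beat sequence.
#'
#' @param state An [online_detector()].
#' @param chunk Numeric vector of new samples (may be empty).
#' @return Integer vector of newly confirmed beat indices (possibly empty).
#' @export
online_push <- function(state, chunk) {
  stopifnot(inherits(state, "online_detector"))
  if (state$flushed) stop("detector already flushed")
  chunk <- as.numeric(chunk)
  if (length(chunk) && !all(is.finite(chunk)))
    stop("stream samples must be finite")
  state$buf <- c(state$buf, chunk)
  state$total <- state$total + length(chunk)
  out <- integer(0)
  while (state$total >= state$next_end) {
    e_abs <- state$next_end
    beats <- .window_beats(state, e_abs - state$W, e_abs)
    lo <- e_abs - state$A - state$S
    hi <- e_abs - state$S
    out <- c(out, .emit(state, beats, lo, hi))
    state$covered_to <- hi
    state$next_end <- state$next_end + state$S
    # the next window starts at next_end - W; nothing earlier is needed
    # again (a final flush looks back at most W samples from the end,
    # which is never earlier than this)
    drop <- (state$next_end - state$W) - state$buf_start
    if (drop > 0L) {
      state$buf <- state$buf[-seq_len(drop)]
      state$buf_start <- state$buf_start + drop
    }
  }
  out
}

#' Flush an online detector at end of stream
#'
#' Runs the detector once over the final (possibly partial) window and
#' returns the beats confirmed after the last active zone, up to the end of
#' the stream. A second flush returns nothing.
#'
#' @param state An [online_detector()].
#' @return Integer vector of remaining confirmed beat indices.
#' @export
online_flush <- function(state) {
  stopifnot(inherits(state, "online_detector"))
  if (state$flushed) return(integer(0))
  state$flushed <- TRUE
  if (state$total <= state$covered_to) return(integer(0))
  from <- max(0L, state$total - state$W, state$buf_start)
  if (state$total - from < 3L) return(integer(0))
  beats <- tryCatch(.window_beats(state, from, state$total),
                    error = function(e) {
                      warning("final window too short to process: ",
                              conditionMessage(e))
                      integer(0)
                    })
  out <- .emit(state, beats, state$covered_to, state$total)
  state$covered_to <- state$total
  out
}

#' Run the online detector over a complete record
#'
#' Convenience wrapper: streams a [signal_record] through an online session
#' in fixed-size chunks and returns all confirmed beats.
#'
#' @param rec A [signal_record].
#' @param config A [detector_config()].
#' @param online An [online_config()].
#' @param chunk_s Chunk size in seconds used for streaming (default 0.25);
#'   the result does not depend on it.
#' @param flush Also flush the tail (default `TRUE`).
#' @return A [beat_annotations] object.
#' @export
detect_online <- function(rec, config = detector_config(),
                          online = online_config(), chunk_s = 0.25,
                          flush = TRUE) {
  stopifnot(inherits(rec, "signal_record"))
  det <- online_detector(rec$fs, rec$modality, config, online)
  n <- length(rec$samples)
  step <- max(1L, round(chunk_s * rec$fs))
  got <- integer(0)
  i <- 1L
  while (i <= n) {
    j <- min(n, i + step - 1L)
    got <- c(got, online_push(det, rec$samples[i:j]))
    i <- j + 1L
  }
  if (flush) got <- c(got, online_flush(det))
  beat_annotations(sort(got), rec$fs)
}
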