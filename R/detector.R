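# Beat localisation on the QRS-enhanced signal |cQRS|: local-maxima
# selection with a 300 ms greedy minimum-separation rule, iterated candidate
# augmentation through an interpolated intermediate signal (midSig), and
# dual upper envelopes whose pointwise mean is the amplitude-adaptive
# detection threshold.

#' Detector configuration
#'
#' Collects the tunable parameters of the detector with their documented
#' defaults.
#'
#' @param min_sep_s Minimum separation between candidate peaks, seconds.
#' @param n_iter Number of candidate-augmentation iterations.
#' @param qrs_band QRS frequency interval in Hz.
#' @param wavelet Mother wavelet tag (only `"sym4"` is built in).
#' @param classify_on Which peak set is thresholded against the mean
#'   envelope: `"selected"` (the minimum-separation survivors; default) or
#'   `"augmented"` (survivors plus midSig-derived candidates).
#' @param tol_s Default beat-matching tolerance used by evaluation helpers.
#' @return A list of class `detector_config`.
#' @export
detector_config <- function(min_sep_s = 0.3, n_iter = 3L,
                            qrs_band = c(5, 20), wavelet = "sym4",
                            classify_on = c("selected", "augmented"),
                            tol_s = 0.15) {
  stopifnot(min_sep_s > 0, n_iter >= 1, length(qrs_band) == 2,
            qrs_band[1] > 0, qrs_band[2] > qrs_band[1])
  if (wavelet != "sym4") stop("only the Symlet-4 wavelet is built in")
  structure(list(min_sep_s = min_sep_s, n_iter = as.integer(n_iter),
                 qrs_band = qrs_band, wavelet = wavelet,
                 classify_on = match.arg(classify_on), tol_s = tol_s),
            class = "detector_config")
}

#' Local maxima of a signal
#'
#' A sample is a local maximum when it is strictly greater than both
#' neighbours; for a plateau (a run of equal values higher than both
#' flanking samples) the first sample of the run is reported. Endpoints are
#' never maxima. Signals shorter than 3 samples have none.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate in Hz (carried into the result).
#' @return A `peak_set` with magnitudes `P` and 0-based locations `L`.
#' @export
local_maxima <- function(x, fs) {
  n <- length(x)
  if (n < 3L) return(peak_set(numeric(0), integer(0), fs))
  r <- rle(x)
  k <- length(r$values)
  if (k < 3L) return(peak_set(numeric(0), integer(0), fs))
  # run j is a maximum iff it is higher than both neighbouring runs;
  # first and last runs touch the endpoints and are excluded
  j <- 2:(k - 1)
  is_max <- r$values[j] > r$values[j - 1] & r$values[j] > r$values[j + 1]
  starts <- cumsum(c(1L, r$lengths))[j][is_max]   # first sample of the run
  peak_set(x[starts], starts - 1L, fs)
}

#' Greedy minimum-separation peak selection
#'
#' Repeatedly takes the highest remaining peak (ties broken toward the
#' earlier location) and removes every other remaining peak less than
#' `min_sep_s` away from it, until no candidates remain. Survivors are
#' returned in temporal order and are pairwise at least
#' `round(min_sep_s * fs)` samples apart.
#'
#' @param peaks A `peak_set`.
#' @param min_sep_s Minimum separation in seconds (default 0.3).
#' @return A `peak_set` of the surviving peaks.
#' @export
min_separation_select <- function(peaks, min_sep_s = 0.3) {
  stopifnot(inherits(peaks, "peak_set"))
  n <- length(peaks$P)
  if (n == 0L) return(peaks)
  m <- round(min_sep_s * peaks$fs)
  ord <- order(-peaks$P, peaks$L)   # highest first, earlier wins ties
  alive <- rep(TRUE, n)
  keep <- logical(n)
  for (i in ord) {
    if (!alive[i]) next
    keep[i] <- TRUE
    alive[abs(peaks$L - peaks$L[i]) < m] <- FALSE
  }
  sel <- which(keep)
  peak_set(peaks$P[sel], peaks$L[sel], peaks$fs)
}

# evaluate a pchip interpolant through (xa, ya) on integer grid 0..n-1,
# held constant beyond the first/last anchor
.pchip_full <- function(xa, ya, n) {
  out <- numeric(n)
  xs <- 0:(n - 1)
  lo <- xa[1]; hi <- xa[length(xa)]
  inside <- xs >= lo & xs <= hi
  if (any(inside)) {
    if (length(xa) == 2) {
      # two anchors: pchip degenerates to the straight segment
      out[inside] <- ya[1] + (ya[2] - ya[1]) * (xs[inside] - lo) / (hi - lo)
    } else {
      out[inside] <- pracma::pchip(xa, ya, xs[inside])
    }
  }
  out[xs < lo] <- ya[1]
  out[xs > hi] <- ya[length(ya)]
  out
}

#' Iterated candidate augmentation through midSig
#'
#' Starting from the minimum-separation survivors (`pc`), the procedure runs
#' `n_iter` times: (a) remove every current candidate from the working copy
#' of the full local-maxima set `pa`; (b) interpolate the remaining maxima
#' with a piecewise cubic Hermite polynomial over the whole sample axis,
#' yielding the intermediate signal midSig; (c) take the local maxima of
#' midSig at least `min_sep_s` apart (greedy selection), discarding any that
#' coincide with an existing candidate location; (d) merge them, in temporal
#' order, into the candidate set. The growing set tracks the temporal
#' evolution of sub-threshold peaks, so the second envelope adapts to QRS
#' amplitude drops.
#'
#' Each round peels one "layer" off the non-candidate maxima: because the
#' Hermite interpolant is monotone between its knots, midSig's maxima sit
#' exactly on the locally-highest remaining |cQRS| maxima, which are then
#' absorbed and removed for the next round.
#'
#' @param pa `peak_set` of all local maxima of |cQRS|.
#' @param pc `peak_set` of minimum-separation survivors (subset of `pa`).
#' @param siglen Length of the underlying signal in samples.
#' @param n_iter Number of iterations (default 3).
#' @param min_sep_s Minimum separation in seconds (default 0.3).
#' @return List with `aux` (the augmented `peak_set`), `pms` (the first
#'   round's midSig maxima -- the intermediate-signal layer the second
#'   envelope is built from), and `pms_last` (the final round's midSig
#'   maxima). Either may be empty.
#' @export
augment_candidates <- function(pa, pc, siglen, n_iter = 3L, min_sep_s = 0.3) {
  stopifnot(inherits(pa, "peak_set"), inherits(pc, "peak_set"))
  if (!all(pc$L %in% pa$L))
    stop("`pc` must be a subset of `pa`")
  fs <- pa$fs
  aux_P <- pc$P; aux_L <- pc$L
  empty <- peak_set(numeric(0), integer(0), fs)
  pms_first <- pms <- empty
  for (it in seq_len(n_iter)) {
    keep <- !(pa$L %in% aux_L)
    pa <- peak_set(pa$P[keep], pa$L[keep], fs)
    if (length(pa$L) < 2L) {
      warning("fewer than 2 anchors remain for midSig interpolation; stopping after ",
              it - 1L, " iteration(s)")
      break
    }
    mid <- .pchip_full(pa$L, pa$P, siglen)
    cand <- min_separation_select(local_maxima(mid, fs), min_sep_s)
    new <- !(cand$L %in% aux_L)
    pms <- peak_set(cand$P[new], cand$L[new], fs)
    if (it == 1L) pms_first <- pms
    ord <- order(c(aux_L, pms$L))
    aux_P <- c(aux_P, pms$P)[ord]
    aux_L <- c(aux_L, pms$L)[ord]
  }
  list(aux = peak_set(aux_P, aux_L, fs), pms = pms_first, pms_last = pms)
}

# anchors for an upper envelope: local maxima of the magnitude sequence
# P[k] (as a series in k), mapped back to their sample locations. Fewer than
# 2 anchors degrades to a constant envelope at the largest magnitude.
.envelope_curve <- function(ps, siglen) {
  k <- length(ps$P)
  if (k == 0L) return(numeric(siglen))
  anchors <- local_maxima(ps$P, ps$fs)   # maxima of the magnitude sequence
  ak <- anchors$L + 1L                   # back to 1-based positions in P
  if (length(ak) < 2L) {
    message("envelope degenerated to a constant (fewer than 2 anchor maxima)")
    return(rep(max(ps$P), siglen))
  }
  .pchip_full(ps$L[ak], ps$P[ak], siglen)
}

#' Dual upper envelopes and their mean
#'
#' Builds two full-length upper envelopes: one through the local maxima of
#' the candidate magnitudes `pc`, one through the local maxima of the midSig
#' magnitudes `pms`, each interpolated with a piecewise cubic Hermite
#' polynomial and held constant beyond its outermost anchor. Their pointwise
#' mean is the adaptive detection threshold. An input with fewer than two
#' anchor maxima degrades to a constant envelope rather than failing, which
#' keeps short online windows usable.
#'
#' @param pc `peak_set` of candidate peaks (envelope one).
#' @param pms `peak_set` of midSig maxima (envelope two).
#' @param siglen Signal length in samples.
#' @return A list of class `envelope_set` with full-length numeric vectors
#'   `env_c`, `env_ms`, `mean_env`.
#' @export
build_envelopes <- function(pc, pms, siglen) {
  stopifnot(inherits(pc, "peak_set"))
  env_c <- .envelope_curve(pc, siglen)
  env_ms <- if (!is.null(pms) && length(pms$P))
    .envelope_curve(pms, siglen) else env_c
  structure(list(env_c = env_c, env_ms = env_ms,
                 mean_env = (env_c + env_ms) / 2),
            class = "envelope_set")
}

#' Classify candidate peaks as heartbeats
#'
#' Every candidate whose magnitude strictly exceeds the mean envelope at its
#' location is a heartbeat.
#'
#' @param pc `peak_set` of candidate peaks.
#' @param env An `envelope_set` covering all candidate locations.
#' @param fs Sampling rate in Hz of the annotated signal.
#' @return A [beat_annotations] object.
#' @export
classify_beats <- function(pc, env, fs = pc$fs) {
  stopifnot(inherits(pc, "peak_set"), inherits(env, "envelope_set"))
  hit <- pc$P > env$mean_env[pc$L + 1L]
  beat_annotations(sort(pc$L[hit]), fs)
}

#' Detect heartbeats in an ECG or PPG record
#'
#' The full pipeline: [prepare_input()] (PPG is differentiated and low-pass
#' filtered), [enhance()] (wavelet band selection, giving |cQRS|),
#' [local_maxima()], [min_separation_select()] (300 ms greedy rule),
#' [augment_candidates()] (3 midSig iterations), [build_envelopes()] and
#' [classify_beats()]. The output is invariant to positive amplitude scaling
#' and DC offsets of the input, and detected beats are always at least
#' `round(min_sep_s * fs)` samples apart.
#'
#' The beat timestamp is the |cQRS| peak location; `refine_s > 0` optionally
#' moves each beat to the largest raw-signal value within that many seconds.
#'
#' @param rec A [signal_record] with modality `"ecg"` or `"ppg"`.
#' @param config A [detector_config()].
#' @param refine_s Optional refinement half-window in seconds (default 0 =
#'   off).
#' @return A [beat_annotations] object.
#' @export
#' @examples
#' sim <- synth_ecg(synth_config(fs = 250, duration_s = 30, seed = 7))
#' det <- detect(sim$record)
#' beat_metrics(match_beats(det, sim$annotations))
detect <- function(rec, config = detector_config(), refine_s = 0) {
  stopifnot(inherits(rec, "signal_record"))
  if (!rec$modality %in% c("ecg", "ppg"))
    stop("detect expects modality 'ecg' or 'ppg'")
  prep <- prepare_input(rec)
  cqrs <- enhance(prep, band = config$qrs_band)
  pa <- local_maxima(cqrs, rec$fs)
  if (length(pa$P) == 0L) return(beat_annotations(integer(0), rec$fs))
  pc <- min_separation_select(pa, config$min_sep_s)
  aug <- augment_candidates(pa, pc, siglen = length(cqrs),
                            n_iter = config$n_iter,
                            min_sep_s = config$min_sep_s)
  env <- build_envelopes(aug$aux, aug$pms, siglen = length(cqrs))
  basis <- if (config$classify_on == "selected") pc else aug$aux
  beats <- classify_beats(basis, env, rec$fs)
  if (refine_s > 0 && length(beats$indices)) {
    w <- round(refine_s * rec$fs)
    n <- length(rec$samples)
    refined <- vapply(beats$indices, function(i) {
      lo <- max(0L, i - w); hi <- min(n - 1L, i + w)
      seg <- rec$samples[(lo:hi) + 1L]
      lo + which.max(seg) - 1L
    }, integer(1))
    beats <- beat_annotations(sort(unique(refined)), rec$fs)
  }
  beats
}
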