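# Maximal-overlap discrete wavelet transform (MODWT) with Symlet-4 filters,
# and the band-selected reconstruction that yields the QRS-enhanced signal
# |cQRS|. The MODWT is undecimated: every detail level and the smooth have
# the length of the input, so band-selected reconstructions stay aligned
# with the original samples. Circular filtering is used internally; records
# are reflection-padded first so record edges do not wrap around.

# Symlet-4 scaling (lo) and wavelet (hi) decomposition filters (8 taps,
# 4 vanishing moments; standard published coefficients)
.sym4_dec_lo <- c(-0.07576571478927333, -0.02963552764599851,
                   0.49761866763201545,  0.80373875180591614,
                   0.29785779560527736, -0.09921954357684722,
                  -0.01260396726203783,  0.03222310060404270)
.sym4_dec_hi <- c(-0.03222310060404270, -0.01260396726203783,
                   0.09921954357684722,  0.29785779560527736,
                  -0.80373875180591614,  0.49761866763201545,
                   0.02963552764599851, -0.07576571478927333)

#' Number of wavelet decomposition levels for a sampling rate
#'
#' The decomposition depth adapts to the sampling rate as
#' `N = floor(log2(fs))`, so the deepest detail level always reaches the
#' low-frequency end of the QRS band regardless of fs.
#'
#' @param fs Sampling rate in Hz (>= 2).
#' @return Integer number of levels.
#' @export
#' @examples
#' n_levels(128) # 7
#' n_levels(360) # 8
n_levels <- function(fs) {
  if (length(fs) != 1L || !is.finite(fs) || fs < 2)
    stop("`fs` must be a single number >= 2 Hz")
  as.integer(floor(log2(fs)))
}

#' Nominal passband of a MODWT detail level
#'
#' Detail level `j` of an undecimated dyadic wavelet transform is nominally
#' associated with the frequency octave `(fs / 2^(j+1), fs / 2^j)` Hz.
#'
#' @param fs Sampling rate in Hz.
#' @param j Detail level (>= 1).
#' @return Numeric vector `c(f_lo, f_hi)` in Hz.
#' @export
level_band <- function(fs, j) {
  if (any(j < 1)) stop("level index must be >= 1")
  c(fs / 2^(j + 1), fs / 2^j)
}

#' Select the detail levels covering the QRS frequency band
#'
#' QRS complexes concentrate their energy in roughly 5-20 Hz. A detail level
#' is kept when its nominal open passband intersects the open interval
#' `(band[1], band[2])`; with the dyadic octaves this always yields a
#' contiguous run of levels. At least one level exists whenever
#' `fs >= 2 * band[2]` (40 Hz with the default band).
#'
#' @param fs Sampling rate in Hz.
#' @param N Number of decomposition levels, normally [n_levels()]`(fs)`.
#' @param band QRS frequency interval in Hz, default `c(5, 20)`.
#' @return Integer vector of selected levels.
#' @export
#' @examples
#' select_levels(128, n_levels(128)) # 2 3 4
#' select_levels(360, n_levels(360)) # 4 5 6
select_levels <- function(fs, N = n_levels(fs), band = c(5, 20)) {
  if (fs < 2 * band[2])
    stop(sprintf(
      "fs = %g Hz cannot represent the %g-%g Hz QRS band; the minimum supported sampling rate is %g Hz",
      fs, band[1], band[2], 2 * band[2]))
  j <- seq_len(N)
  lo <- fs / 2^(j + 1)
  hi <- fs / 2^j
  sel <- j[lo < band[2] & hi > band[1]]
  if (!length(sel))
    stop(sprintf(
      "no decomposition level intersects the %g-%g Hz QRS band at fs = %g Hz; the minimum supported sampling rate is %g Hz",
      band[1], band[2], fs, 2 * band[2]))
  sel
}

# circular MODWT filtering of v with filter f upsampled by 2^(j-1);
# w[t] = sum_l f[l] * v[(t - 2^(j-1) l) mod n]  (analysis)
# and the synthesis direction uses +2^(j-1) l. Only 8 taps, so a plain
# loop over taps on shifted copies is fast.
.circ_filt <- function(v, f, j, dir = -1L) {
  n <- length(v)
  shift <- dir * 2^(j - 1) * (seq_along(f) - 1L)
  out <- numeric(n)
  idx0 <- seq_len(n) - 1L
  for (l in seq_along(f)) {
    out <- out + f[l] * v[((idx0 - shift[l]) %% n) + 1L]
  }
  out
}

#' Maximal-overlap discrete wavelet transform
#'
#' Decomposes a record into `N` same-length detail levels plus the level-`N`
#' smooth, using the Symlet-4 filter pair (rescaled by `1/sqrt(2)` per the
#' MODWT convention). The record is reflection-padded to twice its length
#' before the circular pyramid algorithm runs, and the padding is retained
#' inside the returned object so that [reconstruct_selected()] can trim it
#' after inversion; this suppresses wrap-around artefacts at record edges.
#'
#' `N` is clamped (with a warning) when the record is too short to support
#' the requested depth.
#'
#' @param rec A [signal_record].
#' @param N Number of levels; defaults to [n_levels()] of the record's fs.
#' @return An object of class `wavelet_decomposition`: list with `details`
#'   (list of N numeric vectors, padded length), `smooth`, `n` (original
#'   length), `pad_left`, `N`, `fs`, `wavelet`.
#' @export
mowt <- function(rec, N = n_levels(rec$fs)) {
  stopifnot(inherits(rec, "signal_record"))
  x <- rec$samples
  n <- length(x)
  Lf <- length(.sym4_dec_lo)
  if (n < Lf)
    stop("signal too short for the wavelet filter (need >= ", Lf, " samples)")
  # full reflection pad: [rev(x), x] gives a circularly smooth sequence
  xp <- c(rev(x), x)
  np <- length(xp)
  # level j uses an effective filter span of (2^(j-1))*(Lf-1)+1 samples
  N_max <- max(1L, floor(log2((np - 1) / (Lf - 1))) + 1L)
  if (N > N_max) {
    warning(sprintf("signal of %d samples supports at most %d levels; N clamped from %d",
                    n, N_max, N))
    N <- N_max
  }
  g <- .sym4_dec_lo / sqrt(2)
  h <- .sym4_dec_hi / sqrt(2)
  details <- vector("list", N)
  v <- xp
  for (j in seq_len(N)) {
    details[[j]] <- .circ_filt(v, h, j, dir = -1L)
    v <- .circ_filt(v, g, j, dir = -1L)
  }
  structure(
    list(details = details, smooth = v, n = n, pad_left = n, N = N,
         fs = rec$fs, wavelet = "sym4"),
    class = "wavelet_decomposition"
  )
}

#' @export
print.wavelet_decomposition <- function(x, ...) {
  cat(sprintf("<wavelet_decomposition> %s, %d levels, %d samples @ %g Hz\n",
              x$wavelet, x$N, x$n, x$fs))
  invisible(x)
}

#' Inverse MODWT restricted to chosen detail levels
#'
#' Runs the synthesis pyramid with every non-selected detail level and
#' (unless `include_smooth`) the smooth set to zero, then trims the
#' reflection padding. Selecting all levels plus the smooth reproduces the
#' original signal; the reconstruction is linear in the selected set.
#'
#' @param dec A `wavelet_decomposition` from [mowt()].
#' @param levels Integer vector of detail levels to keep (subset of `1:N`).
#' @param include_smooth Also include the level-N smooth (default `FALSE`:
#'   the smooth carries baseline wander and DC, which the detector discards).
#' @return Numeric vector of the original record length.
#' @export
reconstruct_selected <- function(dec, levels, include_smooth = FALSE) {
  stopifnot(inherits(dec, "wavelet_decomposition"))
  levels <- as.integer(levels)
  if (length(levels) && (any(levels < 1L) || any(levels > dec$N)))
    stop("levels must lie in 1..", dec$N)
  g <- .sym4_dec_lo / sqrt(2)
  h <- .sym4_dec_hi / sqrt(2)
  np <- length(dec$smooth)
  v <- if (include_smooth) dec$smooth else numeric(np)
  for (j in rev(seq_len(dec$N))) {
    w <- if (j %in% levels) dec$details[[j]] else numeric(np)
    v <- .circ_filt(w, h, j, dir = +1L) + .circ_filt(v, g, j, dir = +1L)
  }
  v[dec$pad_left + seq_len(dec$n)]
}

#' QRS-enhanced signal |cQRS|
#'
#' The heartbeat-enhancement stage: decompose the (preprocessed) record with
#' the MODWT, reconstruct using only the detail levels whose bands intersect
#' the QRS interval, and take the absolute value. The result is nonnegative,
#' invariant to DC offsets and baseline drift (which live in the discarded
#' smooth and coarse levels), and positively homogeneous in the input
#' amplitude.
#'
#' @param rec A [signal_record], already passed through [prepare_input()].
#' @param band QRS frequency interval in Hz, default `c(5, 20)`.
#' @return Numeric vector `|cQRS|`, same length as the record.
#' @export
enhance <- function(rec, band = c(5, 20)) {
  stopifnot(inherits(rec, "signal_record"))
  if (rec$fs < 2 * band[2])
    stop(sprintf("fs = %g Hz is below the minimum sampling rate %g Hz (Nyquist for the %g-%g Hz QRS band)",
                 rec$fs, 2 * band[2], band[1], band[2]))
  dec <- mowt(rec)
  sel <- select_levels(rec$fs, dec$N, band = band)
  abs(reconstruct_selected(dec, sel))
}
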