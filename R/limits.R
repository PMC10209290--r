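#' Analytic operating limits of the detector
#'
#' Derives the detector's design limits from its configuration rather than
#' hard-coding them:
#' \itemize{
#'   \item `min_fs_hz`: the minimum sampling rate, twice the upper edge of
#'     the QRS band (Nyquist) -- 40 Hz with the default 5-20 Hz band.
#'   \item `min_duration_s`: the shortest record giving a spectral
#'     resolution equal to the lower band edge, `1 / band[1]` -- 0.2 s.
#'   \item `single_beat_hr_bpm`: the heart rate at which that minimum record
#'     holds one full beat, `60 / min_duration_s` -- 300 BPM, i.e. already
#'     ventricular fibrillation, so in practice records must simply be
#'     longer than `min_duration_s`.
#'   \item `max_hr_bpm`: the fastest rhythm the minimum peak separation can
#'     follow, `60 / min_sep_s` -- 200 BPM.
#'   \item `min_beats_per_window`: beats guaranteed inside one online buffer
#'     at heart rate `hr_bpm`, `floor(window_s * hr_bpm / 60)` -- 5 beats at
#'     40 BPM with the default 7.5 s buffer.
#' }
#'
#' @param band QRS frequency interval in Hz.
#' @param min_sep_s Minimum peak separation in seconds.
#' @param window_s Online buffer length in seconds.
#' @param hr_bpm Heart rate used for the beats-per-window guarantee.
#' @return Named list with the five quantities above.
#' @export
#' @examples
#' design_limits()
design_limits <- function(band = c(5, 20), min_sep_s = 0.3,
                          window_s = 7.5, hr_bpm = 40) {
  min_duration_s <- 1 / band[1]
  list(
    min_fs_hz = 2 * band[2],
    min_duration_s = min_duration_s,
    single_beat_hr_bpm = 60 / min_duration_s,
    max_hr_bpm = 60 / min_sep_s,
    min_beats_per_window = floor(window_s * hr_bpm / 60)
  )
}
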