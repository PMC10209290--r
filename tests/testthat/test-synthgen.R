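test_that("generator configuration enforces its ranges", {
  expect_error(synth_config(fs = 30), ">= 40")
  expect_error(synth_config(hr_bpm = 20))
  expect_error(synth_config(noise_sd = -1))
})

test_that("beat times are deterministic, spaced and hit the target rate", {
  cfg <- synth_config(fs = 250, duration_s = 60, hr_bpm = 70, seed = 4)
  a <- beat_times(cfg)
  b <- beat_times(cfg)
  expect_identical(a$indices, b$indices)
  expect_true(all(diff(a$indices) >= round(0.3 * 250)))
  # 60 s at 70 BPM: close to 70 beats
  expect_lte(abs(length(a$indices) - 70), 2)

  # zero jitter -> perfectly periodic
  per <- beat_times(synth_config(fs = 250, duration_s = 30, hr_bpm = 60,
                                 hr_sd_s = 0, seed = 1))
  expect_true(all(diff(per$indices) == 250))

  # long-run mean interval converges on 60/hr (law of large numbers)
  lng <- beat_times(synth_config(fs = 100, duration_s = 9000, hr_bpm = 70,
                                 hr_sd_s = 0.02, seed = 8))
  expect_gt(length(lng$indices), 10000)
  expect_lt(abs(mean(diff(lng$indices)) / 100 - 60 / 70) / (60 / 70), 0.01)
})

test_that("clean ECG maxima coincide with the ground truth", {
  cfg <- synth_config(fs = 250, duration_s = 20, hr_bpm = 70, hr_sd_s = 0,
                      amp_cv = 0, noise_sd = 0, wander_amp = 0, seed = 2)
  sim <- synth_ecg(cfg)
  x <- sim$record$samples
  for (i in sim$annotations$indices) {
    win <- x[(i - 10):(i + 10) + 1L]
    expect_lte(abs(which.max(win) - 11L), 2L)
  }
})

test_that("same seed reproduces records exactly; amplitudes leave truth alone", {
  cfg <- synth_config(fs = 128, duration_s = 15, seed = 33)
  expect_identical(synth_ecg(cfg)$record$samples, synth_ecg(cfg)$record$samples)
  expect_identical(synth_ppg(cfg)$record$samples, synth_ppg(cfg)$record$samples)

  cfg2 <- synth_config(fs = 128, duration_s = 15, seed = 33, amp_cv = 0.2)
  expect_identical(synth_ecg(cfg)$annotations$indices,
                   synth_ecg(cfg2)$annotations$indices)
})

test_that("dPPG of a noise-free pulse train has one dominant lobe per beat", {
  cfg <- synth_config(fs = 128, duration_s = 20, hr_bpm = 70, noise_sd = 0,
                      wander_amp = 0, seed = 6)
  sim <- synth_ppg(cfg)
  d <- first_difference(sim$record)$samples
  idx <- sim$annotations$indices
  half <- round(0.15 * 128)
  for (k in seq_along(idx)) {
    i <- idx[k]
    lobe <- max(d[max(1, i - half):min(length(d), i + half) + 1L], na.rm = TRUE)
    # everything further than 150 ms from any beat stays well below the lobe
    far <- rep(TRUE, length(d))
    for (j in idx) far[max(1, j - half):min(length(d), j + half) + 1L] <- FALSE
    expect_gt(lobe, 3 * max(d[far]))
    break  # the far mask is beat-independent; one global check suffices
  }
  # per-beat: the steepest ascent lies at the annotated sample (+-2)
  for (i in idx) {
    win <- d[(i - 8):(i + 8) + 1L]
    expect_lte(abs(which.max(win) - 9L), 2L)
  }
})

test_that("generator RNG use does not disturb the session RNG", {
  set.seed(99)
  before <- .Random.seed
  invisible(synth_ecg(synth_config(duration_s = 5, seed = 1)))
  expect_identical(.Random.seed, before)
})
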