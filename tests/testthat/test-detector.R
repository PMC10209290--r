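test_that("local maxima follow the strict-neighbour rule with plateaus", {
  lm <- local_maxima(c(0, 1, 0, 2, 0), fs = 100)
  expect_equal(lm$P, c(1, 2))
  expect_equal(lm$L, c(1L, 3L))
  expect_equal(length(local_maxima(0:5, fs = 100)$P), 0L)       # monotone
  plateau <- local_maxima(c(0, 1, 1, 0), fs = 100)
  expect_equal(plateau$P, 1)
  expect_equal(plateau$L, 1L)                                    # first of run
  expect_equal(length(local_maxima(c(1, 2), fs = 100)$P), 0L)    # too short
  # endpoints never qualify
  ends <- local_maxima(c(5, 1, 1, 5), fs = 100)
  expect_equal(length(ends$P), 0L)
})

test_that("greedy minimum-separation selection matches the worked example", {
  pk <- local_maxima(c(0, 0, 0), fs = 1000)  # empty in -> empty out
  expect_equal(length(min_separation_select(pk)$P), 0L)

  ps <- webeat:::peak_set(c(1.0, 0.5, 0.8), c(100L, 250L, 600L), fs = 1000)
  out <- min_separation_select(ps, 0.3)
  expect_equal(out$P, c(1.0, 0.8))
  expect_equal(out$L, c(100L, 600L))

  single <- webeat:::peak_set(2, 50L, fs = 1000)
  expect_equal(min_separation_select(single)$L, 50L)

  ties <- webeat:::peak_set(c(1, 1), c(100L, 200L), fs = 1000)
  expect_equal(min_separation_select(ties, 0.3)$L, 100L)  # earlier wins
})

test_that("greedy selection agrees with the reference on random instances", {
  set.seed(123)
  for (trial in 1:300) {
    n <- sample(1:15, 1)
    L <- sort(sample(0:3000, n))
    P <- round(runif(n), 3)           # rounding forces occasional ties
    fs <- sample(c(100, 250, 1000), 1)
    ref <- oracle_min_sep(P, L, fs)
    got <- min_separation_select(webeat:::peak_set(P, L, fs))
    expect_equal(got$P, ref$P)
    expect_equal(got$L, as.integer(ref$L))
    if (length(got$L) > 1)
      expect_true(all(diff(got$L) >= round(0.3 * fs)))
  }
})

test_that("candidate augmentation matches a step-by-step reference", {
  set.seed(31)
  fs <- 100
  siglen <- 1200L
  L <- sort(sample(5:1194, 20))
  P <- runif(20, 0.1, 0.3)
  P[seq(2, 20, by = 4)] <- runif(5, 0.8, 1.2)   # 5 tall peaks
  pa <- webeat:::peak_set(P, L, fs)
  pc <- min_separation_select(pa, 0.3)
  got <- augment_candidates(pa, pc, siglen)
  ref <- oracle_augment(pa$P, pa$L, pc$P, pc$L, fs, siglen)
  expect_equal(got$aux$P, ref$aux$P)
  expect_equal(got$aux$L, as.integer(ref$aux$L))
  expect_equal(got$pms$L, as.integer(ref$pms$L))
  expect_equal(got$pms_last$L, as.integer(ref$pms_last$L))
})

test_that("augmentation degrades gracefully when nothing remains", {
  pa <- webeat:::peak_set(c(1, 2, 1.5), c(10L, 200L, 390L), fs = 100)
  pc <- pa   # everything already selected
  expect_warning(out <- augment_candidates(pa, pc, 500L), "fewer than 2")
  expect_equal(out$aux$L, pa$L)
  expect_equal(length(out$pms$P), 0L)
  expect_error(augment_candidates(pc, webeat:::peak_set(5, 77L, 100), 500L),
               "subset")
})

test_that("envelopes pass through their anchors and average pointwise", {
  fs <- 100
  pc <- webeat:::peak_set(c(1, 3, 1, 3, 1), c(0L, 100L, 200L, 300L, 400L), fs)
  env <- build_envelopes(pc, pc, 401L)
  # anchors are the magnitude-sequence maxima: the two 3s
  expect_equal(env$env_c[c(101L, 301L)], c(3, 3), tolerance = 1e-9)
  expect_equal(env$env_ms, env$env_c)
  expect_equal(env$mean_env, (env$env_c + env$env_ms) / 2)

  # shape preservation: no overshoot between monotone anchors
  set.seed(9)
  mono <- sort(runif(8, 1, 5))
  pm <- webeat:::peak_set(as.numeric(rbind(0.1, mono))[-1],
                          as.integer(seq(0, 1400, by = 100))[1:15], fs)
  e2 <- build_envelopes(pm, pm, 1500L)
  anchors <- local_maxima(pm$P, fs)
  span <- (pm$L[anchors$L[1] + 1]):(pm$L[anchors$L[length(anchors$L)] + 1])
  expect_true(all(diff(e2$env_c[span + 1L]) >= -1e-9))

  # degenerate input: constant envelope at the largest magnitude
  few <- webeat:::peak_set(c(2, 5), c(10L, 50L), fs)
  expect_message(env3 <- build_envelopes(few, few, 100L), "constant")
  expect_true(all(env3$env_c == 5))
})

test_that("classification keeps exactly the peaks above the mean envelope", {
  fs <- 100
  pc <- webeat:::peak_set(c(0.5, 1, 2), c(10L, 60L, 120L), fs)
  zero_env <- structure(list(env_c = rep(0, 200), env_ms = rep(0, 200),
                             mean_env = rep(0, 200)), class = "envelope_set")
  expect_equal(classify_beats(pc, zero_env)$indices, c(10L, 60L, 120L))
  hi <- structure(list(env_c = rep(2, 200), env_ms = rep(2, 200),
                       mean_env = rep(2, 200)), class = "envelope_set")
  expect_equal(length(classify_beats(pc, hi)), 0L)  # strict inequality
})

test_that("detection is invariant to amplitude scale and DC offset", {
  sim <- fixture_ecg(duration_s = 20)
  rec <- sim$record
  base <- detect(rec)
  expect_gt(length(base), 15)
  for (a in c(0.01, 13)) {
    got <- detect(signal_record(a * rec$samples, fs = rec$fs))
    expect_equal(got$indices, base$indices, info = paste("scale", a))
  }
  shifted <- detect(signal_record(rec$samples - 42, fs = rec$fs))
  expect_equal(shifted$indices, base$indices)
})

test_that("detected beats always respect the minimum separation", {
  for (sim in list(fixture_ecg(duration_s = 20),
                   fixture_ppg(duration_s = 20),
                   fixture_ecg(fs = 128, duration_s = 20, hr_bpm = 180,
                               seed = 77))) {
    beats <- detect(sim$record)
    if (length(beats) > 1)
      expect_true(all(diff(beats$indices) >= round(0.3 * sim$record$fs)))
  }
})

test_that("detection recovers the ground truth on clean fixtures", {
  for (mk in list(fixture_ecg, fixture_ppg)) {
    sim <- mk(duration_s = 60)
    m <- evaluate_detection(detect(sim$record), sim$annotations)
    expect_gte(m$tpr, 99)
    expect_gte(m$ppv, 99)
  }
})

test_that("degenerate inputs fail loudly or return no beats", {
  expect_equal(length(detect(signal_record(rep(0, 2000), fs = 128))), 0L)
  expect_error(detect(signal_record(c(0, 1, 0), fs = 128, modality = "dppg")),
               "modality")
  expect_error(detect(signal_record(rnorm(1000), fs = 30)), "sampling rate")
})
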