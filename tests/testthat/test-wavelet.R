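test_that("decomposition depth follows floor(log2(fs))", {
  expect_equal(n_levels(128), 7L)
  expect_equal(n_levels(250), 7L)
  expect_equal(n_levels(360), 8L)
  expect_error(n_levels(1.5), ">= 2")
})

test_that("dyadic level bands nest and QRS-band selection is correct", {
  expect_equal(level_band(128, 3), c(8, 16))
  expect_equal(level_band(360, 4), c(11.25, 22.5))
  for (j in 2:6)
    expect_equal(level_band(500, j)[2], level_band(500, j - 1)[1])

  expect_equal(select_levels(128, 7), c(2L, 3L, 4L))
  expect_equal(select_levels(360, 8), c(4L, 5L, 6L))
  expect_equal(select_levels(256, 8), c(3L, 4L, 5L))
  expect_error(select_levels(30, n_levels(30)), "minimum supported sampling rate")
})

test_that("selected levels always form a contiguous run", {
  for (fs in c(40, 64, 100, 128, 200, 250, 256, 360, 500, 1000)) {
    sel <- select_levels(fs, n_levels(fs))
    expect_equal(sel, seq(min(sel), max(sel)), info = paste("fs =", fs))
  }
})

test_that("the transform is exactly invertible and linear", {
  set.seed(42)
  x <- rnorm(700)
  rec <- signal_record(x, fs = 128)
  dec <- mowt(rec)
  # completeness: all details + smooth reproduce the input
  full <- reconstruct_selected(dec, 1:dec$N, include_smooth = TRUE)
  expect_lt(max(abs(full - x)) / max(abs(x)), 1e-8)
  # zero signal -> zero components
  dec0 <- mowt(signal_record(rep(0, 1000), fs = 128))
  expect_true(all(vapply(dec0$details, function(d) all(d == 0), logical(1))))
  # additivity over disjoint level sets
  a <- reconstruct_selected(dec, c(2L, 3L))
  b <- reconstruct_selected(dec, 5L)
  ab <- reconstruct_selected(dec, c(2L, 3L, 5L))
  expect_lt(max(abs(ab - (a + b))) / max(abs(ab)), 1e-8)
  # empty selection
  expect_true(all(reconstruct_selected(dec, integer(0)) == 0))
  expect_error(reconstruct_selected(dec, 99L), "levels")
})

test_that("a 10 Hz tone at fs=128 concentrates in the level covering 10 Hz", {
  rec <- signal_record(sin(2 * pi * 10 * (0:1279) / 128), fs = 128)
  dec <- mowt(rec)
  energy <- vapply(seq_len(dec$N),
                   function(j) sum(reconstruct_selected(dec, j)^2), numeric(1))
  frac <- energy / sum(energy)
  expect_equal(which.max(frac), 3L)   # level 3 band is (8, 16) Hz
  expect_gt(frac[3], 0.9)
})

test_that("depth is clamped with a warning on short records", {
  expect_warning(dec <- mowt(signal_record(rnorm(64), fs = 500)), "clamped")
  expect_lt(dec$N, n_levels(500))
  expect_error(mowt(signal_record(rnorm(4), fs = 500)), "too short")
})

test_that("|cQRS| is nonnegative, homogeneous and offset-invariant", {
  sim <- fixture_ecg(duration_s = 10)
  rec <- sim$record
  e <- enhance(rec)
  expect_true(all(e >= 0))
  expect_equal(length(e), length(rec))

  a <- 2.9
  e_scaled <- enhance(signal_record(a * rec$samples, fs = rec$fs))
  expect_equal(e_scaled, a * e, tolerance = 1e-9)

  e_shift <- enhance(signal_record(rec$samples + 57, fs = rec$fs))
  expect_lt(max(abs(e_shift - e)) / max(e), 1e-6)

  expect_true(all(enhance(signal_record(rep(0, 1000), fs = 128)) < 1e-12))
  expect_error(enhance(signal_record(rnorm(100), fs = 30)), "minimum sampling rate")
})

test_that("enhancement raises spike-to-background energy contrast", {
  # QRS-like spike train over strong 0.3 Hz wander
  fs <- 128
  t <- (0:(20 * fs - 1)) / fs
  spikes <- numeric(length(t))
  centres <- seq(1, 19, by = 0.8)
  for (ck in centres) {
    u <- (t - ck) / 0.015
    spikes <- spikes + (1 - u^2) * exp(-u^2 / 2)
  }
  set.seed(7)
  x <- spikes + 2 * sin(2 * pi * 0.3 * t) + rnorm(length(t), sd = 0.03)
  near <- Reduce(`|`, lapply(centres, function(ck) abs(t - ck) < 0.05))
  contrast <- function(v) sum(v[near]^2) / sum(v[!near]^2)
  e <- enhance(signal_record(x, fs = fs))
  expect_gt(contrast(e), contrast(x))
})
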