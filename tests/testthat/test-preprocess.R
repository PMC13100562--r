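# Modality preprocessing: QA, interpolation, filtering, downsampling,
# z-transform, gaze exclusion, heart period, respiration amplitude.

scr_rec <- function(values, fs = 10) {
  recording("p1", "s1", "SCR", fs, values)
}

test_that("SCR QA flags range and slope violations with reason codes", {
  # constant in-range trace: clean
  mask <- detect_scr_artifacts(scr_rec(rep(10, 100)))
  expect_false(any(mask$flag))

  # one 70 uS sample: flagged as range
  x <- rep(10, 100); x[50] <- 70
  mask <- detect_scr_artifacts(scr_rec(x))
  expect_true(mask$flag[50])
  expect_match(mask$reason[50], "range")

  # a ramp rising 0.02 uS per 1000 Hz sample = 20 uS/s: flagged as slope
  ramp <- c(rep(5, 20), 5 + cumsum(rep(0.02, 30)), rep(5.6, 20))
  mask <- detect_scr_artifacts(scr_rec(ramp, fs = 1000))
  mid <- 25:45  # interior of the ramp, central-difference slope = 20
  expect_true(all(mask$flag[mid]))
  expect_true(all(mask$reason[mid] == "slope"))
  expect_false(any(mask$flag[1:18]))

  # sub-threshold slope (9.9 uS/s) is retained
  ramp99 <- 5 + cumsum(rep(0.0099, 50))
  expect_false(any(detect_scr_artifacts(scr_rec(ramp99, fs = 1000))$flag))

  expect_error(detect_scr_artifacts(recording("p", "s", "PSR", 10, 1:10)),
               "SCR")
})

test_that("masked spans interpolate linearly and stay excluded", {
  # single flagged sample between 1 and 3 -> 2
  r <- scr_rec(c(1, 99, 3))
  out <- interpolate_masked(r, c(FALSE, TRUE, FALSE))
  expect_equal(out$values, c(1, 2, 3))
  expect_equal(out$missing, c(FALSE, TRUE, FALSE))

  # 3-sample flagged span between 0 and 4 -> 1, 2, 3
  r <- scr_rec(c(0, 9, 9, 9, 4))
  out <- interpolate_masked(r, c(FALSE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(out$values, c(0, 1, 2, 3, 4))

  # edge spans hold the nearest valid value
  r <- scr_rec(c(9, 9, 2, 3))
  out <- interpolate_masked(r, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(out$values, c(2, 2, 2, 3))

  # no flags: identity
  r <- scr_rec(c(1, 2, 3))
  expect_equal(interpolate_masked(r, rep(FALSE, 3))$values, c(1, 2, 3))

  expect_error(interpolate_masked(r, rep(TRUE, 3)), "all samples")
})

test_that("bidirectional Butterworth is unity at DC and -6 dB at cutoff", {
  fs <- 100; fc <- 5
  # constant passes unchanged
  const <- recording("p", "s", "SCR", fs, rep(3.7, 500))
  expect_equal(lowpass_bidirectional(const, fc)$values, rep(3.7, 500),
               tolerance = 1e-6)
  # cutoff-frequency tone attenuated to amplitude 0.5
  t <- seq(0, 60, by = 1 / fs)
  tone <- recording("p", "s", "SCR", fs, sin(2 * pi * fc * t))
  y <- lowpass_bidirectional(tone, fc)$values
  mid <- y[(20 * fs):(40 * fs)]
  expect_equal((max(mid) - min(mid)) / 2, 0.5, tolerance = 0.02)
  # zero phase: symmetric pulse keeps its peak position
  pulse <- exp(-((seq_len(1001) - 501) / 40)^2)
  pr <- recording("p", "s", "SCR", fs, pulse)
  expect_equal(which.max(lowpass_bidirectional(pr, fc)$values), 501)
  expect_error(lowpass_bidirectional(const, 50), "Nyquist")
})

test_that("downsampling averages 0.1-s bins and propagates the mask", {
  r <- recording("p", "s", "SCR", 1000, rep(2.5, 60000))
  d <- downsample(r)
  expect_equal(d$fs_hz, 10)
  expect_equal(length(d$values), 600)
  expect_equal(unique(d$values), 2.5)

  # one masked source sample -> exactly one masked 10 Hz bin
  r$missing[777] <- TRUE
  d <- downsample(r)
  expect_equal(sum(d$missing), 1)
  expect_true(d$missing[8])  # sample 777 falls in bin 8

  expect_error(downsample(recording("p", "s", "SCR", 5, 1:10)), "target")
})

test_that("session z-transform standardises over valid samples", {
  r <- scr_rec(c(1, 2, 3))
  expect_equal(zscore_session(r)$values, c(-1, 0, 1))

  # affine invariance
  x <- rnorm(50)
  r1 <- zscore_session(scr_rec(x))$values
  r2 <- zscore_session(scr_rec(3 * x + 7))$values
  expect_equal(r1, r2, tolerance = 1e-12)

  # masked samples excluded from the statistics
  x <- c(1, 2, 3, 1000)
  r <- scr_rec(x); r$missing <- c(FALSE, FALSE, FALSE, TRUE)
  z <- zscore_session(r)$values
  expect_equal(z[1:3], (x[1:3] - 2) / sd(x[1:3]))

  expect_error(zscore_session(scr_rec(rep(5, 10))), "variance")
})

test_that("gaze deviation beyond 5 degrees masks pupil samples", {
  dist <- 70
  offs <- c(0, dist * tan(5 * pi / 180), dist * tan(6 * pi / 180))
  pupil <- recording("p", "s", "PSR", 10, rep(4, 3))
  gx <- recording("p", "s", "GAZE_X", 10, offs)
  gy <- recording("p", "s", "GAZE_Y", 10, rep(0, 3))
  out <- exclude_gaze_deviation(pupil, gx, gy, c(0, 0),
                                geometry = list(viewing_distance_cm = dist))
  # fixation kept, exactly 5 degrees kept (non-strict), 6 degrees masked
  expect_equal(out$missing, c(FALSE, FALSE, TRUE))
  expect_error(exclude_gaze_deviation(pupil, gx, gy, c(0, 0),
                                      geometry = list()), "viewing_distance")
})

test_that("heart period is interpolated with validity filtering", {
  # regular 1 Hz beats give a constant 1.0 s series
  hp <- heartbeats_to_heart_period(0:4)
  expect_equal(unique(round(hp$values, 10)), 1.0)
  expect_equal(hp$fs_hz, 10)

  # one 1.6 s interval removed; the series stays near 1.0
  beats <- c(0, 1, 2, 3.6, 4.6, 5.6)
  hp <- heartbeats_to_heart_period(beats)
  expect_lt(max(abs(hp$values - 1.0)), 1e-9)

  # alternating 0.8/1.0 intervals stay within [0.8, 1.0]
  beats <- cumsum(c(0, rep(c(0.8, 1.0), 10)))
  hp <- heartbeats_to_heart_period(beats)
  expect_gte(min(hp$values), 0.8 - 1e-9)
  expect_lte(max(hp$values), 1.0 + 1e-9)

  expect_error(heartbeats_to_heart_period(c(0, 1)), "3 beats")
  expect_error(heartbeats_to_heart_period(c(0, 2, 4)), "valid range")
})

test_that("respiration cycles become a peak-to-trough amplitude series", {
  fs <- 50
  t <- seq(0, 30, by = 1 / fs)
  # pure sinusoid of amplitude a: cycle amplitude 2a
  a <- 0.7
  r <- recording("p", "s", "RAR", fs, a * sin(2 * pi * 0.25 * t))
  ra <- respiration_to_amplitude(r)
  expect_equal(ra$fs_hz, 10)
  core <- ra$values[ra$values > 0]
  expect_equal(stats::median(core), 2 * a, tolerance = 0.02)

  # constant signal has no cycles
  expect_error(respiration_to_amplitude(recording("p", "s", "RAR", fs,
                                                  rep(1, 100))), "cycle")

  # two cycles with amplitudes 1 and 2: interpolation spans [1, 2] monotonically
  x <- c(0, 1, 0, 0, 2, 0)   # troughs at 0, peaks 1 then 2
  r2 <- recording("p", "s", "RAR", 1, x)
  ra2 <- respiration_to_amplitude(r2, fs_out = 1)
  seg <- ra2$values[ra2$values >= 1 & ra2$values <= 2]
  expect_true(all(diff(seg) >= 0))
  expect_equal(range(seg), c(1, 2))
})

test_that("SCR pipeline enforces stage order and refuses re-processing", {
  set.seed(1)
  raw <- scr_rec(2 + 0.3 * sin(seq(0, 20, length.out = 2000)) +
                   rnorm(2000, 0, 0.01), fs = 100)
  out <- preprocess_scr(raw)
  expect_equal(out$fs_hz, 10)
  expect_equal(mean(out$values[!out$missing]), 0, tolerance = 1e-9)
  expect_equal(sd(out$values[!out$missing]), 1, tolerance = 1e-9)
  expect_error(preprocess_scr(out), "already preprocessed")
  expect_true(!is.null(attr(out, "log")))
})

test_that("masked 10 Hz bins grow with injected artifact duration", {
  base <- rep(10, 3000)
  n_masked <- sapply(c(0, 100, 300, 600), function(len) {
    x <- base
    if (len > 0) x[1001:(1000 + len)] <- 70
    rec <- preprocess_scr(recording("p", "s", "SCR", 100, x), zscore = FALSE)
    sum(rec$missing)
  })
  expect_true(all(diff(n_masked) > 0))
})

test_that("a low tone survives filter + downsample within 5%", {
  fs <- 100
  t <- seq(0, 120, by = 1 / fs)
  tone <- recording("p", "s", "SCR", fs, sin(2 * pi * 0.5 * t))
  out <- downsample(lowpass_bidirectional(tone, 5))
  mid <- out$values[200:1000]
  expect_equal((max(mid) - min(mid)) / 2, 1, tolerance = 0.05)
})
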