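# Trial schedules, response kernels and the recording generator.

test_that("schedules have exact outcome counts, ordering and US timing", {
  sched <- generate_schedule(dataset2_design(n_participants = 4), seed = 11)

  # exact reinforcement per condition and participant
  for (p in unique(sched$participant_id)) {
    s <- sched[sched$participant_id == p, ]
    counts <- table(s$cs_label, s$outcome)
    expect_equal(unname(counts["CS+20", "US+"]), 5)   # round(0.2 * 23)
    expect_equal(unname(counts["CS+50", "US+"]), 11)  # round(0.5 * 22)
    expect_equal(unname(counts["CS+80", "US+"]), 18)  # round(0.8 * 23)
    # trials time-ordered and non-overlapping
    expect_true(all(diff(s$cs_onset_s) > 0))
    expect_true(all(s$cs_onset_s[-1] >=
                      (s$cs_onset_s + 6.5)[-nrow(s)]))
  }
  # US onset 6 s after CS onset on every trial, delivered or omitted
  expect_equal(unique(sched$us_onset_s - sched$cs_onset_s), 6.0)

  # 50% over an even trial count splits exactly
  d <- design_spec(1, list(cs_condition("CS+", 0.5, 32)), 4, 3.5)
  s32 <- generate_schedule(d, seed = 3)
  expect_equal(sum(s32$outcome == "US+"), 16)
  expect_equal(sum(s32$outcome == "US-"), 16)
})

test_that("tie rounding of reinforced counts goes toward more US+", {
  # 0.5 * 5 = 2.5 -> 3 reinforced
  d <- design_spec(1, list(cs_condition("CS+", 0.5, 5)), 4, 3.5)
  s <- generate_schedule(d, seed = 1)
  expect_equal(sum(s$outcome == "US+"), 3)
})

test_that("ITIs are uniform on the configured range", {
  d <- design_spec(50, list(cs_condition("CS+", 0.5, 40)), 4, 3.5)
  sched <- generate_schedule(d, seed = 7)
  iti <- sched$iti_s  # 2000 draws
  expect_gte(min(iti), 7)
  expect_lte(max(iti), 11)
  # mean of U(7,11) is 9, SE = (4 / sqrt(12)) / sqrt(n)
  se <- (4 / sqrt(12)) / sqrt(length(iti))
  expect_lt(abs(mean(iti) - 9), 3 * se)
})

test_that("schedules and recordings are reproducible under a fixed seed", {
  d <- dataset1_design(n_participants = 2, n_trials = 6)
  s1 <- generate_schedule(d, seed = 42)
  s2 <- generate_schedule(d, seed = 42)
  expect_identical(s1, s2)
  params <- gen_params(
    amplitude_maps = list(SCR = amplitude_map_observed(c(0, 0.5))),
    noise_sd = c(SCR = 0.05))
  r1 <- generate_recordings(s1, params, seed = 9)
  r2 <- generate_recordings(s2, params, seed = 9)
  expect_identical(r1, r2)
})

test_that("invalid designs are rejected", {
  expect_error(design_spec(2, list(cs_condition("CS+", 0.5, 10)),
                           cs_duration_s = 4, us_onset_s = 5),
               "precede")
  expect_error(cs_condition("CS+", 1.2, 10), "\\[0, 1\\]")
  expect_error(cs_condition("CS+", 0.5, 0), "positive")
})

test_that("kernels are peak-normalised, causal and decaying", {
  for (m in c("SCR", "PSR", "RAR")) {
    kp <- default_kernel_params(m)
    expect_equal(canonical_kernel(m, kp$latency_s), 1.0)
    expect_lte(canonical_kernel(m, 0), 0.01)
    expect_lt(canonical_kernel(m, 60), 1e-3)
    tg <- seq(0, 20, by = 0.001)
    k <- canonical_kernel(m, tg)
    expect_true(all(k >= 0))
    # numeric argmax matches the latency parameter to within one grid step
    expect_lt(abs(tg[which.max(k)] - kp$latency_s), 0.0015)
  }
  # heart-period kernel is biphasic: crosses zero, max |k| = 1
  tg <- seq(0, 25, by = 0.01)
  kh <- canonical_kernel("HPR", tg)
  expect_true(any(kh > 0) && any(kh < 0))
  expect_equal(max(abs(kh)), 1, tolerance = 1e-6)
  expect_error(canonical_kernel("SCR", 1, list(latency_s = 3, dispersion_s = -1)),
               "dispersion")
})

test_that("noiseless recordings equal baseline plus amplitude-scaled kernel", {
  d <- design_spec(1, list(cs_condition("CS+", 1, 1)), 4, 3.5, fs_hz = 100)
  sched <- generate_schedule(d, seed = 1)
  params <- gen_params(
    amplitude_maps = list(SCR = tibble::tibble(outcome = "US+", rate = 1,
                                               amplitude = 0.7)),
    between_subject_sd = 0, noise_sd = c(SCR = 0),
    baseline_level = c(SCR = 2))
  rec <- generate_recordings(sched, params, seed = 1)[[1]]
  t <- pephys:::rec_times(rec)
  expected <- 2 + 0.7 * canonical_kernel("SCR", pmax(t - sched$us_onset_s[1], 0))
  expect_equal(rec$values, expected, tolerance = 1e-10)
})

test_that("generator is linear: doubling amplitude doubles the evoked mean", {
  d <- design_spec(1, list(cs_condition("CS+", 1, 4)), 4, 3.5, fs_hz = 50)
  sched <- generate_schedule(d, seed = 2)
  mk <- function(a) {
    p <- gen_params(amplitude_maps = list(
      SCR = tibble::tibble(outcome = "US+", rate = 1, amplitude = a)),
      between_subject_sd = 0, noise_sd = c(SCR = 0),
      baseline_level = c(SCR = 0))
    generate_recordings(sched, p, seed = 3)[[1]]$values
  }
  expect_equal(mk(1.6), 2 * mk(0.8), tolerance = 1e-10)
})

test_that("US+/US- amplitude ratio survives averaging at realistic n", {
  d <- design_spec(29, list(cs_condition("CS+", 0.5, 20)), 6.5, 6, fs_hz = 20)
  sched <- generate_schedule(d, seed = 5)
  params <- gen_params(
    amplitude_maps = list(SCR = tibble::tibble(
      outcome = c("US+", "US-"), rate = 0.5, amplitude = c(1.2, 1.0))),
    between_subject_sd = 0.2, noise_sd = c(SCR = 0.05),
    baseline_level = c(SCR = 0))
  recs <- generate_recordings(sched, params, seed = 6)
  # mean single-trial value at the kernel peak, per outcome, across everyone
  peak_of <- function(outcome) {
    vals <- unlist(lapply(unique(sched$participant_id), function(p) {
      rec <- recs[[paste0(p, "_SCR")]]
      tr <- sched[sched$participant_id == p & sched$outcome == outcome, ]
      sapply(tr$us_onset_s, function(us) {
        rec$values[round((us + 3) * rec$fs_hz) + 1]
      })
    }))
    mean(vals)
  }
  expect_equal(peak_of("US+") / peak_of("US-"), 1.2, tolerance = 0.05)
})

test_that("injected plateau artifacts are flagged by the SCR QA", {
  d <- design_spec(1, list(cs_condition("CS+", 1, 2)), 4, 3.5, fs_hz = 100)
  sched <- generate_schedule(d, seed = 4)
  params <- gen_params(
    amplitude_maps = list(SCR = tibble::tibble(outcome = "US+", rate = 1,
                                               amplitude = 0.5)),
    between_subject_sd = 0, noise_sd = c(SCR = 0),
    baseline_level = c(SCR = 2),
    artifacts = tibble::tibble(participant_id = "p001", modality = "SCR",
                               start_s = 5, end_s = 6, value = 70))
  rec <- generate_recordings(sched, params, seed = 4)[[1]]
  mask <- detect_scr_artifacts(rec)
  t <- pephys:::rec_times(rec)
  inside <- t >= 5.01 & t < 5.99
  expect_true(all(mask$flag[inside]))
  expect_true(all(grepl("range", mask$reason[inside])))
  # and nothing far from the plateau is flagged
  expect_false(any(mask$flag[t > 8 | t < 4.9]))
})
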