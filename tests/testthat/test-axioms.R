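# Axiomatic evaluation: directions, signed consistency, unsigned conditions.

test_that("cluster signs map onto direction labels", {
  mk <- function(signs, masses, ps) {
    tibble::tibble(start_bin = seq_along(signs), end_bin = seq_along(signs),
                   start_s = 0, end_s = 0, sign = signs, mass = masses,
                   n_bins = 1L, p_cluster = ps)
  }
  expect_equal(direction_of(mk("+", 10, 0.01)), "a_greater")
  expect_equal(direction_of(mk("-", -10, 0.01)), "b_greater")
  expect_equal(direction_of(mk(c("+", "-"), c(10, -5), c(0.01, 0.02))),
               "mixed")
  expect_equal(direction_of(mk(c("+", "-"), c(10, -5), c(0.01, 0.02)),
                            policy = "dominant"), "a_greater")
  expect_equal(direction_of(mk("+", 10, 0.2)), "null")
  expect_equal(direction_of(NULL), "null")
})

test_that("signed verdicts follow the ordering logic of the axioms", {
  # observed empirical pattern: omission response in the SAME direction as
  # the US response -> incompatible with signed PE
  expect_equal(evaluate_signed("a_greater", c(a2 = "b_greater")),
               "inconsistent")
  # a true signed-PE pattern: all contrasts ordered with the lower rate
  # (higher PE) larger
  expect_equal(evaluate_signed("a_greater",
                               c("a_greater", "a_greater", "null")),
               "consistent")
  # mirrored code (US response is a signal decrease)
  expect_equal(evaluate_signed("b_greater", c("b_greater", "b_greater")),
               "consistent")
  expect_equal(evaluate_signed("null", c("a_greater")), "indeterminate")
  expect_equal(evaluate_signed("a_greater", c("null", "null")),
               "indeterminate")
  expect_equal(evaluate_signed("mixed", c("a_greater")), "inconsistent")
  expect_equal(evaluate_signed("a_greater", c("mixed")), "inconsistent")
})

test_that("the evaluator is total and mirror-symmetric over all directions", {
  dirs <- c("a_greater", "b_greater", "mixed", "null")
  flip <- function(d) pephys:::flip_direction(d)
  verdicts <- c("consistent", "inconsistent", "indeterminate")
  # exhaustive truth table: one A1 x three A2 contrasts
  grid <- expand.grid(a1 = dirs, x = dirs, y = dirs, z = dirs,
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    a2 <- c(grid$x[i], grid$y[i], grid$z[i])
    v <- evaluate_signed(grid$a1[i], a2)
    expect_true(v %in% verdicts)
    expect_identical(evaluate_signed(flip(grid$a1[i]), flip(a2)), v)
  }
})

test_that("unsigned conditions match their defining patterns", {
  # all probability contrasts null: C3 indeterminate, C1 needs 20/80
  oc <- make_outcomes_ds2(a1 = c("a_greater", "a_greater", "a_greater"),
                          a2 = rep("null", 6))
  u <- evaluate_unsigned(oc)
  expect_equal(unname(u["c3"]), "indeterminate")
  # 50% US-vs-omission contrast significant: C2 violated
  expect_equal(unname(u["c2"]), "violated")
  # US+ > US- at every rate including 80%: C1 violated
  expect_equal(unname(u["c1"]), "violated")

  # constructed fully surprise-consistent pattern:
  # US+ > US- at 20%, null at 50%, US- > US+ at 80%,
  # US+ maximal at 20% and US- maximal at 80%
  oc2 <- make_outcomes_ds2(a1 = c("a_greater", "null", "b_greater"),
                           a2 = c("a_greater", "a_greater", "a_greater",
                                  "b_greater", "b_greater", "b_greater"))
  u2 <- evaluate_unsigned(oc2)
  expect_equal(unname(u2), c("satisfied", "satisfied", "satisfied"))

  # inverted-sign modality (heart period): same logic after sign flip
  oc3 <- make_outcomes_ds2(a1 = c("b_greater", "null", "a_greater"),
                           a2 = c("b_greater", "b_greater", "b_greater",
                                  "a_greater", "a_greater", "a_greater"))
  u3 <- evaluate_unsigned(oc3, response_sign = -1)
  expect_equal(unname(u3), c("satisfied", "satisfied", "satisfied"))
})

test_that("full verdicts combine signed and unsigned flags", {
  # empirical pattern: strong US response at all rates, null probability
  # contrasts
  oc <- make_outcomes_ds2()
  v <- evaluate_axioms(oc, modality = "SCR")
  expect_s3_class(v, "axiom_verdict")
  expect_equal(v$a1_direction, "a_greater")
  expect_equal(v$signed_consistent, "indeterminate")  # all A2 null
  expect_equal(v$a3, "not testable")
  expect_equal(v$c4, "not testable")
  expect_output(print(v), "signed PE")

  # differential-design pattern: omission response same sign as US response
  oc1 <- tibble::tibble(
    name = c("A1", "A2"), type = c("A1", "A2"),
    rate = c(0.5, NA), outcome = c(NA, "US-"),
    rate_a = c(NA, 0.0), rate_b = c(NA, 0.5),
    direction = c("a_greater", "b_greater"), n_sig_clusters = 1L)
  v1 <- evaluate_axioms(oc1, modality = "SCR")
  expect_equal(v1$signed_consistent, "inconsistent")
  expect_equal(v1$c2, "violated")
})

test_that("end-to-end: generative amplitude maps drive the verdict", {
  # small parametric-design simulation; the amplitude map is the only
  # difference between the two runs
  run_with <- function(scheme) {
    design <- dataset2_design(n_participants = 8, n_trials = c(15, 14, 15),
                              fs_hz = 20)
    sched <- generate_schedule(design, seed = 101)
    map <- if (scheme == "signed") {
      amplitude_map_signed_pe(c(0.2, 0.5, 0.8), gain = 1.5)
    } else {
      amplitude_map_observed(c(0.2, 0.5, 0.8), us_amp = 1.5,
                             omission_gain = 1.2)
    }
    params <- gen_params(amplitude_maps = list(SCR = map),
                         between_subject_sd = 0.1,
                         within_subject_sd = c(SCR = 0.15),
                         noise_sd = c(SCR = 0.02))
    recs <- generate_recordings(sched, params, seed = 102)
    ems <- lapply(Filter(function(x) x$modality == "SCR", recs), function(r) {
      extract_epochs(preprocess_scr(r), sched, epoch_window("SCR"))
    })
    em <- baseline_correct(pephys:::bind_epochs(ems))
    tests <- lapply(table_contrasts(2), function(con) {
      cluster_test(em, con, n_perm = 200, seed = 103)
    })
    evaluate_axioms(contrast_outcomes(tests), modality = "SCR")
  }
  expect_equal(run_with("signed")$signed_consistent, "consistent")
  expect_equal(run_with("observed")$signed_consistent, "inconsistent")
})
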