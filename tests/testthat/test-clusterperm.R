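# Cluster formation, permutation null, cluster p-values.

test_that("clusters are maximal same-sign sub-threshold runs", {
  # below threshold only at bins 12-19, positive stats
  p <- rep(0.5, 30); p[12:19] <- 0.01
  s <- rep(1, 30)
  bs <- make_bin_stats(s, p)
  cl <- form_clusters(bs)
  expect_equal(nrow(cl), 1)
  expect_equal(c(cl$start_bin, cl$end_bin), c(12, 19))
  expect_equal(cl$mass, 8)
  expect_equal(cl$sign, "+")

  # alternating signs split into length-1 clusters
  p2 <- rep(0.01, 6)
  s2 <- c(2, -2, 2, -2, 2, -2)
  cl2 <- form_clusters(make_bin_stats(s2, p2))
  expect_equal(nrow(cl2), 6)
  expect_true(all(cl2$n_bins == 1))

  # absent bins break contiguity
  p3 <- rep(0.01, 5); p3[3] <- NA
  cl3 <- form_clusters(make_bin_stats(rep(1, 5), p3))
  expect_equal(nrow(cl3), 2)

  # nothing below threshold: empty result
  expect_equal(nrow(form_clusters(make_bin_stats(rep(1, 10), rep(0.2, 10)))), 0)

  # inclusion threshold is strict: p exactly 0.05 is excluded
  p4 <- c(0.05, 0.01)
  cl4 <- form_clusters(make_bin_stats(c(1, 1), p4))
  expect_equal(c(cl4$start_bin, cl4$end_bin), c(2, 2))
})

test_that("cluster p follows the add-one permutation formula", {
  cl <- form_clusters(make_bin_stats(rep(3, 4), rep(0.001, 4)))  # mass 12
  null1 <- structure(list(max_mass = rep(1, 999), n_perm = 999,
                          exhaustive = FALSE), class = "perm_null")
  expect_equal(cluster_p(cl, null1)$p_cluster, 1 / 1000)
  # observed at the null median
  null2 <- structure(list(max_mass = c(rep(1, 500), rep(20, 500)),
                          n_perm = 1000, exhaustive = FALSE),
                     class = "perm_null")
  expect_equal(cluster_p(cl, null2)$p_cluster, 501 / 1001)
  expect_error(cluster_p(cl, structure(list(max_mass = numeric(0), n_perm = 0,
                                            exhaustive = FALSE),
                                       class = "perm_null")), "empty")
})

test_that("permutation null matches brute-force enumeration on a tiny case", {
  # 2 participants x 4 trials (2 per level): 6 x 6 = 36 relabellings
  set.seed(33)
  vals <- matrix(rnorm(8 * 6), 8, 6)
  em <- make_epochs(vals, rep(c("p1", "p2"), each = 4),
                    outcome = rep(c("US+", "US+", "US-", "US-"), 2))
  con <- two_level_contrast()
  null <- build_null(em, con, exhaustive = TRUE)
  expect_equal(null$n_perm, 36)

  # independent oracle: enumerate label assignments and recompute the
  # max |cluster mass| from scratch (paired t per bin, strict p < 0.05 runs)
  combos1 <- combn(4, 2, simplify = FALSE)
  oracle <- c()
  for (c1 in combos1) for (c2 in combos1) {
    is_a <- rep(FALSE, 8)
    is_a[c1] <- TRUE; is_a[4 + c2] <- TRUE
    d <- sapply(seq_len(ncol(vals)), function(b) {
      m1 <- mean(vals[1:4, b][is_a[1:4]]) - mean(vals[1:4, b][!is_a[1:4]])
      m2 <- mean(vals[5:8, b][is_a[5:8]]) - mean(vals[5:8, b][!is_a[5:8]])
      c(m1, m2)
    })
    tt <- apply(d, 2, function(x) {
      tv <- mean(x) / (sd(x) / sqrt(2))
      c(tv, 2 * pt(-abs(tv), 1))
    })
    ok <- tt[2, ] < 0.05
    mass <- 0
    if (any(ok)) {
      runs <- rle(ok & c(TRUE, diff(sign(tt[1, ])) == 0 | !ok[-1]) | ok)
      # simple scan: accumulate same-sign runs
      best <- 0; cur <- 0; cur_sign <- 0
      for (b in seq_along(ok)) {
        if (ok[b] && (cur_sign == 0 || sign(tt[1, b]) == cur_sign)) {
          cur <- cur + tt[1, b]; cur_sign <- sign(tt[1, b])
        } else if (ok[b]) {
          cur <- tt[1, b]; cur_sign <- sign(tt[1, b])
        } else {
          cur <- 0; cur_sign <- 0
        }
        best <- max(best, abs(cur))
      }
      mass <- best
    }
    oracle <- c(oracle, mass)
  }
  expect_equal(sort(null$max_mass), sort(oracle), tolerance = 1e-10)
})

test_that("identity relabelling places the observed mass inside the null", {
  em <- make_two_level_epochs(3, 2, 8, effect = 0, seed = 44)
  con <- two_level_contrast()
  bs <- fit_all_bins(em, con, method = "paired")
  cl <- form_clusters(bs)
  null <- build_null(em, con, exhaustive = TRUE)
  if (nrow(cl) > 0) {
    # exhaustive null contains the observed configuration, so p >= 1/n
    pc <- cluster_p(cl, null)$p_cluster
    expect_true(all(pc >= 1 / null$n_perm))
    expect_true(any(null$max_mass >= max(abs(cl$mass)) - 1e-12))
  } else {
    succeed()
  }
})

test_that("null data give non-extreme observed masses and reproducible nulls", {
  em <- make_two_level_epochs(8, 6, 20, effect = 0, seed = 55)
  con <- two_level_contrast()
  n1 <- build_null(em, con, n_perm = 300, seed = 7)
  n2 <- build_null(em, con, n_perm = 300, seed = 7)
  expect_identical(n1$max_mass, n2$max_mass)
  bs <- fit_all_bins(em, con, method = "paired")
  obs <- pephys:::max_abs_cluster_mass(bs$statistic, bs$p, 0.05)
  q <- mean(n1$max_mass >= obs)
  expect_gt(q, 0.01)  # observed mass is not an extreme outlier under H0
  expect_warning(build_null(em, con, n_perm = 50, seed = 1), "coarse")
})

test_that("detected cluster mass grows with injected amplitude", {
  masses <- sapply(c(0.3, 0.8, 1.6), function(eff) {
    em <- make_two_level_epochs(10, 6, 30, effect = eff,
                                effect_bins = 10:20, seed = 66)
    bs <- fit_all_bins(em, two_level_contrast(), method = "paired")
    pephys:::max_abs_cluster_mass(bs$statistic, bs$p, 0.05)
  })
  expect_true(all(diff(masses) > 0))
})

test_that("participant order does not affect the test", {
  em <- make_two_level_epochs(5, 4, 10, effect = 1, seed = 77)
  con <- two_level_contrast()
  perm <- rev(seq_len(nrow(em$values)))
  em2 <- em
  em2$values <- em$values[perm, , drop = FALSE]
  em2$trials <- em$trials[perm, , drop = FALSE]
  ct1 <- cluster_test(em, con, n_perm = 200, seed = 3)
  ct2 <- cluster_test(em2, con, n_perm = 200, seed = 3)
  expect_equal(ct1$bin_stats$statistic, ct2$bin_stats$statistic,
               tolerance = 1e-10)
  expect_equal(ct1$clusters$mass, ct2$clusters$mass, tolerance = 1e-10)
})

test_that("lmm-based cluster test agrees with the fast statistic on strong
           effects", {
  em <- make_two_level_epochs(6, 4, 6, effect = 2, effect_bins = 2:5,
                              seed = 88)
  con <- two_level_contrast()
  ct_fast <- cluster_test(em, con, n_perm = 120, seed = 4, method = "paired")
  ct_lmm <- cluster_test(em, con, n_perm = 120, seed = 4, method = "lmm")
  main_fast <- ct_fast$clusters[which.max(abs(ct_fast$clusters$mass)), ]
  main_lmm <- ct_lmm$clusters[which.max(abs(ct_lmm$clusters$mass)), ]
  expect_equal(main_fast$sign, main_lmm$sign)
  # both localise the effect to the injected support
  expect_true(main_fast$start_bin >= 1 && main_fast$end_bin <= 6)
  expect_true(main_lmm$start_bin >= 1 && main_lmm$end_bin <= 6)
  expect_lt(main_lmm$p_cluster, 0.05)
})
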