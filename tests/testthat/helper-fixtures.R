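# Shared fixture builders. Everything is generated in code; no stored data.

# Epoch matrix built directly from a trials-by-bins value matrix.
make_epochs <- function(values, participant, outcome = NULL, rate = NULL,
                        cs_label = NULL, bin_start = 0, study = "s1") {
  nt <- nrow(values)
  trials <- tibble::tibble(
    participant_id = participant,
    study_id = rep_len(study, nt),
    trial_index = stats::ave(seq_len(nt), participant, FUN = seq_along),
    cs_label = cs_label %||% rep("CS", nt),
    reinforcement_rate = rate %||% rep(0.5, nt),
    outcome = outcome %||% rep("US+", nt),
    half = "first",
    baseline = rep(0, nt))
  structure(list(values = values,
                 bin_times = bin_start + 0.1 * (seq_len(ncol(values)) - 1),
                 trials = trials, modality = "SCR",
                 window = epoch_window("SCR", start_s = bin_start,
                                       end_s = bin_start + 0.1 * ncol(values)),
                 baseline_corrected = TRUE),
            class = "epoch_matrix")
}

# Two-level within-participant epochs: n_ppt participants, n_per trials per
# level, optional effect added to level "a" on the given bins.
make_two_level_epochs <- function(n_ppt, n_per, n_bins, effect = 0,
                                  effect_bins = seq_len(n_bins), sd = 1,
                                  ppt_sd = 0, seed = 1) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    nt <- n_ppt * 2 * n_per
    participant <- rep(sprintf("p%02d", seq_len(n_ppt)), each = 2 * n_per)
    level <- rep(rep(c("a", "b"), each = n_per), n_ppt)
    values <- matrix(stats::rnorm(nt * n_bins, sd = sd), nt, n_bins)
    values <- values + rep(stats::rnorm(n_ppt, 0, ppt_sd), each = 2 * n_per)
    values[level == "a", effect_bins] <-
      values[level == "a", effect_bins] + effect
    make_epochs(values, participant,
                outcome = ifelse(level == "a", "US+", "US-"),
                rate = rep(0.5, nt))
  })
}

two_level_contrast <- function() {
  contrast_spec("US+ (50%) vs US- (50%)",
                level_a = list(outcome = "US+", rate = 0.5),
                level_b = list(outcome = "US-", rate = 0.5))
}

# A bin_stats tibble from raw vectors (for cluster-formation tests).
make_bin_stats <- function(statistic, p, bin_start = 0) {
  out <- tibble::tibble(bin_index = seq_along(statistic),
                        bin_time = bin_start + 0.1 * (seq_along(statistic) - 1),
                        estimate = statistic, statistic = statistic, p = p,
                        n = 10L, fallback = NA_integer_)
  class(out) <- c("bin_stats", class(out))
  out
}

# Synthetic contrast-outcome tables for the axiom evaluator.
make_outcomes_ds2 <- function(a1 = c("a_greater", "a_greater", "a_greater"),
                              a2 = rep("null", 6)) {
  rates <- c(0.2, 0.5, 0.8)
  pairs <- utils::combn(rates, 2)
  a2_rows <- do.call(rbind, lapply(c("US+", "US-"), function(oc) {
    tibble::tibble(outcome = oc, rate_a = pairs[1, ], rate_b = pairs[2, ])
  }))
  tibble::tibble(
    name = c(sprintf("A1 %d%%", rates * 100),
             sprintf("A2 %s %d-%d", a2_rows$outcome, a2_rows$rate_a * 100,
                     a2_rows$rate_b * 100)),
    type = rep(c("A1", "A2"), c(3, 6)),
    rate = c(rates, rep(NA, 6)),
    outcome = c(rep(NA, 3), a2_rows$outcome),
    rate_a = c(rep(NA, 3), a2_rows$rate_a),
    rate_b = c(rep(NA, 3), a2_rows$rate_b),
    direction = c(a1, a2),
    n_sig_clusters = 0L)
}
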