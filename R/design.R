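# Experimental designs and trial schedules for partial-reinforcement
# Pavlovian conditioning.

#' Define one conditioned-stimulus condition
#'
#' @param label Condition label, e.g. `"CS+"`.
#' @param reinforcement_rate Probability in `[0, 1]` that a trial of this CS
#'   ends with the aversive outcome (US delivery).
#' @param n_trials Number of trials per participant.
#' @return A list with class `cs_condition`.
#' @export
#' @examples
#' cs_condition("CS+", 0.5, 32)
cs_condition <- function(label, reinforcement_rate, n_trials) {
  stop_if_not(is.character(label) && length(label) == 1L, "label must be a string")
  stop_if_not(is.numeric(reinforcement_rate) &&
                reinforcement_rate >= 0 && reinforcement_rate <= 1,
              "reinforcement_rate must be in [0, 1]")
  stop_if_not(is.numeric(n_trials) && n_trials >= 1 && n_trials == round(n_trials),
              "n_trials must be a positive integer")
  structure(list(label = label,
                 reinforcement_rate = reinforcement_rate,
                 n_trials = as.integer(n_trials)),
            class = "cs_condition")
}

#' Define a conditioning design
#'
#' Captures the trial-structure parameters of a delay fear-conditioning
#' experiment: CS conditions with their reinforcement rates and trial counts,
#' CS and US timing, inter-trial interval range and the sampling rate of the
#' synthetic recordings.
#'
#' @param n_participants Number of participants.
#' @param cs_conditions List of [cs_condition()] objects.
#' @param cs_duration_s CS duration in seconds.
#' @param us_onset_s US onset in seconds after CS onset; must be smaller than
#'   `cs_duration_s`.
#' @param us_duration_s US duration in seconds.
#' @param iti_range_s Length-2 numeric, inter-trial interval bounds in
#'   seconds; ITIs are drawn i.i.d. uniform on this range.
#' @param fs_hz Sampling rate of generated recordings in Hz.
#' @param study_id Study label attached to every generated trial/recording.
#' @return A list with class `design_spec`.
#' @seealso [dataset1_design()], [dataset2_design()], [generate_schedule()]
#' @export
design_spec <- function(n_participants, cs_conditions,
                        cs_duration_s, us_onset_s, us_duration_s = 0.5,
                        iti_range_s = c(7, 11), fs_hz = 100,
                        study_id = "synth") {
  stop_if_not(n_participants >= 1 && n_participants == round(n_participants),
              "n_participants must be a positive integer")
  stop_if_not(is.list(cs_conditions) && length(cs_conditions) >= 1 &&
                all(vapply(cs_conditions, inherits, logical(1), "cs_condition")),
              "cs_conditions must be a list of cs_condition objects")
  stop_if_not(us_onset_s < cs_duration_s, "us_onset_s must precede CS offset")
  stop_if_not(length(iti_range_s) == 2 && iti_range_s[1] <= iti_range_s[2] &&
                all(iti_range_s > 0), "invalid iti_range_s")
  stop_if_not(fs_hz > 0, "fs_hz must be positive")
  labs <- vapply(cs_conditions, `[[`, character(1), "label")
  stop_if_not(!anyDuplicated(labs), "cs_condition labels must be unique")
  structure(list(n_participants = as.integer(n_participants),
                 cs_conditions = cs_conditions,
                 cs_duration_s = cs_duration_s,
                 us_onset_s = us_onset_s,
                 us_duration_s = us_duration_s,
                 iti_range_s = iti_range_s,
                 fs_hz = fs_hz,
                 study_id = study_id),
            class = "design_spec")
}

#' Differential-conditioning design (one 50% CS+, one CS-)
#'
#' Differential delay conditioning with a partially (50%) reinforced CS+ and
#' a never-reinforced CS-; CS lasts 4 s with US onset at 3.5 s. Trial counts
#' per CS vary between 10 and 96 across the published studies this design
#' emulates; 40/40 is used as a representative default.
#'
#' @param n_participants Number of participants (default 30).
#' @param n_trials Trials per CS condition.
#' @param fs_hz Sampling rate of generated recordings.
#' @return A `design_spec`.
#' @export
dataset1_design <- function(n_participants = 30, n_trials = 40, fs_hz = 100) {
  design_spec(
    n_participants = n_participants,
    cs_conditions = list(cs_condition("CS+", 0.5, n_trials),
                         cs_condition("CS-", 0.0, n_trials)),
    cs_duration_s = 4, us_onset_s = 3.5, us_duration_s = 0.5,
    iti_range_s = c(7, 11), fs_hz = fs_hz, study_id = "ds1")
}

#' Parametric-probability design (three CS+ at 20/50/80%)
#'
#' Three CS+ with reinforcement rates 20%, 50% and 80% and no CS-; CS lasts
#' 6.5 s with US onset at 6 s. Default N = 29 with 23/22/23 trials per rate
#' (68 CS+ trials in total).
#'
#' @param n_participants Number of participants (default 29).
#' @param n_trials Length-3 trial counts for the 20/50/80% conditions.
#' @param fs_hz Sampling rate of generated recordings.
#' @return A `design_spec`.
#' @export
dataset2_design <- function(n_participants = 29, n_trials = c(23, 22, 23),
                            fs_hz = 100) {
  stop_if_not(length(n_trials) == 3, "n_trials must have length 3")
  design_spec(
    n_participants = n_participants,
    cs_conditions = list(cs_condition("CS+20", 0.2, n_trials[1]),
                         cs_condition("CS+50", 0.5, n_trials[2]),
                         cs_condition("CS+80", 0.8, n_trials[3])),
    cs_duration_s = 6.5, us_onset_s = 6, us_duration_s = 0.5,
    iti_range_s = c(7, 11), fs_hz = fs_hz, study_id = "ds2")
}

# Exact US+ count for a condition: nearest integer, ties toward more US+.
n_reinforced <- function(rate, n_trials) as.integer(floor(rate * n_trials + 0.5))

#' Generate a per-participant trial schedule
#'
#' Builds the trial table for every participant of a design. Outcome counts
#' are exact per condition (e.g. a 50% rate over 32 trials yields exactly 16
#' reinforced trials; non-integer products are rounded to the nearest
#' integer, ties toward more reinforced trials). Trial order is randomly
#' permuted per participant and inter-trial intervals are drawn i.i.d.
#' uniform on the design's ITI range. On omission (`US-`) trials
#' `us_onset_s` is the *expected* US onset, so downstream epochs can be
#' time-locked to the omission.
#'
#' @param design A [design_spec()].
#' @param seed Integer seed; identical seeds give identical schedules.
#' @return A tibble with one row per trial and columns `participant_id`,
#'   `study_id`, `trial_index`, `cs_label`, `reinforcement_rate`, `outcome`
#'   (`"US+"`/`"US-"`), `cs_onset_s`, `us_onset_s`, `iti_s`.
#' @export
#' @examples
#' sched <- generate_schedule(dataset2_design(n_participants = 2), seed = 1)
#' table(sched$cs_label, sched$outcome)
generate_schedule <- function(design, seed) {
  stop_if_not(inherits(design, "design_spec"), "design must be a design_spec")
  with_seed(seed, {
    per_ppt <- lapply(seq_len(design$n_participants), function(p) {
      rows <- do.call(rbind, lapply(design$cs_conditions, function(cc) {
        n_plus <- n_reinforced(cc$reinforcement_rate, cc$n_trials)
        data.frame(cs_label = cc$label,
                   reinforcement_rate = cc$reinforcement_rate,
                   outcome = rep(c("US+", "US-"),
                                 c(n_plus, cc$n_trials - n_plus)),
                   stringsAsFactors = FALSE)
      }))
      rows <- rows[sample.int(nrow(rows)), , drop = FALSE]
      n <- nrow(rows)
      iti <- stats::runif(n, design$iti_range_s[1], design$iti_range_s[2])
      # trial i starts after trials 1..i-1 (CS + ITI each); session starts
      # with one ITI-length lead-in so the first baseline window exists
      trial_len <- design$cs_duration_s + iti
      cs_onset <- iti[1] + c(0, cumsum(trial_len[-n]))
      tibble::tibble(
        participant_id = sprintf("p%03d", p),
        study_id = design$study_id,
        trial_index = seq_len(n),
        cs_label = rows$cs_label,
        reinforcement_rate = rows$reinforcement_rate,
        outcome = rows$outcome,
        cs_onset_s = cs_onset,
        us_onset_s = cs_onset + design$us_onset_s,
        iti_s = iti)
    })
    out <- do.call(rbind, per_ppt)
    attr(out, "fs_hz") <- design$fs_hz
    attr(out, "design") <- design
    out
  })
}
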