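# Synthetic multi-modal recordings with known evoked-response structure.

#' Construct a recording object
#'
#' A `recording` is one participant's sampled signal for one modality, with a
#' per-sample missing mask.
#'
#' @param participant_id,study_id Identifiers.
#' @param modality One of `"SCR"`, `"PSR"`, `"HPR"`, `"RAR"`, `"GAZE_X"`,
#'   `"GAZE_Y"`.
#' @param fs_hz Sampling rate in Hz.
#' @param values Numeric sample vector (microsiemens for SCR, seconds for
#'   heart period, arbitrary units for PSR/RAR, cm on screen for gaze).
#' @param start_time_s Time of the first sample, seconds.
#' @param missing Logical per-sample missing mask (default all `FALSE`).
#' @return A list with class `recording`.
#' @export
recording <- function(participant_id, study_id, modality, fs_hz, values,
                      start_time_s = 0, missing = NULL) {
  stop_if_not(modality %in% modalities_known, "unknown modality: %s", modality)
  stop_if_not(fs_hz > 0, "fs_hz must be positive")
  missing <- missing %||% rep(FALSE, length(values))
  stop_if_not(length(missing) == length(values),
              "missing mask and values must have equal length")
  structure(list(participant_id = participant_id, study_id = study_id,
                 modality = modality, fs_hz = fs_hz,
                 values = as.numeric(values),
                 start_time_s = start_time_s,
                 missing = as.logical(missing)),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %s / %s / %s: %d samples @ %g Hz (%.1f s), %d missing\n",
              x$study_id, x$participant_id, x$modality, length(x$values),
              x$fs_hz, length(x$values) / x$fs_hz, sum(x$missing)))
  invisible(x)
}

rec_times <- function(rec) rec$start_time_s + (seq_along(rec$values) - 1) / rec$fs_hz

#' Amplitude map with same-sign omission responses
#'
#' Mean evoked amplitudes per outcome and reinforcement rate in which the US
#' omission response has the *same* sign as the US response and grows with
#' the unexpectedness of the omission -- the pattern observed empirically in
#' autonomic recordings, which is incompatible with signed prediction-error
#' encoding.
#'
#' @param rates Reinforcement rates present in the design.
#' @param us_amp US-response amplitude (same for all rates).
#' @param omission_gain Omission amplitude per unit reinforcement rate.
#' @return A tibble with columns `outcome`, `rate`, `amplitude`.
#' @export
amplitude_map_observed <- function(rates, us_amp = 1, omission_gain = 0.6) {
  tibble::tibble(
    outcome = rep(c("US+", "US-"), each = length(rates)),
    rate = rep(rates, 2),
    amplitude = c(rep(us_amp, length(rates)), omission_gain * rates))
}

#' Amplitude map implementing a signed prediction-error code
#'
#' Evoked amplitude proportional to the signed prediction error
#' (outcome minus expectation): `gain * (1 - rate)` on US trials and
#' `-gain * rate` on omission trials, so better-than-expected outcomes drive
#' the signal in the opposite direction.
#'
#' @param rates Reinforcement rates present in the design.
#' @param gain Scaling from prediction error to signal units.
#' @return A tibble with columns `outcome`, `rate`, `amplitude`.
#' @export
amplitude_map_signed_pe <- function(rates, gain = 1) {
  tibble::tibble(
    outcome = rep(c("US+", "US-"), each = length(rates)),
    rate = rep(rates, 2),
    amplitude = c(gain * (1 - rates), -gain * rates))
}

#' Generator parameters
#'
#' Parameters of the synthetic-recording generator for one or more
#' modalities: response kernels, condition amplitude maps, multiplicative
#' between-subject gain variability, additive Gaussian noise, baseline
#' levels, an optional slow autoregressive drift and an optional artifact
#' injector.
#'
#' @param modalities Character vector of modalities to generate.
#' @param amplitude_maps Named list (per modality) of amplitude maps: tibbles
#'   with columns `outcome`, `rate`, `amplitude` and optionally `cs_label`
#'   for designs whose conditions differ beyond outcome and rate.
#' @param kernels Named list (per modality) of kernel parameter lists;
#'   defaults from [default_kernel_params()].
#' @param between_subject_sd SD of the log-normal participant gain (drawn
#'   once per participant, multiplies all evoked amplitudes).
#' @param within_subject_sd Named numeric (per modality) SD of an additive
#'   per-trial perturbation of the evoked amplitude, in signal units
#'   (trial-to-trial response variability; 0 by default).
#' @param noise_sd Named numeric (per modality) SD of i.i.d. Gaussian sample
#'   noise, in signal units.
#' @param baseline_level Named numeric (per modality) baseline signal level.
#' @param drift If `TRUE`, add a slow first-order autoregressive drift.
#' @param drift_sd Innovation SD of the drift process.
#' @param drift_ar AR(1) coefficient of the drift (close to 1 = slow).
#' @param artifacts Optional tibble of artifact episodes to inject, with
#'   columns `participant_id`, `modality`, `start_s`, `end_s`, `value`; the
#'   signal is clamped to `value` over the episode (a plateau such as an
#'   electrode detaching).
#' @return A list with class `gen_params`.
#' @export
gen_params <- function(modalities = "SCR",
                       amplitude_maps,
                       kernels = NULL,
                       between_subject_sd = 0.3,
                       within_subject_sd = c(SCR = 0),
                       noise_sd = c(SCR = 0.05),
                       baseline_level = c(SCR = 2, PSR = 3, HPR = 1, RAR = 1,
                                          GAZE_X = 0, GAZE_Y = 0),
                       drift = FALSE, drift_sd = 0.001, drift_ar = 0.999,
                       artifacts = NULL) {
  stop_if_not(all(modalities %in% modalities_known), "unknown modality")
  stop_if_not(between_subject_sd >= 0, "between_subject_sd must be >= 0")
  stop_if_not(all(noise_sd >= 0), "noise_sd must be >= 0")
  stop_if_not(all(within_subject_sd >= 0), "within_subject_sd must be >= 0")
  core <- setdiff(modalities, c("GAZE_X", "GAZE_Y"))
  stop_if_not(all(core %in% names(amplitude_maps)),
              "amplitude_maps must cover every non-gaze modality")
  kernels <- kernels %||% stats::setNames(
    lapply(core, default_kernel_params), core)
  structure(list(modalities = modalities,
                 amplitude_maps = amplitude_maps,
                 kernels = kernels,
                 between_subject_sd = between_subject_sd,
                 within_subject_sd = within_subject_sd,
                 noise_sd = noise_sd,
                 baseline_level = baseline_level,
                 drift = drift, drift_sd = drift_sd, drift_ar = drift_ar,
                 artifacts = artifacts),
            class = "gen_params")
}

# Look up the evoked amplitude for one trial in an amplitude map.
lookup_amplitude <- function(map, outcome, rate, cs_label) {
  hit <- map$outcome == outcome & abs(map$rate - rate) < 1e-9
  if ("cs_label" %in% names(map)) hit <- hit & map$cs_label == cs_label
  i <- which(hit)
  stop_if_not(length(i) >= 1, "no amplitude for %s %s at rate %g",
              cs_label, outcome, rate)
  map$amplitude[i[1]]
}

#' Generate synthetic recordings for a schedule
#'
#' For every participant and requested modality, builds a sampled signal of
#' `baseline + gain * amplitude * kernel(t - us_onset)` summed over trials,
#' plus i.i.d. Gaussian noise (and optional slow drift). On omission trials
#' the response is time-locked to the *expected* US onset (an omission
#' response). The participant gain is drawn once per participant from a
#' log-normal with the configured SD. Gaze channels are generated as small
#' fixational jitter around the fixation point. Artifact episodes listed in
#' `params$artifacts` are injected as plateaus.
#'
#' @param schedule Trial table from [generate_schedule()].
#' @param params A [gen_params()] object.
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @param fs_hz Sampling rate; defaults to the schedule's design rate.
#' @return Named list of [recording()] objects
#'   (`"<participant>_<modality>"`), with the per-participant gains in
#'   `attr(, "gains")`.
#' @export
generate_recordings <- function(schedule, params, seed,
                                fs_hz = attr(schedule, "fs_hz") %||% 100) {
  stop_if_not(inherits(params, "gen_params"), "params must be gen_params")
  with_seed(seed, {
    ppts <- unique(schedule$participant_id)
    gains <- stats::setNames(
      exp(stats::rnorm(length(ppts), 0, params$between_subject_sd)), ppts)
    out <- list()
    for (p in ppts) {
      tr <- schedule[schedule$participant_id == p, , drop = FALSE]
      fs_p <- fs_hz
      dur <- max(tr$us_onset_s) + 20
      n <- ceiling(dur * fs_p)
      tgrid <- (seq_len(n) - 1) / fs_p
      for (m in params$modalities) {
        if (m %in% c("GAZE_X", "GAZE_Y")) {
          vals <- named_get(params$baseline_level, m, 0)
          vals <- vals + stats::rnorm(n, 0, 0.2)
        } else {
          vals <- rep(named_get(params$baseline_level, m, 0), n)
          map <- params$amplitude_maps[[m]]
          kp <- params$kernels[[m]]
          span <- ceiling(20 * fs_p)  # kernel support window per trial
          wsd <- named_get(params$within_subject_sd, m, 0)
          for (i in seq_len(nrow(tr))) {
            amp <- lookup_amplitude(map, tr$outcome[i],
                                    tr$reinforcement_rate[i], tr$cs_label[i])
            if (wsd > 0) amp <- amp + stats::rnorm(1, 0, wsd)
            i0 <- floor(tr$us_onset_s[i] * fs_p) + 1L
            idx <- i0:min(n, i0 + span)
            vals[idx] <- vals[idx] + gains[[p]] * amp *
              canonical_kernel(m, tgrid[idx] - tr$us_onset_s[i], kp)
          }
          nsd <- named_get(params$noise_sd, m, 0)
          if (nsd > 0) vals <- vals + stats::rnorm(n, 0, nsd)
          if (isTRUE(params$drift)) {
            innov <- stats::rnorm(n, 0, params$drift_sd)
            vals <- vals + stats::filter(innov, params$drift_ar,
                                         method = "recursive")
          }
        }
        rec <- recording(p, tr$study_id[1], m, fs_p, vals)
        if (!is.null(params$artifacts)) {
          af <- params$artifacts
          af <- af[af$participant_id == p & af$modality == m, , drop = FALSE]
          for (j in seq_len(nrow(af))) {
            t <- rec_times(rec)
            rec$values[t >= af$start_s[j] & t < af$end_s[j]] <- af$value[j]
          }
        }
        out[[paste(p, m, sep = "_")]] <- rec
      }
    }
    attr(out, "gains") <- gains
    out
  })
}
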