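# Modality-specific preprocessing into clean 10 Hz signals.
#
# Skin conductance: automatic range/slope quality assessment, linear
# interpolation of artifact periods (which stay excluded from statistics via
# the missing mask), first-order bidirectional low-pass Butterworth filter,
# downsampling to 10 Hz by 0.1-s bin averaging, and a per-session
# z-transform that absorbs between-subjects amplitude variance. Pupil:
# gaze-deviation exclusion and low-pass + downsample. Heart period: built
# from heartbeat timestamps with a physiological validity range.
# Respiration: cycle detection into a peak-to-trough amplitude series.

#' Quality-assessment configuration
#'
#' Thresholds used by the automatic artifact detection and validity filters.
#'
#' @param scr_range_uS Valid skin-conductance range in microsiemens.
#' @param scr_slope_max_uS_per_s Maximum absolute SCR slope.
#' @param gaze_deviation_max_deg Maximum gaze deviation from fixation in
#'   degrees visual angle.
#' @param hp_valid_range_s Valid heart-period (inter-beat interval) range in
#'   seconds (0.6-1.5 s corresponds to 40-100 bpm).
#' @param lowpass_cutoff_hz Named per-modality low-pass cutoffs in Hz.
#' @param target_fs_hz Analysis sampling rate.
#' @return A list with class `qa_config`.
#' @export
qa_config <- function(scr_range_uS = c(0.05, 60),
                      scr_slope_max_uS_per_s = 10,
                      gaze_deviation_max_deg = 5,
                      hp_valid_range_s = c(0.6, 1.5),
                      lowpass_cutoff_hz = c(SCR = 5, PSR = 50),
                      target_fs_hz = 10) {
  stop_if_not(scr_range_uS[1] < scr_range_uS[2] && all(scr_range_uS > 0),
              "invalid scr_range_uS")
  stop_if_not(hp_valid_range_s[1] < hp_valid_range_s[2] &&
                all(hp_valid_range_s > 0), "invalid hp_valid_range_s")
  stop_if_not(scr_slope_max_uS_per_s > 0 && gaze_deviation_max_deg > 0 &&
                target_fs_hz > 0, "thresholds must be positive")
  structure(list(scr_range_uS = scr_range_uS,
                 scr_slope_max_uS_per_s = scr_slope_max_uS_per_s,
                 gaze_deviation_max_deg = gaze_deviation_max_deg,
                 hp_valid_range_s = hp_valid_range_s,
                 lowpass_cutoff_hz = lowpass_cutoff_hz,
                 target_fs_hz = target_fs_hz),
            class = "qa_config")
}

#' Detect skin-conductance artifacts
#'
#' Flags every sample that lies outside the valid conductance range or whose
#' local slope magnitude exceeds the threshold. Slopes are finite
#' differences on the raw sampling grid: central differences for interior
#' samples, one-sided at the first and last sample. Both criteria are
#' strict (`>` the threshold / outside the closed range).
#'
#' @param rec An SCR [recording()].
#' @param cfg A [qa_config()].
#' @return A list with class `artifact_mask`: logical `flag` and character
#'   `reason` (`""`, `"range"`, `"slope"` or `"range,slope"`) per sample.
#' @export
detect_scr_artifacts <- function(rec, cfg = qa_config()) {
  stop_if_not(inherits(rec, "recording") && rec$modality == "SCR",
              "detect_scr_artifacts requires an SCR recording")
  x <- rec$values
  n <- length(x)
  range_bad <- x < cfg$scr_range_uS[1] | x > cfg$scr_range_uS[2]
  slope <- numeric(n)
  if (n >= 2) {
    slope[1] <- (x[2] - x[1]) * rec$fs_hz
    slope[n] <- (x[n] - x[n - 1]) * rec$fs_hz
    if (n >= 3) {
      i <- 2:(n - 1)
      slope[i] <- (x[i + 1] - x[i - 1]) * rec$fs_hz / 2
    }
  }
  slope_bad <- abs(slope) > cfg$scr_slope_max_uS_per_s
  reason <- rep("", n)
  reason[range_bad] <- "range"
  reason[slope_bad] <- ifelse(reason[slope_bad] == "", "slope", "range,slope")
  structure(list(flag = range_bad | slope_bad, reason = reason),
            class = "artifact_mask")
}

#' Linearly interpolate flagged samples
#'
#' Replaces flagged spans by linear interpolation between the nearest valid
#' neighbours (edge spans are held at the nearest valid value) and records
#' the flags in the recording's missing mask so that statistics exclude the
#' interpolated stretches.
#'
#' @param rec A [recording()].
#' @param mask An `artifact_mask` (or logical vector) aligned with `rec`.
#' @return The interpolated [recording()], with `missing` OR-ed with the mask.
#' @export
interpolate_masked <- function(rec, mask) {
  flag <- if (inherits(mask, "artifact_mask")) mask$flag else as.logical(mask)
  stop_if_not(length(flag) == length(rec$values),
              "mask and recording lengths differ")
  stop_if_not(!all(flag), "all samples flagged; nothing to interpolate from")
  if (any(flag)) {
    idx <- seq_along(rec$values)
    rec$values <- stats::approx(idx[!flag], rec$values[!flag], xout = idx,
                                rule = 2)$y
    rec$missing <- rec$missing | flag
  }
  rec
}

#' Bidirectional low-pass Butterworth filter
#'
#' Zero-phase low-pass filtering: a Butterworth filter of the given order is
#' applied forward and backward, so the magnitude response is the squared
#' one-pass gain (a first-order filter passes a tone at the cutoff frequency
#' with amplitude 1/2) and symmetric features keep their timing.
#'
#' @param rec A [recording()].
#' @param cutoff_hz Cutoff frequency; must be below the Nyquist frequency.
#' @param order Filter order (default 1, as used for skin conductance).
#' @return The filtered [recording()].
#' @export
lowpass_bidirectional <- function(rec, cutoff_hz, order = 1) {
  stop_if_not(cutoff_hz > 0 && cutoff_hz < rec$fs_hz / 2,
              "cutoff must lie in (0, Nyquist)")
  bf <- signal::butter(order, cutoff_hz / (rec$fs_hz / 2), type = "low")
  x <- rec$values
  n <- length(x)
  # odd-symmetric edge padding suppresses the start/end transients of the
  # forward and backward passes
  p <- min(n - 1, ceiling(3 * rec$fs_hz / cutoff_hz))
  xp <- c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
  yp <- as.numeric(signal::filtfilt(bf, xp))
  rec$values <- yp[(p + 1):(p + n)]
  rec
}

#' Downsample to the analysis rate by bin averaging
#'
#' Averages non-overlapping windows of `fs / target_fs` source samples
#' (0.1 s bins at the default 10 Hz). The source rate must be an integer
#' multiple of the target rate. A target bin is marked missing iff any of
#' its source samples was missing; values are the plain window means (run
#' after [interpolate_masked()] so flagged stretches hold interpolated
#' values).
#'
#' @param rec A [recording()].
#' @param target_fs_hz Output sampling rate (default 10 Hz).
#' @return The downsampled [recording()].
#' @export
downsample <- function(rec, target_fs_hz = 10) {
  stop_if_not(target_fs_hz <= rec$fs_hz, "target rate above source rate")
  ratio <- rec$fs_hz / target_fs_hz
  stop_if_not(abs(ratio - round(ratio)) < 1e-9,
              "source rate must be an integer multiple of the target rate")
  ratio <- as.integer(round(ratio))
  if (ratio == 1L) return(rec)
  n_out <- floor(length(rec$values) / ratio)
  used <- seq_len(n_out * ratio)
  rec$values <- colMeans(matrix(rec$values[used], nrow = ratio))
  rec$missing <- colSums(matrix(rec$missing[used], nrow = ratio)) > 0
  rec$fs_hz <- target_fs_hz
  rec
}

#' Z-transform a session
#'
#' Standardises the whole session per participant to mean 0 and sample SD 1
#' (denominator n - 1), computed over valid (non-missing) samples only.
#' Used for skin conductance to absorb between-subjects amplitude variance
#' from peripheral factors such as skin properties.
#'
#' @param rec A [recording()].
#' @return The standardised [recording()].
#' @export
zscore_session <- function(rec) {
  v <- rec$values[!rec$missing]
  stop_if_not(length(v) >= 2, "need at least 2 valid samples")
  s <- stats::sd(v)
  stop_if_not(s > 0, "zero variance; cannot z-transform")
  rec$values <- (rec$values - mean(v)) / s
  rec
}

#' Mask pupil samples during gaze deviation
#'
#' Marks pupil samples as missing whenever gaze direction deviates beyond
#' the maximum visual angle from the fixation point. The visual angle is
#' `atan(on-screen distance / viewing distance)`; the boundary itself (an
#' angle of exactly `max_deg`) is retained, since only deviation *beyond*
#' the limit is excluded.
#'
#' @param pupil A PSR [recording()].
#' @param gaze_x,gaze_y Gaze [recording()]s time-aligned with `pupil`, in cm
#'   on screen.
#' @param fixation_point Length-2 fixation point (cm on screen).
#' @param geometry List with `viewing_distance_cm` (70 cm in the
#'   differential-conditioning setup, 64.5 cm in the parametric one).
#' @param max_deg Maximum visual angle in degrees (default 5).
#' @return The pupil [recording()] with deviating samples marked missing.
#' @export
exclude_gaze_deviation <- function(pupil, gaze_x, gaze_y,
                                   fixation_point = c(0, 0), geometry,
                                   max_deg = 5) {
  stop_if_not(!missing(geometry) && !is.null(geometry$viewing_distance_cm),
              "geometry with viewing_distance_cm is required")
  n <- length(pupil$values)
  stop_if_not(length(gaze_x$values) == n && length(gaze_y$values) == n,
              "gaze channels must be time-aligned with the pupil channel")
  dx <- gaze_x$values - fixation_point[1]
  dy <- gaze_y$values - fixation_point[2]
  ang <- atan(sqrt(dx^2 + dy^2) / geometry$viewing_distance_cm) * 180 / pi
  pupil$missing <- pupil$missing | (ang > max_deg)
  pupil
}

#' Heart-period series from heartbeat timestamps
#'
#' Converts heartbeat timestamps into a uniformly sampled heart-period
#' signal: each inter-beat interval is assigned at the time of its later
#' beat, intervals outside the physiological validity range are removed,
#' and the remaining values are linearly interpolated onto a uniform grid
#' (edge-held beyond the first/last valid interval).
#'
#' @param beat_times_s Strictly increasing heartbeat times in seconds
#'   (at least 3 beats).
#' @param fs_out Output sampling rate (default 10 Hz).
#' @param valid_range Valid inter-beat interval range in seconds.
#' @param participant_id,study_id Identifiers for the output recording.
#' @return An HPR [recording()] starting at time 0.
#' @export
heartbeats_to_heart_period <- function(beat_times_s, fs_out = 10,
                                       valid_range = c(0.6, 1.5),
                                       participant_id = "p", study_id = "s") {
  stop_if_not(length(beat_times_s) >= 3, "need at least 3 beats")
  stop_if_not(all(diff(beat_times_s) > 0), "beat times must be strictly increasing")
  ibi <- diff(beat_times_s)
  at <- beat_times_s[-1]
  ok <- ibi >= valid_range[1] & ibi <= valid_range[2]
  stop_if_not(any(ok), "all inter-beat intervals outside the valid range")
  grid <- seq(0, max(beat_times_s), by = 1 / fs_out)
  vals <- stats::approx(at[ok], ibi[ok], xout = grid, rule = 2)$y
  recording(participant_id, study_id, "HPR", fs_out, vals, start_time_s = 0)
}

# Indices of strict local maxima/minima of a numeric vector.
local_extrema <- function(x, what = c("max", "min")) {
  what <- match.arg(what)
  d <- diff(x)
  if (what == "min") d <- -d
  which(d[-length(d)] > 0 & d[-1] < 0) + 1L
}

#' Respiration amplitude series from a raw respiratory signal
#'
#' Detects respiratory cycles as successive troughs bracketing a peak,
#' computes the per-cycle amplitude (peak minus preceding trough), assigns
#' it at the peak time, and linearly interpolates to a uniform output grid.
#'
#' @param rec A raw respiration [recording()] (quasi-periodic).
#' @param fs_out Output sampling rate (default 10 Hz).
#' @return An RAR [recording()] at `fs_out`.
#' @export
respiration_to_amplitude <- function(rec, fs_out = 10) {
  x <- rec$values
  t <- rec_times(rec)
  peaks <- local_extrema(x, "max")
  troughs <- local_extrema(x, "min")
  # first cycle may start at the recording onset rather than a detected trough
  if (length(peaks) > 0 && (length(troughs) == 0 || troughs[1] > peaks[1])) {
    troughs <- c(1L, troughs)
  }
  amp <- numeric(0); at <- numeric(0)
  for (pk in peaks) {
    pre <- troughs[troughs < pk]
    if (length(pre) == 0) next
    tr <- max(pre)
    amp <- c(amp, x[pk] - x[tr])
    at <- c(at, t[pk])
  }
  stop_if_not(length(amp) >= 1, "no respiratory cycles detected")
  grid <- seq(t[1], t[length(t)], by = 1 / fs_out)
  vals <- stats::approx(at, amp, xout = grid, rule = 2, ties = "ordered")$y
  recording(rec$participant_id, rec$study_id, "RAR", fs_out, vals,
            start_time_s = t[1])
}

#' Full skin-conductance preprocessing chain
#'
#' Enforces the canonical stage order: artifact detection, linear
#' interpolation of flagged spans, first-order bidirectional 5 Hz low-pass,
#' downsampling to 10 Hz and per-session z-transform. The processing log
#' (flag counts per stage) is attached as `attr(, "log")` and a processed
#' marker prevents accidental re-runs on already-processed output.
#'
#' @param rec A raw SCR [recording()].
#' @param cfg A [qa_config()].
#' @param zscore Apply the final z-transform (default `TRUE`).
#' @return The preprocessed 10 Hz [recording()].
#' @export
preprocess_scr <- function(rec, cfg = qa_config(), zscore = TRUE) {
  stop_if_not(is.null(attr(rec, "processed")),
              "recording already preprocessed; refusing to re-run")
  mask <- detect_scr_artifacts(rec, cfg)
  rec <- interpolate_masked(rec, mask)
  rec <- lowpass_bidirectional(rec, cfg$lowpass_cutoff_hz[["SCR"]])
  rec <- downsample(rec, cfg$target_fs_hz)
  if (zscore) rec <- zscore_session(rec)
  attr(rec, "processed") <- TRUE
  attr(rec, "log") <- list(n_flagged_raw = sum(mask$flag),
                           reasons = table(mask$reason[mask$flag]),
                           n_missing_10hz = sum(rec$missing))
  rec
}

#' Pupil preprocessing chain
#'
#' Range and dilation-speed validity filtering (a simplified form of the
#' standard pupil validity procedure; see the methods vignette), optional
#' gaze-deviation exclusion, interpolation of invalid samples, low-pass
#' filtering and downsampling to 10 Hz. The low-pass cutoff is capped below
#' the recording's Nyquist frequency when the source rate cannot support the
#' configured cutoff.
#'
#' @param rec A raw PSR [recording()].
#' @param cfg A [qa_config()].
#' @param gaze_x,gaze_y,fixation_point,geometry Optional gaze-deviation
#'   inputs, as in [exclude_gaze_deviation()].
#' @param valid_range Plausible pupil-size range (signal units).
#' @param speed_max Maximum absolute dilation speed (units/s).
#' @return The preprocessed 10 Hz [recording()].
#' @export
preprocess_psr <- function(rec, cfg = qa_config(), gaze_x = NULL,
                           gaze_y = NULL, fixation_point = c(0, 0),
                           geometry = NULL, valid_range = c(0.1, 12),
                           speed_max = 50) {
  stop_if_not(is.null(attr(rec, "processed")),
              "recording already preprocessed; refusing to re-run")
  if (!is.null(gaze_x) && !is.null(gaze_y)) {
    rec <- exclude_gaze_deviation(rec, gaze_x, gaze_y, fixation_point,
                                  geometry, cfg$gaze_deviation_max_deg)
  }
  x <- rec$values
  bad <- x < valid_range[1] | x > valid_range[2]
  speed <- c(0, abs(diff(x)) * rec$fs_hz)
  bad <- bad | speed > speed_max
  if (any(bad) && !all(bad)) rec <- interpolate_masked(rec, bad)
  cutoff <- min(cfg$lowpass_cutoff_hz[["PSR"]], 0.45 * rec$fs_hz)
  rec <- lowpass_bidirectional(rec, cutoff)
  rec <- downsample(rec, cfg$target_fs_hz)
  attr(rec, "processed") <- TRUE
  rec
}
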