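# Outcome-locked, baseline-corrected trial epochs on 0.1-s bins.

#' Analysis window for a modality
#'
#' Response intervals relative to (expected) US onset: skin conductance
#' 2-10 s, heart period and respiration amplitude 0-10 s, pupil 0-4 s, each
#' preceded by a 0.5 s pre-US baseline window. Bins are half-open
#' `[t, t + 0.1)` so the window covers exactly `(end - start) / 0.1` bins.
#'
#' @param modality Optional modality whose default window to use.
#' @param start_s,end_s Window bounds in seconds relative to US onset.
#' @param baseline Length-2 baseline window relative to US onset.
#' @param bin_s Bin width in seconds (default 0.1).
#' @return A list with class `epoch_window`.
#' @export
#' @examples
#' epoch_window("SCR")  # 2-10 s, 80 bins
epoch_window <- function(modality = NULL, start_s = NULL, end_s = NULL,
                         baseline = c(-0.5, 0), bin_s = 0.1) {
  if (!is.null(modality) && (is.null(start_s) || is.null(end_s))) {
    w <- switch(modality,
                SCR = c(2, 10), HPR = c(0, 10), RAR = c(0, 10), PSR = c(0, 4),
                stop("no default window for modality ", modality, call. = FALSE))
    start_s <- start_s %||% w[1]
    end_s <- end_s %||% w[2]
  }
  stop_if_not(start_s < end_s, "start must precede end")
  n_bins <- (end_s - start_s) / bin_s
  stop_if_not(abs(n_bins - round(n_bins)) < 1e-9,
              "bin width must divide the window exactly")
  structure(list(modality = modality, start_s = start_s, end_s = end_s,
                 baseline = baseline, bin_s = bin_s),
            class = "epoch_window")
}

#' Cut a 10 Hz recording into outcome-locked epochs
#'
#' Extracts one row per trial from a preprocessed recording, time-locked to
#' the trial's actual or expected US onset. Cells that overlap masked
#' samples, or that extend past the recording, are marked missing. The
#' per-trial mean over the baseline window is stored as a `baseline` column
#' (used by [baseline_correct()] and available as a model covariate), and a
#' `half` label (`"first"`/`"second"`, median split of the participant's
#' trial indices) is assigned once here so that [filter_half()] is
#' idempotent.
#'
#' @param rec A [recording()] at the analysis rate (10 Hz).
#' @param trials Trial table rows for this recording's participant (other
#'   participants' rows are ignored).
#' @param window An [epoch_window()].
#' @return An `epoch_matrix`: list with `values` (trials x bins, `NA` for
#'   missing cells), `bin_times` (bin start times relative to US onset),
#'   `trials` (per-trial labels) and `modality`.
#' @export
extract_epochs <- function(rec, trials, window) {
  stop_if_not(inherits(window, "epoch_window"), "window must be an epoch_window")
  tr <- trials[trials$participant_id == rec$participant_id, , drop = FALSE]
  stop_if_not(nrow(tr) > 0, "no trials for participant %s", rec$participant_id)
  fs <- rec$fs_hz
  stop_if_not(abs(fs * window$bin_s - 1) < 1e-9,
              "recording rate must match the bin width (expected %g Hz)",
              1 / window$bin_s)
  bin_times <- seq(window$start_s, window$end_s - window$bin_s,
                   by = window$bin_s)
  nb <- length(bin_times)
  n <- length(rec$values)
  sample_at <- function(t_abs) {
    i <- floor((t_abs - rec$start_time_s) * fs + 1e-6) + 1L
    ifelse(i >= 1 & i <= n, i, NA_integer_)
  }
  vals <- matrix(NA_real_, nrow(tr), nb)
  bl <- rep(NA_real_, nrow(tr))
  bl_times <- seq(window$baseline[1], window$baseline[2] - window$bin_s,
                  by = window$bin_s)
  for (i in seq_len(nrow(tr))) {
    us <- tr$us_onset_s[i]
    idx <- sample_at(us + bin_times)
    v <- ifelse(is.na(idx) | rec$missing[pmax(idx, 1L)], NA_real_,
                rec$values[pmax(idx, 1L)])
    vals[i, ] <- v
    bidx <- sample_at(us + bl_times)
    bv <- ifelse(is.na(bidx) | rec$missing[pmax(bidx, 1L)], NA_real_,
                 rec$values[pmax(bidx, 1L)])
    if (any(!is.na(bv))) bl[i] <- mean(bv, na.rm = TRUE)
  }
  med <- stats::median(tr$trial_index)
  labels <- tibble::tibble(
    participant_id = tr$participant_id, study_id = tr$study_id,
    trial_index = tr$trial_index, cs_label = tr$cs_label,
    reinforcement_rate = tr$reinforcement_rate, outcome = tr$outcome,
    half = ifelse(tr$trial_index > med, "second", "first"),
    baseline = bl)
  structure(list(values = vals, bin_times = bin_times, trials = labels,
                 modality = window$modality %||% rec$modality,
                 window = window, baseline_corrected = FALSE),
            class = "epoch_matrix")
}

#' @export
print.epoch_matrix <- function(x, ...) {
  cat(sprintf("<epoch_matrix> %s: %d trials x %d bins (%g to %g s post-US), %d participants%s\n",
              x$modality, nrow(x$values), ncol(x$values),
              x$window$start_s, x$window$end_s,
              length(unique(x$trials$participant_id)),
              if (isTRUE(x$baseline_corrected)) ", baseline-corrected" else ""))
  invisible(x)
}

# Bind epoch matrices from several participants (same window/modality).
bind_epochs <- function(ems) {
  stop_if_not(length(ems) >= 1, "no epoch matrices to bind")
  out <- ems[[1]]
  out$values <- do.call(rbind, lapply(ems, `[[`, "values"))
  out$trials <- do.call(rbind, lapply(ems, `[[`, "trials"))
  out
}

#' Baseline-correct epochs
#'
#' Subtracts the mean of the 0.5 s pre-US interval. The default
#' (`per_participant`) subtracts each participant's mean over all trials'
#' baselines; `per_trial` subtracts each trial's own baseline (provided for
#' sensitivity analysis). The raw per-trial baseline is retained in the
#' `baseline` label column as a potential model covariate.
#'
#' @param em An `epoch_matrix` from [extract_epochs()].
#' @param mode `"per_participant"` (default) or `"per_trial"`.
#' @return The corrected `epoch_matrix`.
#' @export
baseline_correct <- function(em, mode = c("per_participant", "per_trial")) {
  mode <- match.arg(mode)
  if (mode == "per_participant") {
    bl <- tapply(em$trials$baseline, em$trials$participant_id,
                 mean, na.rm = TRUE)
    stop_if_not(!any(is.na(bl)),
                "a participant has no valid baseline bins")
    shift <- as.numeric(bl[em$trials$participant_id])
  } else {
    shift <- em$trials$baseline
    stop_if_not(!any(is.na(shift)), "a trial has no valid baseline bins")
  }
  em$values <- em$values - shift
  em$baseline_corrected <- TRUE
  em$baseline_mode <- mode
  em
}

#' Restrict epochs to one experiment half
#'
#' Keeps trials from the first or second half of each participant's
#' session, using the `half` labels assigned at extraction (trial index
#' above the participant's median index = second half); filtering is
#' therefore idempotent.
#'
#' @param em An `epoch_matrix`.
#' @param half `"second"` (default; the assumption-light subset in which
#'   contingencies are well learned) or `"first"`.
#' @return The filtered `epoch_matrix`.
#' @export
filter_half <- function(em, half = c("second", "first")) {
  half <- match.arg(half)
  keep <- em$trials$half == half
  stop_if_not(any(keep), "no trials in the requested half")
  em$values <- em$values[keep, , drop = FALSE]
  em$trials <- em$trials[keep, , drop = FALSE]
  em
}
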