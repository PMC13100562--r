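# Trough-to-peak robustness scoring for skin conductance and pupil size,
# with paired comparisons on per-participant condition means.

#' Trough-to-peak score for one skin-conductance epoch
#'
#' The response onset is the trough (local minimum) within 1-4 s after US
#' onset; the peak is the maximum within 0.5-5 s after that onset (clipped
#' to the epoch's extent); the amplitude is peak minus onset.
#'
#' @param values Epoch sample vector.
#' @param bin_times Bin times in seconds relative to US onset (must cover
#'   the onset window).
#' @param onset_window Onset search window, seconds post-US.
#' @param peak_offset Peak search window relative to the onset time.
#' @return A list: `amplitude`, `onset_time_s`, `peak_time_s`, `clipped`;
#'   or `NULL` when the onset window is fully missing.
#' @export
score_scr <- function(values, bin_times, onset_window = c(1, 4),
                      peak_offset = c(0.5, 5)) {
  on_idx <- which(bin_times >= onset_window[1] & bin_times <= onset_window[2] &
                    !is.na(values))
  if (length(on_idx) == 0) return(NULL)
  o <- on_idx[which.min(values[on_idx])]
  pw <- bin_times[o] + peak_offset
  clipped <- pw[2] > max(bin_times)
  pk_idx <- which(bin_times >= pw[1] & bin_times <= pw[2] & !is.na(values))
  if (length(pk_idx) == 0) return(NULL)
  p <- pk_idx[which.max(values[pk_idx])]
  list(amplitude = values[p] - values[o],
       onset_time_s = bin_times[o], peak_time_s = bin_times[p],
       clipped = clipped)
}

#' Baseline-to-peak score for one pupil epoch
#'
#' The amplitude is the maximum within 1-4 s after US onset minus the mean
#' over the 1 s immediately before US onset.
#'
#' @param values Epoch sample vector.
#' @param bin_times Bin times relative to US onset (must cover -1 to 4 s).
#' @param peak_window Peak search window, seconds post-US.
#' @param baseline_window Pre-US baseline window.
#' @return A list: `amplitude`, `peak_time_s`; or `NULL` when either window
#'   is fully missing.
#' @export
score_psr <- function(values, bin_times, peak_window = c(1, 4),
                      baseline_window = c(-1, 0)) {
  bl_idx <- which(bin_times >= baseline_window[1] &
                    bin_times < baseline_window[2] & !is.na(values))
  pk_idx <- which(bin_times >= peak_window[1] & bin_times <= peak_window[2] &
                    !is.na(values))
  if (length(bl_idx) == 0 || length(pk_idx) == 0) return(NULL)
  p <- pk_idx[which.max(values[pk_idx])]
  list(amplitude = values[p] - mean(values[bl_idx]),
       peak_time_s = bin_times[p])
}

#' Score every epoch of a matrix
#'
#' Applies the modality's peak scorer ([score_scr()] or [score_psr()]) to
#' every trial and returns a per-trial score table.
#'
#' @param em An `epoch_matrix` whose window covers the scorer's windows
#'   (SCR: 1 s post-US through onset + 5 s; PSR: -1 to 4 s).
#' @param modality `"SCR"` or `"PSR"` (default: the matrix's modality).
#' @return Tibble with `participant_id`, `cs_label`, `reinforcement_rate`,
#'   `outcome`, `trial_index`, `amplitude`, `peak_time_s` (plus
#'   `onset_time_s` for SCR).
#' @export
score_epochs <- function(em, modality = em$modality) {
  stop_if_not(modality %in% c("SCR", "PSR"), "peak scoring is defined for SCR and PSR")
  rows <- lapply(seq_len(nrow(em$values)), function(i) {
    sc <- if (modality == "SCR") {
      score_scr(em$values[i, ], em$bin_times)
    } else {
      score_psr(em$values[i, ], em$bin_times)
    }
    if (is.null(sc)) return(NULL)
    tibble::tibble(participant_id = em$trials$participant_id[i],
                   cs_label = em$trials$cs_label[i],
                   reinforcement_rate = em$trials$reinforcement_rate[i],
                   outcome = em$trials$outcome[i],
                   trial_index = em$trials$trial_index[i],
                   amplitude = sc$amplitude,
                   onset_time_s = sc$onset_time_s %||% NA_real_,
                   peak_time_s = sc$peak_time_s)
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' Paired comparison of per-participant condition means
#'
#' Standard paired t-test on participant-matched condition means. When the
#' paired differences have zero variance the t statistic is infinite; the
#' result is flagged (`zero_variance = TRUE`) with `p = NA` rather than
#' reporting a spurious certainty.
#'
#' @param scores_a,scores_b Named numeric vectors of per-participant means
#'   (names = participant ids); only participants present in both are used.
#' @return A list: `t`, `df`, `p`, `mean_diff`, `n`, `zero_variance`.
#' @export
paired_compare <- function(scores_a, scores_b) {
  common <- intersect(names(scores_a), names(scores_b))
  stop_if_not(length(common) >= 3, "need at least 3 matched pairs")
  d <- scores_a[common] - scores_b[common]
  n <- length(d)
  md <- mean(d)
  s <- stats::sd(d)
  if (s == 0) {
    return(list(t = ifelse(md == 0, 0, sign(md) * Inf), df = n - 1,
                p = if (md == 0) 1 else NA_real_, mean_diff = md, n = n,
                zero_variance = TRUE))
  }
  tt <- stats::t.test(scores_a[common], scores_b[common], paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = md, n = n, zero_variance = FALSE)
}

#' Per-participant mean peak amplitudes for one condition
#'
#' @param scores Score table from [score_epochs()].
#' @param sel Level selector as in [contrast_spec()] (`outcome`, `rate`,
#'   `cs_label`).
#' @return Named numeric vector of per-participant mean amplitudes.
#' @export
participant_means <- function(scores, sel) {
  keep <- match_level(
    tibble::tibble(outcome = scores$outcome,
                   reinforcement_rate = scores$reinforcement_rate,
                   cs_label = scores$cs_label), sel)
  s <- scores[keep, , drop = FALSE]
  stop_if_not(nrow(s) > 0, "selector matches no scored trials")
  out <- tapply(s$amplitude, s$participant_id, mean)
  stats::setNames(as.numeric(out), names(out))
}
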