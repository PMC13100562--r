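# Readers, writers, configuration and the end-to-end pipeline.

#' Write recordings to a long-format delimited table
#'
#' Columns: `participant`, `study`, `modality`, `time_s`, `value`,
#' `missing`. One row per sample.
#'
#' @param recs List of [recording()] objects.
#' @param path Output file (CSV).
#' @export
write_recordings <- function(recs, path) {
  rows <- lapply(recs, function(r) {
    data.frame(participant = r$participant_id, study = r$study_id,
               modality = r$modality, time_s = rec_times(r),
               value = r$values, missing = r$missing)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
}

#' Read recordings from a long-format delimited table
#'
#' Reads the format written by [write_recordings()]. Rows may appear in any
#' order; each (participant, study, modality) series is sorted by time and
#' checked for uniform sampling. Time stamps must lie on a uniform grid
#' (the most common time step); grid positions without a row are treated as
#' missing samples (the gap rule), and inconsistent time steps raise an
#' error naming the series.
#'
#' @param path Input file.
#' @return Named list of [recording()] objects.
#' @export
read_recordings <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant", "study", "modality", "time_s", "value", "missing")
  stop_if_not(all(need %in% names(df)), "missing columns: %s",
              paste(setdiff(need, names(df)), collapse = ", "))
  stop_if_not(all(df$modality %in% modalities_known),
              "unknown modality in file: %s",
              paste(setdiff(unique(df$modality), modalities_known),
                    collapse = ", "))
  key <- paste(df$participant, df$study, df$modality, sep = "\r")
  out <- lapply(split(df, key), function(g) {
    g <- g[order(g$time_s), , drop = FALSE]
    sid <- sprintf("%s/%s/%s", g$participant[1], g$study[1], g$modality[1])
    stop_if_not(nrow(g) >= 2, "series %s has fewer than 2 samples", sid)
    dts <- diff(g$time_s)
    stop_if_not(all(dts > 0), "non-monotone or duplicate time in series %s", sid)
    dt <- min(dts)
    steps <- dts / dt
    stop_if_not(all(abs(steps - round(steps)) < 1e-6),
                "inconsistent sampling step in series %s", sid)
    n <- round((g$time_s[nrow(g)] - g$time_s[1]) / dt) + 1L
    idx <- round((g$time_s - g$time_s[1]) / dt) + 1L
    vals <- rep(NA_real_, n)
    miss <- rep(TRUE, n)
    vals[idx] <- g$value
    miss[idx] <- as.logical(g$missing)
    # gap samples hold the previous value so the series stays numeric
    if (anyNA(vals)) {
      vals <- stats::approx(idx, g$value, xout = seq_len(n), rule = 2,
                            method = "constant")$y
    }
    recording(g$participant[1], g$study[1], g$modality[1], 1 / dt, vals,
              start_time_s = g$time_s[1], missing = miss)
  })
  names(out) <- vapply(out, function(r) paste(r$participant_id, r$modality,
                                              sep = "_"), character(1))
  out
}

#' Write a trial schedule to a delimited table
#' @param schedule Trial table from [generate_schedule()].
#' @param path Output file (CSV, with header).
#' @export
write_schedule <- function(schedule, path) {
  utils::write.csv(as.data.frame(schedule), path, row.names = FALSE)
}

#' Read a trial schedule written by [write_schedule()]
#' @param path Input file.
#' @return A trial-table tibble.
#' @export
read_schedule <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Convert an epoch matrix to long format (and back)
#'
#' Round-trippable long representation with one row per trial x bin, plus
#' the per-trial labels.
#'
#' @param em An `epoch_matrix`.
#' @return A tibble: trial labels, `bin_time`, `value`, `missing`.
#' @export
epochs_to_long <- function(em) {
  nb <- length(em$bin_times)
  nt <- nrow(em$values)
  lab <- em$trials[rep(seq_len(nt), each = nb), , drop = FALSE]
  tibble::tibble(lab,
                 bin_time = rep(em$bin_times, nt),
                 value = as.numeric(t(em$values)),
                 missing = is.na(as.numeric(t(em$values))))
}

#' Write an epoch matrix
#'
#' Delimited long-format text by default; when `format = "parquet"` (and
#' the arrow package is available) a hierarchical binary container.
#'
#' @param em An `epoch_matrix`.
#' @param path Output file.
#' @param format `"csv"` or `"parquet"`.
#' @export
write_epochs <- function(em, path, format = c("csv", "parquet")) {
  format <- match.arg(format)
  long <- epochs_to_long(em)
  if (format == "parquet") {
    stop_if_not(requireNamespace("arrow", quietly = TRUE),
                "the arrow package is required for parquet output")
    arrow::write_parquet(long, path)
  } else {
    utils::write.csv(as.data.frame(long), path, row.names = FALSE)
  }
  invisible(path)
}

#' Read an epoch matrix written by [write_epochs()]
#'
#' @param path Input file.
#' @param format `"csv"` or `"parquet"`.
#' @param window The [epoch_window()] the matrix was extracted with.
#' @return An `epoch_matrix`.
#' @export
read_epochs <- function(path, format = c("csv", "parquet"), window = NULL) {
  format <- match.arg(format)
  long <- if (format == "parquet") {
    stop_if_not(requireNamespace("arrow", quietly = TRUE),
                "the arrow package is required for parquet input")
    as.data.frame(arrow::read_parquet(path))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  bt <- sort(unique(long$bin_time))
  key <- paste(long$participant_id, long$trial_index, sep = "\r")
  ord <- order(long$participant_id, long$trial_index, long$bin_time)
  long <- long[ord, , drop = FALSE]
  first <- !duplicated(paste(long$participant_id, long$trial_index))
  trials <- tibble::as_tibble(
    long[first, c("participant_id", "study_id", "trial_index", "cs_label",
                  "reinforcement_rate", "outcome", "half", "baseline")])
  vals <- matrix(long$value, ncol = length(bt), byrow = TRUE)
  structure(list(values = vals, bin_times = bt, trials = trials,
                 modality = attr(window, "modality") %||% NA_character_,
                 window = window, baseline_corrected = NA),
            class = "epoch_matrix")
}

#' Write / read a run configuration as structured text (YAML)
#'
#' @param config A [run_config()] (or any list).
#' @param path File path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg[names(cfg) %in% names(formals(run_config))])
}

#' End-to-end pipeline configuration
#'
#' @param design `"dataset1"` (differential, 50% CS+ vs CS-) or
#'   `"dataset2"` (parametric 20/50/80%).
#' @param n_participants Participants to simulate.
#' @param modalities Modalities to simulate and analyse.
#' @param n_perm Permutations per cluster test.
#' @param seed Master seed; determines every output.
#' @param trial_half `"all"` or `"second"` (restrict to the second half of
#'   each session).
#' @param baseline_mode Baseline-correction mode, see [baseline_correct()].
#' @param axiom_policy Direction policy for mixed clusters, see
#'   [direction_of()].
#' @param stat_method Bin statistic for the cluster tests (`"paired"` fast
#'   collapsed statistic or `"lmm"`).
#' @param amplitude_scheme `"observed"` (same-sign omission responses, the
#'   empirical pattern) or `"signed_pe"` (a true signed-PE code), see
#'   [amplitude_map_observed()] / [amplitude_map_signed_pe()].
#' @param fs_hz Synthetic recording rate.
#' @param out_dir Optional output directory; when given, all result tables,
#'   the configuration and the schedule are written there.
#' @return A list with class `run_config`.
#' @export
run_config <- function(design = c("dataset2", "dataset1"),
                       n_participants = NULL,
                       modalities = c("SCR"),
                       n_perm = 1000, seed = 1,
                       trial_half = c("all", "second"),
                       baseline_mode = c("per_participant", "per_trial"),
                       axiom_policy = c("strict", "dominant"),
                       stat_method = c("paired", "lmm"),
                       amplitude_scheme = c("observed", "signed_pe"),
                       fs_hz = 100, out_dir = NULL) {
  design <- match.arg(design)
  trial_half <- match.arg(trial_half)
  baseline_mode <- match.arg(baseline_mode)
  axiom_policy <- match.arg(axiom_policy)
  stat_method <- match.arg(stat_method)
  amplitude_scheme <- match.arg(amplitude_scheme)
  stop_if_not(all(modalities %in% c("SCR", "PSR", "HPR", "RAR")),
              "modalities must be among SCR, PSR, HPR, RAR")
  structure(list(design = design, n_participants = n_participants,
                 modalities = modalities, n_perm = n_perm, seed = seed,
                 trial_half = trial_half, baseline_mode = baseline_mode,
                 axiom_policy = axiom_policy, stat_method = stat_method,
                 amplitude_scheme = amplitude_scheme, fs_hz = fs_hz,
                 out_dir = out_dir),
            class = "run_config")
}

# Default per-modality generator for a pipeline run.
pipeline_gen_params <- function(config, rates) {
  maps <- list()
  sgn <- c(SCR = 1, PSR = 1, RAR = 1, HPR = -1)  # HPR US response: bradycardic axis inverted
  for (m in config$modalities) {
    base <- if (config$amplitude_scheme == "observed") {
      amplitude_map_observed(rates)
    } else {
      amplitude_map_signed_pe(rates)
    }
    base$amplitude <- base$amplitude * sgn[[m]] *
      switch(m, SCR = 0.5, PSR = 0.5, HPR = 0.05, RAR = 0.3)
    maps[[m]] <- base
  }
  gen_params(modalities = config$modalities, amplitude_maps = maps,
             between_subject_sd = 0.3,
             within_subject_sd = c(SCR = 0.25, PSR = 0.25, HPR = 0.025,
                                   RAR = 0.15),
             noise_sd = c(SCR = 0.01, PSR = 0.02, HPR = 0.002, RAR = 0.02),
             baseline_level = c(SCR = 2, PSR = 3, HPR = 1, RAR = 1))
}

preprocess_any <- function(rec, cfg) {
  switch(rec$modality,
         SCR = preprocess_scr(rec, cfg),
         PSR = preprocess_psr(rec, cfg),
         downsample(rec, cfg$target_fs_hz))
}

#' Run the full analysis pipeline
#'
#' Simulates the configured design, preprocesses every modality to 10 Hz,
#' cuts baseline-corrected outcome-locked epochs, runs the full contrast
#' battery with cluster-based permutation tests, evaluates the signed and
#' unsigned prediction-error conditions per modality, and computes peak
#' scores with paired comparisons for SCR/PSR. Any modality may fail
#' independently; failures are recorded in the bundle rather than aborting
#' the run. All time intervals are reported both relative to US onset and
#' relative to CS onset.
#'
#' @param config A [run_config()].
#' @return A list with class `pipeline_result`: `config`, `schedule`,
#'   `results` (cluster-table tibble across modalities and contrasts),
#'   `verdicts` (per-modality `axiom_verdict`), `peak_tests`, `failed`
#'   (named character of per-modality errors).
#' @export
run_pipeline <- function(config = run_config()) {
  design <- switch(config$design,
                   dataset1 = dataset1_design(
                     n_participants = config$n_participants %||% 30,
                     fs_hz = config$fs_hz),
                   dataset2 = dataset2_design(
                     n_participants = config$n_participants %||% 29,
                     fs_hz = config$fs_hz))
  dataset_no <- if (config$design == "dataset1") 1 else 2
  rates <- unique(vapply(design$cs_conditions, `[[`, numeric(1),
                         "reinforcement_rate"))
  params <- pipeline_gen_params(config, rates)
  sched <- generate_schedule(design, seed = config$seed)
  recs <- generate_recordings(sched, params, seed = config$seed + 1)
  cfg <- qa_config()
  contrasts <- table_contrasts(dataset_no)
  us_offset <- design$us_onset_s

  results <- list(); verdicts <- list(); peak_tests <- list()
  failed <- character()
  for (m in config$modalities) {
    res_m <- tryCatch({
      mrecs <- Filter(function(x) x$modality == m, recs)
      ems <- lapply(mrecs, function(rec) {
        extract_epochs(preprocess_any(rec, cfg), sched, epoch_window(m))
      })
      em <- baseline_correct(bind_epochs(ems), config$baseline_mode)
      if (config$trial_half == "second") em <- filter_half(em, "second")
      tests <- lapply(contrasts, function(con) {
        cluster_test(em, con, n_perm = config$n_perm, seed = config$seed + 7,
                     method = config$stat_method)
      })
      tab <- do.call(rbind, lapply(names(tests), function(nm) {
        cl <- tests[[nm]]$clusters
        if (nrow(cl) == 0) {
          return(tibble::tibble(modality = m, contrast = nm, sign = NA_character_,
                                mass = NA_real_, p_cluster = NA_real_,
                                start_post_us_s = NA_real_, end_post_us_s = NA_real_,
                                start_post_cs_s = NA_real_, end_post_cs_s = NA_real_))
        }
        tibble::tibble(modality = m, contrast = nm, sign = cl$sign,
                       mass = cl$mass, p_cluster = cl$p_cluster,
                       start_post_us_s = cl$start_s,
                       end_post_us_s = cl$end_s + 0.1,
                       start_post_cs_s = cl$start_s + us_offset,
                       end_post_cs_s = cl$end_s + 0.1 + us_offset)
      }))
      outcomes <- contrast_outcomes(tests, policy = config$axiom_policy)
      verdict <- evaluate_axioms(outcomes, modality = m,
                                 response_sign = if (m == "HPR") -1 else 1)
      pk <- NULL
      if (m %in% c("SCR", "PSR")) {
        pw <- if (m == "SCR") epoch_window(m, start_s = 1, end_s = 10)
              else epoch_window(m, start_s = -1, end_s = 4)
        pems <- lapply(mrecs, function(rec) {
          r2 <- rec; attr(r2, "processed") <- NULL
          extract_epochs(preprocess_any(r2, cfg), sched, pw)
        })
        scores <- score_epochs(bind_epochs(pems), m)
        pk <- lapply(contrasts, function(con) {
          tryCatch(paired_compare(participant_means(scores, con$level_a),
                                  participant_means(scores, con$level_b)),
                   error = function(e) NULL)
        })
      }
      list(tab = tab, verdict = verdict, peaks = pk)
    }, error = function(e) e)
    if (inherits(res_m, "error")) {
      failed[m] <- conditionMessage(res_m)
    } else {
      results[[m]] <- res_m$tab
      verdicts[[m]] <- res_m$verdict
      peak_tests[[m]] <- res_m$peaks
    }
  }
  bundle <- structure(list(config = config, schedule = sched,
                           results = do.call(rbind, results),
                           verdicts = verdicts, peak_tests = peak_tests,
                           failed = failed),
                      class = "pipeline_result")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_config(config, file.path(config$out_dir, "config.yaml"))
    write_schedule(sched, file.path(config$out_dir, "schedule.csv"))
    if (!is.null(bundle$results)) {
      utils::write.csv(as.data.frame(bundle$results),
                       file.path(config$out_dir, "cluster_results.csv"),
                       row.names = FALSE)
    }
    vlines <- unlist(lapply(bundle$verdicts, function(v) {
      c(sprintf("== %s ==", v$modality), v$rationale, "")
    }))
    writeLines(vlines %||% character(),
               file.path(config$out_dir, "axiom_verdicts.txt"))
  }
  bundle
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %s, %d modalities, seed %d\n",
              x$config$design, length(x$verdicts), x$config$seed))
  for (v in x$verdicts) {
    cat(sprintf("  %s: signed %s | C1 %s C2 %s C3 %s\n", v$modality,
                v$signed_consistent, v$c1, v$c2, v$c3))
  }
  if (length(x$failed)) {
    cat("  failed:", paste(names(x$failed), collapse = ", "), "\n")
  }
  invisible(x)
}
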