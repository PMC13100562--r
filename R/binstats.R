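# Per-0.1-s-bin condition contrasts: linear mixed-effects models with
# participant (optionally nested in study) random intercepts, plus a fast
# collapsed within-participant statistic used during permutations.

#' Define a condition contrast
#'
#' A contrast compares two disjoint sets of trials (levels) selected by
#' outcome, reinforcement rate and/or CS label.
#'
#' @param name Human-readable contrast name, e.g. `"US+ (50%) vs US- (50%)"`.
#' @param level_a,level_b Selector lists with any of `outcome`, `rate`,
#'   `cs_label`; a trial belongs to a level iff all stated fields match.
#'   The reported effect is `level_a - level_b`.
#' @param grouping `"participant"` for `(1 | ppid)` or
#'   `"study_nested_participant"` for `(1 | study/ppid)` random intercepts.
#' @param covariates Subset of `"baseline"`; adds the per-trial pre-US
#'   baseline as a fixed covariate.
#' @param type,meta Optional metadata used by the axiom evaluator
#'   (`type` is `"A1"` or `"A2"`, `meta` carries rates/outcome).
#' @return A list with class `contrast_spec`.
#' @export
contrast_spec <- function(name, level_a, level_b,
                          grouping = c("participant", "study_nested_participant"),
                          covariates = character(), type = NULL, meta = NULL) {
  grouping <- match.arg(grouping)
  stop_if_not(all(covariates %in% "baseline"), "unknown covariate")
  structure(list(name = name, level_a = level_a, level_b = level_b,
                 grouping = grouping, covariates = covariates,
                 type = type, meta = meta),
            class = "contrast_spec")
}

# Logical selector over the trial-label table.
match_level <- function(trials, sel) {
  keep <- rep(TRUE, nrow(trials))
  if (!is.null(sel$outcome)) keep <- keep & trials$outcome == sel$outcome
  if (!is.null(sel$rate)) {
    keep <- keep & abs(trials$reinforcement_rate - sel$rate) < 1e-9
  }
  if (!is.null(sel$cs_label)) keep <- keep & trials$cs_label == sel$cs_label
  keep
}

# Subset an epoch matrix to a contrast's trials; adds .level ("a"/"b").
contrast_subset <- function(em, contrast) {
  in_a <- match_level(em$trials, contrast$level_a)
  in_b <- match_level(em$trials, contrast$level_b)
  stop_if_not(!any(in_a & in_b), "contrast levels overlap")
  stop_if_not(any(in_a) && any(in_b), "a contrast level selects no trials")
  keep <- in_a | in_b
  list(values = em$values[keep, , drop = FALSE],
       trials = em$trials[keep, , drop = FALSE],
       level = ifelse(in_a[keep], "a", "b"),
       bin_times = em$bin_times)
}

#' Standard axiomatic contrasts for a design
#'
#' The contrast battery for the axiomatic analysis. For the differential
#' design (`dataset = 1`): outcome-magnitude test US+ (50%) vs US- (50%)
#' (study/participant nesting) and outcome-probability test US- (0%) vs
#' US- (50%). For the parametric design (`dataset = 2`): US+ vs US- at each
#' of 20/50/80%, and all same-outcome probability contrasts, each oriented
#' with the lower reinforcement rate as `level_a`.
#'
#' @param dataset 1 or 2.
#' @return Named list of [contrast_spec()] objects.
#' @export
table_contrasts <- function(dataset) {
  if (dataset == 1) {
    list(
      "A1: US+ (50%) vs US- (50%)" = contrast_spec(
        "A1: US+ (50%) vs US- (50%)",
        level_a = list(outcome = "US+", rate = 0.5),
        level_b = list(outcome = "US-", rate = 0.5),
        grouping = "study_nested_participant",
        type = "A1", meta = list(rate = 0.5)),
      "A2: US- (0%) vs US- (50%)" = contrast_spec(
        "A2: US- (0%) vs US- (50%)",
        level_a = list(outcome = "US-", rate = 0.0),
        level_b = list(outcome = "US-", rate = 0.5),
        grouping = "study_nested_participant",
        type = "A2", meta = list(outcome = "US-", rate_a = 0.0, rate_b = 0.5)))
  } else if (dataset == 2) {
    rates <- c(0.2, 0.5, 0.8)
    out <- list()
    for (r in rates) {
      nm <- sprintf("A1: US+ (%d%%) vs US- (%d%%)", r * 100, r * 100)
      out[[nm]] <- contrast_spec(
        nm, level_a = list(outcome = "US+", rate = r),
        level_b = list(outcome = "US-", rate = r),
        grouping = "participant", type = "A1", meta = list(rate = r))
    }
    pairs <- utils::combn(rates, 2)
    for (oc in c("US+", "US-")) {
      for (j in seq_len(ncol(pairs))) {
        ra <- pairs[1, j]; rb <- pairs[2, j]
        nm <- sprintf("A2: %s (%d%%) vs %s (%d%%)", oc, ra * 100, oc, rb * 100)
        out[[nm]] <- contrast_spec(
          nm, level_a = list(outcome = oc, rate = ra),
          level_b = list(outcome = oc, rate = rb),
          grouping = "participant", type = "A2",
          meta = list(outcome = oc, rate_a = ra, rate_b = rb))
      }
    }
    out
  } else {
    stop("dataset must be 1 or 2", call. = FALSE)
  }
}

# Fast collapsed statistic, vectorised over bins: per-participant condition
# mean difference, then a one-sample t across participants. Split into a
# preparation step (NA handling, grouping factor) and the per-relabelling
# statistic so the permutation loop pays no repeated setup cost.
paired_prep <- function(values, participant) {
  v0 <- values
  nn <- !is.na(values)
  v0[!nn] <- 0
  list(v0 = v0, nn = nn * 1, pidf = factor(participant))
}

paired_stat <- function(prep, a_ind) {
  sa <- rowsum(prep$v0 * a_ind, prep$pidf)
  ca <- rowsum(prep$nn * a_ind, prep$pidf)
  b_ind <- 1 - a_ind
  sb <- rowsum(prep$v0 * b_ind, prep$pidf)
  cb <- rowsum(prep$nn * b_ind, prep$pidf)
  d <- sa / ca - sb / cb
  d[ca == 0 | cb == 0] <- NA_real_
  mo <- col_moments(d)
  tstat <- mo$mean / (mo$sd / sqrt(mo$n))
  tstat[!is.finite(tstat)] <- NA_real_
  p <- 2 * stats::pt(-abs(tstat), pmax(mo$n - 1, 1))
  list(estimate = mo$mean, statistic = tstat, p = p, n = mo$n)
}

paired_bin_stats <- function(values, participant, level) {
  paired_stat(paired_prep(values, participant), (level == "a") * 1)
}

# Fit one bin with lme4; returns estimate, Wald statistic, p, n, fallback.
# Fallback chain: nested model -> participant-only model -> OLS.
fit_bin_lmm <- function(df, grouping, covariates) {
  rhs <- "condition"
  if ("baseline" %in% covariates) rhs <- paste(rhs, "+ baseline")
  fit_one <- function(level) {
    form <- switch(level,
      nested = stats::as.formula(paste(
        "value ~", rhs, "+ (1 | study_id) + (1 | study_id:participant_id)")),
      ppt = stats::as.formula(paste("value ~", rhs, "+ (1 | participant_id)")),
      ols = stats::as.formula(paste("value ~", rhs)))
    if (level == "ols") {
      m <- stats::lm(form, data = df)
      co <- summary(m)$coefficients["conditiona", ]
      return(list(est = co[1], stat = co[3], p = co[4], singular = FALSE))
    }
    m <- suppressMessages(suppressWarnings(
      lme4::lmer(form, data = df, REML = TRUE,
                 control = lme4::lmerControl(calc.derivs = FALSE,
                                             check.conv.singular = "ignore"))))
    co <- summary(m)$coefficients["conditiona", ]
    z <- co[1] / co[2]
    list(est = co[1], stat = z, p = 2 * stats::pnorm(-abs(z)),
         singular = lme4::isSingular(m, tol = 1e-5))
  }
  chain <- if (grouping == "study_nested_participant") {
    c("nested", "ppt", "ols")
  } else {
    c("ppt", "ols")
  }
  for (k in seq_along(chain)) {
    res <- tryCatch(fit_one(chain[k]), error = function(e) NULL)
    if (!is.null(res) && (!res$singular || chain[k] == "ols")) {
      return(list(estimate = unname(res$est), statistic = unname(res$stat),
                  p = unname(res$p), fallback = k - 1L))
    }
  }
  list(estimate = NA_real_, statistic = NA_real_, p = NA_real_,
       fallback = length(chain))
}

#' Fit the contrast model in a single time bin
#'
#' Fits a random-intercept linear mixed-effects model
#' `value ~ condition (+ baseline) + (1 | ppid)` (or `(1 | study/ppid)`,
#' realised as study plus participant-within-study variance components) by
#' REML for one 0.1-s bin, and returns the condition fixed effect
#' (`level_a - level_b`), its Wald z statistic and two-sided normal p-value.
#' Missing cells are excluded, not imputed. Singular or failed fits fall
#' back to the model without the study intercept and then to ordinary least
#' squares (with a t-based p); the fallback level is recorded.
#'
#' @param em An `epoch_matrix`.
#' @param contrast A [contrast_spec()].
#' @param bin_index Bin to fit (1-based).
#' @return A list: `estimate`, `statistic`, `p`, `n_obs`, `fallback`
#'   (0 = requested model, higher = fallback depth).
#' @export
fit_bin <- function(em, contrast, bin_index) {
  cs <- contrast_subset(em, contrast)
  y <- cs$values[, bin_index]
  ok <- !is.na(y)
  df <- data.frame(value = y[ok],
                   condition = factor(cs$level[ok], levels = c("b", "a")),
                   participant_id = cs$trials$participant_id[ok],
                   study_id = cs$trials$study_id[ok],
                   baseline = cs$trials$baseline[ok])
  stop_if_not(nlevels(droplevels(df$condition)) == 2,
              "a contrast level has no data in this bin")
  stop_if_not(length(unique(df$participant_id)) >= 2,
              "need at least 2 participants")
  res <- fit_bin_lmm(df, contrast$grouping, contrast$covariates)
  res$n_obs <- nrow(df)
  res
}

#' Fit the contrast model in every time bin
#'
#' Applies the bin-level model across the whole response window. With
#' `method = "lmm"` each bin is fit with [fit_bin()]; with
#' `method = "paired"` the fast collapsed statistic is used (per-participant
#' condition-mean difference tested across participants), which is the
#' statistic the permutation engine uses. Bins where fewer than two
#' participants have data in both levels are marked absent (`NA`), not zero.
#'
#' @param em An `epoch_matrix`.
#' @param contrast A [contrast_spec()].
#' @param method `"lmm"` or `"paired"`.
#' @return A `bin_stats` tibble: `bin_index`, `bin_time`, `estimate`,
#'   `statistic`, `p`, `n`, `fallback`.
#' @export
fit_all_bins <- function(em, contrast, method = c("lmm", "paired")) {
  method <- match.arg(method)
  nb <- length(em$bin_times)
  if (method == "paired") {
    cs <- contrast_subset(em, contrast)
    st <- paired_bin_stats(cs$values, cs$trials$participant_id, cs$level)
    out <- tibble::tibble(bin_index = seq_len(nb), bin_time = em$bin_times,
                          estimate = st$estimate, statistic = st$statistic,
                          p = st$p, n = st$n, fallback = NA_integer_)
  } else {
    rows <- lapply(seq_len(nb), function(b) {
      r <- tryCatch(fit_bin(em, contrast, b), error = function(e) NULL)
      if (is.null(r)) {
        list(estimate = NA_real_, statistic = NA_real_, p = NA_real_,
             n_obs = 0L, fallback = NA_integer_)
      } else r
    })
    out <- tibble::tibble(
      bin_index = seq_len(nb), bin_time = em$bin_times,
      estimate = vapply(rows, `[[`, numeric(1), "estimate"),
      statistic = vapply(rows, `[[`, numeric(1), "statistic"),
      p = vapply(rows, `[[`, numeric(1), "p"),
      n = vapply(rows, function(r) as.integer(r$n_obs), integer(1)),
      fallback = vapply(rows, function(r) as.integer(r$fallback %||% NA),
                        integer(1)))
    stop_if_not(mean(is.na(out$p)) <= 0.5, "more than half of the bins failed")
  }
  class(out) <- c("bin_stats", class(out))
  attr(out, "contrast") <- contrast$name
  attr(out, "method") <- method
  out
}
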