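# Axiomatic evaluation of signed and unsigned prediction-error encoding.
#
# A physiological signal that monotonically encodes a *signed* prediction
# error (outcome minus expectation) must satisfy two testable directional
# axioms: the US-vs-omission contrast at fixed probability (A1) must be
# unidirectional, and every probability contrast (A2, oriented with the
# lower reinforcement rate as level_a) must point the same way as A1,
# because both US responses (PE = 1 - rate) and omission responses
# (PE = -rate) grow as the rate falls. An *unsigned* (surprise) code instead
# requires larger responses for less expected outcomes (C1), equal US and
# omission responses at 50% (C2), and maximal US responses at 20% with
# maximal omission responses at 80% (C3). The third signed axiom and its
# unsigned counterpart (no response to a fully predicted US) are untestable
# without a 100% reinforced condition and are reported as such.

axiom_directions <- c("a_greater", "b_greater", "mixed", "null")

#' Direction label of a contrast from its clusters
#'
#' Maps the signs of significant clusters to a direction: only positive
#' clusters mean `level_a` responded more (`"a_greater"`), only negative
#' clusters `"b_greater"`, clusters of both signs `"mixed"` (under the
#' default strict policy) and no significant clusters `"null"`. Under the
#' `"dominant"` policy a mixed result is resolved by the sign of the
#' largest-magnitude cluster.
#'
#' @param clusters Cluster tibble with `p_cluster` (from [cluster_p()] or
#'   [cluster_test()]).
#' @param alpha Cluster-level significance threshold.
#' @param policy `"strict"` or `"dominant"`.
#' @return One of `"a_greater"`, `"b_greater"`, `"mixed"`, `"null"`.
#' @export
direction_of <- function(clusters, alpha = 0.05,
                         policy = c("strict", "dominant")) {
  policy <- match.arg(policy)
  if (is.null(clusters) || nrow(clusters) == 0) return("null")
  sig <- clusters[clusters$p_cluster <= alpha, , drop = FALSE]
  if (nrow(sig) == 0) return("null")
  signs <- unique(sig$sign)
  if (length(signs) == 1) {
    return(if (signs == "+") "a_greater" else "b_greater")
  }
  if (policy == "dominant") {
    dom <- sig$sign[which.max(abs(sig$mass))]
    return(if (dom == "+") "a_greater" else "b_greater")
  }
  "mixed"
}

flip_direction <- function(d) {
  vapply(d, function(x) switch(x, a_greater = "b_greater",
                               b_greater = "a_greater", x),
         character(1), USE.NAMES = FALSE)
}

# Combine several same-type directions (e.g. the three A1 contrasts of the
# parametric design) into one: agreement wins, disagreement is mixed.
combine_directions <- function(dirs) {
  dirs <- dirs[dirs != "null"]
  if (length(dirs) == 0) return("null")
  if ("mixed" %in% dirs) return("mixed")
  u <- unique(dirs)
  if (length(u) == 1) u else "mixed"
}

#' Evaluate the signed prediction-error axioms
#'
#' A modality is consistent with signed PE encoding iff A1 (US vs omission
#' at fixed probability) is significant and unidirectional, and every
#' non-null probability contrast (A2, lower rate as `level_a`) points in the
#' same direction as A1: with larger US responses, both US and omission
#' responses must fall as the reinforcement rate rises (and mirrored when
#' the US response is a decrease, as for heart period). Any contradiction
#' or any mixed direction is inconsistent; a null A1, or all-null A2, is
#' indeterminate.
#'
#' @param a1_direction Direction of the A1 contrast (combined across rates
#'   if several; see [combine_directions()]).
#' @param a2_directions Character vector of A2 contrast directions, each
#'   oriented with the lower reinforcement rate as `level_a`.
#' @return `"consistent"`, `"inconsistent"` or `"indeterminate"`.
#' @export
evaluate_signed <- function(a1_direction, a2_directions) {
  stop_if_not(a1_direction %in% axiom_directions, "unknown A1 direction")
  stop_if_not(length(a2_directions) >= 1 &&
                all(a2_directions %in% axiom_directions),
              "A2 directions missing or unknown")
  if (a1_direction == "null") return("indeterminate")
  if (a1_direction == "mixed") return("inconsistent")
  active <- a2_directions[a2_directions != "null"]
  if (length(active) == 0) return("indeterminate")
  if (all(active == a1_direction)) "consistent" else "inconsistent"
}

# Shared verdict logic for the unsigned conditions: given required
# directions for a set of available contrasts, a wrong-direction (or mixed)
# significant result violates; all requirements met satisfies; anything
# less (nulls, missing contrasts) is indeterminate.
unsigned_verdict <- function(observed, required) {
  if (length(required) == 0) return("indeterminate")
  avail <- names(required) %in% names(observed)
  obs <- observed[names(required)[avail]]
  req <- required[avail]
  if (length(obs) > 0 &&
      any(obs != "null" & obs != req)) return("violated")
  if (all(avail) && length(obs) > 0 && all(obs == req)) return("satisfied")
  "indeterminate"
}

#' Evaluate the unsigned prediction-error (surprise) conditions
#'
#' Takes the table of contrast outcomes and checks: C1 - at 20% the US
#' response must exceed the omission response and at 80% the reverse; C2 -
#' the 50% US-vs-omission contrast must be null; C3 - US responses must be
#' maximal at 20% (both 20%-anchored probability contrasts significant with
#' the lower rate larger) and omission responses maximal at 80%. For
#' modalities whose US response is a signal decrease (heart period), set
#' `response_sign = -1` so "larger response" reads as larger in the
#' response direction. Contrasts that the design does not afford leave the
#' condition indeterminate.
#'
#' @param outcomes Tibble of contrast outcomes as built by
#'   [contrast_outcomes()].
#' @param response_sign `+1` (default) if the modality's US response is a
#'   signal increase, `-1` if a decrease.
#' @return Named character vector with `c1`, `c2`, `c3`, each
#'   `"satisfied"`, `"violated"` or `"indeterminate"`.
#' @export
evaluate_unsigned <- function(outcomes, response_sign = 1) {
  dirs <- outcomes$direction
  if (response_sign < 0) dirs <- flip_direction(dirs)
  names(dirs) <- outcomes$name

  a1 <- outcomes[outcomes$type == "A1", , drop = FALSE]
  a1_dirs <- dirs[a1$name]
  names(a1_dirs) <- sprintf("%.2f", a1$rate)

  req_c1 <- c()
  if ("0.20" %in% names(a1_dirs)) req_c1["0.20"] <- "a_greater"
  if ("0.80" %in% names(a1_dirs)) req_c1["0.80"] <- "b_greater"
  c1 <- unsigned_verdict(a1_dirs, req_c1)

  c2 <- if (!"0.50" %in% names(a1_dirs)) {
    "indeterminate"
  } else if (a1_dirs[["0.50"]] == "null") "satisfied" else "violated"

  a2 <- outcomes[outcomes$type == "A2", , drop = FALSE]
  a2_dirs <- dirs[a2$name]
  req_c3 <- c()
  for (i in seq_len(nrow(a2))) {
    nm <- a2$name[i]
    if (a2$outcome[i] == "US+" && abs(a2$rate_a[i] - 0.2) < 1e-9) {
      req_c3[nm] <- "a_greater"   # 20% US+ maximal
    }
    if (a2$outcome[i] == "US-" && abs(a2$rate_b[i] - 0.8) < 1e-9) {
      req_c3[nm] <- "b_greater"   # 80% omission maximal
    }
  }
  c3 <- unsigned_verdict(a2_dirs, req_c3)

  c(c1 = c1, c2 = c2, c3 = c3)
}

#' Tabulate contrast outcomes for the axiom evaluator
#'
#' Builds the per-contrast outcome table (direction plus the contrast
#' metadata the evaluator needs) from a named list of [cluster_test()]
#' results.
#'
#' @param tests Named list of `cluster_test` objects whose contrasts carry
#'   `type`/`meta` metadata (as from [table_contrasts()]).
#' @param alpha Cluster-level significance threshold.
#' @param policy Direction policy, see [direction_of()].
#' @return A tibble with `name`, `type`, `rate` (A1), `outcome`, `rate_a`,
#'   `rate_b` (A2), `direction`, `n_sig_clusters`.
#' @export
contrast_outcomes <- function(tests, alpha = 0.05,
                              policy = c("strict", "dominant")) {
  policy <- match.arg(policy)
  rows <- lapply(tests, function(ct) {
    con <- ct$contrast
    tibble::tibble(
      name = con$name,
      type = con$type %||% NA_character_,
      rate = con$meta$rate %||% NA_real_,
      outcome = con$meta$outcome %||% NA_character_,
      rate_a = con$meta$rate_a %||% NA_real_,
      rate_b = con$meta$rate_b %||% NA_real_,
      direction = direction_of(ct$clusters, alpha, policy),
      n_sig_clusters = sum(ct$clusters$p_cluster <= alpha))
  })
  do.call(rbind, rows)
}

#' Full axiomatic verdict for one modality
#'
#' Combines the contrast outcomes into the per-modality verdict: the A1
#' direction, all A2 directions, the signed-PE consistency flag, the
#' unsigned conditions C1-C3, and the untestable third axiom / fourth
#' condition (no 100% reinforced condition exists in either design).
#'
#' @param outcomes Contrast-outcome tibble from [contrast_outcomes()].
#' @param modality Modality label carried into the verdict.
#' @param response_sign See [evaluate_unsigned()].
#' @return A list with class `axiom_verdict`.
#' @export
evaluate_axioms <- function(outcomes, modality = "SCR", response_sign = 1) {
  a1_rows <- outcomes[outcomes$type == "A1", , drop = FALSE]
  a2_rows <- outcomes[outcomes$type == "A2", , drop = FALSE]
  stop_if_not(nrow(a1_rows) >= 1 && nrow(a2_rows) >= 1,
              "outcomes must contain A1 and A2 contrasts")
  a1 <- combine_directions(a1_rows$direction)
  a2 <- stats::setNames(a2_rows$direction, a2_rows$name)
  signed <- evaluate_signed(a1, a2)
  unsigned <- evaluate_unsigned(outcomes, response_sign)
  rationale <- c(
    sprintf("A1 direction: %s (%d contrast(s))", a1, nrow(a1_rows)),
    sprintf("A2 directions: %s", paste(a2, collapse = ", ")),
    sprintf("signed verdict: %s", signed),
    sprintf("unsigned: C1 %s, C2 %s, C3 %s",
            unsigned["c1"], unsigned["c2"], unsigned["c3"]))
  structure(list(modality = modality,
                 a1_direction = a1,
                 a2_directions = a2,
                 signed_consistent = switch(signed,
                                            consistent = "consistent",
                                            inconsistent = "inconsistent",
                                            "indeterminate"),
                 c1 = unname(unsigned["c1"]), c2 = unname(unsigned["c2"]),
                 c3 = unname(unsigned["c3"]),
                 a3 = "not testable", c4 = "not testable",
                 response_sign = response_sign,
                 outcomes = outcomes,
                 rationale = rationale),
            class = "axiom_verdict")
}

#' @export
print.axiom_verdict <- function(x, ...) {
  cat(sprintf("<axiom_verdict> %s\n", x$modality))
  cat(sprintf("  signed PE: %s (A1 %s)\n", x$signed_consistent, x$a1_direction))
  for (nm in names(x$a2_directions)) {
    cat(sprintf("    %s: %s\n", nm, x$a2_directions[[nm]]))
  }
  cat(sprintf("  unsigned PE: C1 %s | C2 %s | C3 %s | C4 %s\n",
              x$c1, x$c2, x$c3, x$c4))
  cat(sprintf("  A3: %s\n", x$a3))
  invisible(x)
}
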