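# Cluster-based permutation inference over bin-wise statistics.
#
# Contiguous runs of sub-threshold-p bins with a common statistic sign form
# clusters; the cluster mass (sum of bin statistics) is compared against a
# null distribution of maximum absolute masses obtained by re-labelling
# condition labels across trials *within* each participant (preserving the
# participant and study structure), with the same re-labelling applied to
# every time bin.

#' Form clusters from bin-wise statistics
#'
#' Maximal runs of temporally contiguous bins with `p < alpha_inclusion`
#' (strict) and a common statistic sign. Absent bins (`NA`) break
#' contiguity. The cluster mass is the sum of the member bin statistics.
#'
#' @param bs A `bin_stats` tibble from [fit_all_bins()].
#' @param alpha_inclusion Bin inclusion threshold (default 0.05).
#' @return A tibble of clusters: `start_bin`, `end_bin` (inclusive),
#'   `start_s`, `end_s` (bin times), `sign` (`"+"`/`"-"`), `mass`,
#'   `n_bins`. Zero rows when no bin crosses the threshold.
#' @export
form_clusters <- function(bs, alpha_inclusion = 0.05) {
  ok <- !is.na(bs$p) & bs$p < alpha_inclusion & !is.na(bs$statistic)
  sgn <- ifelse(ok, sign(bs$statistic), 0)
  # new run whenever inclusion status or sign changes, or bins not adjacent
  brk <- c(TRUE, diff(bs$bin_index) != 1L | diff(sgn) != 0)
  run <- cumsum(brk)
  keep <- which(ok)
  if (length(keep) == 0) {
    return(tibble::tibble(start_bin = integer(), end_bin = integer(),
                          start_s = numeric(), end_s = numeric(),
                          sign = character(), mass = numeric(),
                          n_bins = integer()))
  }
  out <- lapply(split(keep, run[keep]), function(i) {
    tibble::tibble(start_bin = bs$bin_index[min(i)],
                   end_bin = bs$bin_index[max(i)],
                   start_s = bs$bin_time[min(i)],
                   end_s = bs$bin_time[max(i)],
                   sign = if (sgn[i[1]] > 0) "+" else "-",
                   mass = sum(bs$statistic[i]),
                   n_bins = length(i))
  })
  do.call(rbind, out)
}

# Lean max |cluster mass| from raw statistic/p vectors (no table
# construction; used inside the permutation loop).
max_abs_cluster_mass <- function(statistic, p, alpha) {
  ok <- !is.na(p) & p < alpha & !is.na(statistic)
  if (!any(ok)) return(0)
  sgn <- ifelse(ok, sign(statistic), 0)
  run <- cumsum(c(TRUE, diff(sgn) != 0))
  masses <- vapply(split(which(ok), run[ok]),
                   function(i) sum(statistic[i]), numeric(1))
  max(abs(masses))
}

# All within-participant relabellings (distinct label vectors) for the
# exhaustive null; returns a list of level vectors.
enumerate_relabellings <- function(participant, level, max_total = 2e5) {
  pid <- factor(participant)
  per <- lapply(levels(pid), function(p) {
    idx <- which(pid == p)
    na <- sum(level[idx] == "a")
    utils::combn(length(idx), na, simplify = FALSE)
  })
  total <- prod(vapply(per, length, numeric(1)))
  stop_if_not(total <= max_total,
              "exhaustive enumeration too large (%g relabellings)", total)
  grid <- expand.grid(lapply(per, seq_along))
  idx_by_p <- split(seq_along(participant), pid)
  lapply(seq_len(nrow(grid)), function(g) {
    lev <- rep("b", length(level))
    for (j in seq_along(per)) {
      lev[idx_by_p[[j]][per[[j]][[grid[g, j]]]]] <- "a"
    }
    lev
  })
}

#' Build the permutation null distribution
#'
#' For each permutation, condition labels are shuffled across trials within
#' each participant (the same re-labelling applied to every bin), the
#' bin-wise statistics are recomputed with the fast collapsed statistic (or
#' the full mixed model when `method = "lmm"`), clusters are formed, and the
#' maximum absolute cluster mass is recorded (0 when no cluster forms).
#' The absolute maximum pools both signs, controlling the family-wise error
#' across both directions. With `exhaustive = TRUE` all distinct
#' within-participant relabellings are enumerated instead of sampled.
#'
#' @param em An `epoch_matrix`.
#' @param contrast A [contrast_spec()].
#' @param n_perm Number of permutations (default 1000; below 100 a warning
#'   is issued).
#' @param seed Integer seed.
#' @param alpha_inclusion Bin inclusion threshold.
#' @param method Bin statistic used throughout: `"paired"` (fast, default)
#'   or `"lmm"`.
#' @param exhaustive Enumerate all relabellings instead of sampling.
#' @return A list with class `perm_null`: `max_mass` (one per permutation),
#'   `n_perm`, `seed`, `exhaustive`.
#' @export
build_null <- function(em, contrast, n_perm = 1000, seed = 1,
                       alpha_inclusion = 0.05,
                       method = c("paired", "lmm"), exhaustive = FALSE) {
  method <- match.arg(method)
  cs <- contrast_subset(em, contrast)
  pid <- factor(cs$trials$participant_id)
  idx_by_p <- split(seq_along(cs$level), pid)

  max_mass_of <- if (method == "paired") {
    prep <- paired_prep(cs$values, cs$trials$participant_id)
    function(lev) {
      st <- paired_stat(prep, (lev == "a") * 1)
      max_abs_cluster_mass(st$statistic, st$p, alpha_inclusion)
    }
  } else {
    relabel_fit <- function(lev) {
      em2 <- em
      keep <- match_level(em$trials, contrast$level_a) |
        match_level(em$trials, contrast$level_b)
      em2$values <- em$values[keep, , drop = FALSE]
      em2$trials <- em$trials[keep, , drop = FALSE]
      # rewrite the outcome/rate/cs labels so the contrast selectors pick up
      # the permuted assignment
      sel <- function(which) if (which == "a") contrast$level_a else contrast$level_b
      for (f in c("outcome", "rate", "cs_label")) {
        va <- sel("a")[[f]]; vb <- sel("b")[[f]]
        col <- if (f == "rate") "reinforcement_rate" else f
        if (!is.null(va)) em2$trials[[col]][lev == "a"] <- va
        if (!is.null(vb)) em2$trials[[col]][lev == "b"] <- vb
      }
      fit_all_bins(em2, contrast, method = "lmm")
    }
    function(lev) {
      bs <- relabel_fit(lev)
      max_abs_cluster_mass(bs$statistic, bs$p, alpha_inclusion)
    }
  }

  if (exhaustive) {
    labs <- enumerate_relabellings(cs$trials$participant_id, cs$level)
    mm <- vapply(labs, max_mass_of, numeric(1))
    return(structure(list(max_mass = mm, n_perm = length(mm), seed = NA,
                          exhaustive = TRUE, alpha_inclusion = alpha_inclusion),
                     class = "perm_null"))
  }
  if (n_perm < 100) warning("n_perm < 100: permutation p-values are coarse")
  mm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      lev <- cs$level
      for (ip in idx_by_p) lev[ip] <- lev[ip][sample.int(length(ip))]
      max_mass_of(lev)
    }, numeric(1))
  })
  structure(list(max_mass = mm, n_perm = n_perm, seed = seed,
                 exhaustive = FALSE, alpha_inclusion = alpha_inclusion),
            class = "perm_null")
}

#' Assign permutation p-values to clusters
#'
#' For sampled nulls, `p = (1 + #\{null >= |mass|\}) / (1 + n_perm)` (the
#' add-one correction guarantees `p > 0` and is exact under
#' exchangeability). For exhaustive nulls the identity re-labelling is part
#' of the enumeration, so `p = #\{null >= |mass|\} / n_enumerated`.
#'
#' @param clusters Cluster tibble from [form_clusters()].
#' @param null A `perm_null` from [build_null()].
#' @return The cluster tibble with a `p_cluster` column.
#' @export
cluster_p <- function(clusters, null) {
  stop_if_not(inherits(null, "perm_null") && length(null$max_mass) > 0,
              "empty permutation null")
  pc <- vapply(clusters$mass, function(m) {
    hits <- sum(null$max_mass >= abs(m))
    if (isTRUE(null$exhaustive)) hits / length(null$max_mass)
    else (1 + hits) / (1 + null$n_perm)
  }, numeric(1))
  clusters$p_cluster <- pc
  clusters
}

#' Cluster-based permutation test of a condition contrast
#'
#' Convenience wrapper: computes the observed bin-wise statistics, forms
#' clusters, builds the within-participant permutation null with the same
#' statistic, and attaches cluster-level p-values.
#'
#' @inheritParams build_null
#' @param alpha Cluster-level significance threshold carried in the result.
#' @return A list with class `cluster_test`: `bin_stats`, `clusters`
#'   (with `p_cluster`), `null`, `contrast`, `alpha`.
#' @export
cluster_test <- function(em, contrast, n_perm = 1000, seed = 1,
                         alpha_inclusion = 0.05, alpha = 0.05,
                         method = c("paired", "lmm")) {
  method <- match.arg(method)
  bs <- fit_all_bins(em, contrast, method = method)
  cl <- form_clusters(bs, alpha_inclusion)
  null <- build_null(em, contrast, n_perm = n_perm, seed = seed,
                     alpha_inclusion = alpha_inclusion, method = method)
  cl <- cluster_p(cl, null)
  structure(list(bin_stats = bs, clusters = cl, null = null,
                 contrast = contrast, alpha = alpha),
            class = "cluster_test")
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf("<cluster_test> %s (%d permutations)\n", x$contrast$name,
              x$null$n_perm))
  if (nrow(x$clusters) == 0) {
    cat("  no supra-threshold clusters\n")
  } else {
    for (i in seq_len(nrow(x$clusters))) {
      cl <- x$clusters[i, ]
      cat(sprintf("  %s cluster [%g, %g] s post-US, mass %.1f, p = %.4g%s\n",
                  cl$sign, cl$start_s, cl$end_s, cl$mass, cl$p_cluster,
                  if (cl$p_cluster <= x$alpha) " *" else ""))
    }
  }
  invisible(x)
}
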