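# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the RNG seeded to `seed` and restores the caller's RNG
#' state afterwards, so seeded package functions do not disturb the global
#' random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# Safe lookup in a named vector/list: default when the name is absent.
named_get <- function(x, name, default = 0) {
  if (is.null(x) || !name %in% names(x)) return(default)
  x[[name]]
}

stop_if_not <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

# Column-wise mean/sd of a matrix with NAs, returning n per column as well.
col_moments <- function(x) {
  n <- colSums(!is.na(x))
  s1 <- colSums(x, na.rm = TRUE)
  s2 <- colSums(x * x, na.rm = TRUE)
  m <- ifelse(n > 0, s1 / n, NA_real_)
  v <- ifelse(n > 1, (s2 - n * m^2) / (n - 1), NA_real_)
  v[v < 0] <- 0  # numerical guard
  list(n = n, mean = m, sd = sqrt(v))
}

modalities_known <- c("SCR", "PSR", "HPR", "RAR", "GAZE_X", "GAZE_Y")
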