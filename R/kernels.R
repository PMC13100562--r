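# Canonical evoked-response kernels per modality.
#
# SCR/PSR/RAR use a gamma-density-shaped kernel, amplitude-normalised to 1 at
# the parameterised latency-to-peak; the heart-period kernel is the
# difference of two such components (biphasic). The shapes are chosen to
# match canonical autonomic response morphologies (skin conductance peaking
# ~3 s after the eliciting event, pupil ~1.5 s, respiration amplitude ~2 s,
# heart period with an early and a late opposite-signed component).

# Solve gamma shape/scale from mode (latency-to-peak) and sd (dispersion).
gamma_from_peak <- function(latency_s, dispersion_s) {
  stop_if_not(dispersion_s > 0, "dispersion must be positive")
  stop_if_not(latency_s > 0, "latency-to-peak must be positive")
  # mode = (k - 1) * theta, sd = sqrt(k) * theta
  theta <- (-latency_s + sqrt(latency_s^2 + 4 * dispersion_s^2)) / 2
  k <- latency_s / theta + 1
  list(shape = k, scale = theta)
}

# Unnormalised gamma kernel value, peak-normalised to 1 at latency_s.
gamma_kernel <- function(t, latency_s, dispersion_s) {
  g <- gamma_from_peak(latency_s, dispersion_s)
  out <- numeric(length(t))
  pos <- t > 0
  logf <- function(x) (g$shape - 1) * log(x) - x / g$scale
  out[pos] <- exp(logf(t[pos]) - logf(latency_s))
  out
}

#' Default kernel parameters per modality
#'
#' @param modality One of `"SCR"`, `"PSR"`, `"HPR"`, `"RAR"`.
#' @return A list of kernel parameters: `latency_s` and `dispersion_s`, plus
#'   for the biphasic heart-period kernel a second component (`latency2_s`,
#'   `dispersion2_s`) and its relative weight `w2`.
#' @export
default_kernel_params <- function(modality) {
  switch(modality,
    SCR = list(latency_s = 3,   dispersion_s = 1.4),
    PSR = list(latency_s = 1.5, dispersion_s = 0.8),
    RAR = list(latency_s = 2,   dispersion_s = 1.2),
    HPR = list(latency_s = 2,   dispersion_s = 1.0,
               latency2_s = 6, dispersion2_s = 2.0, w2 = 0.8),
    stop("unknown modality: ", modality, call. = FALSE))
}

#' Canonical evoked-response kernel
#'
#' Evaluates the modality's canonical response kernel at times `t` (seconds
#' after the eliciting event). SCR, PSR and RAR kernels are unimodal,
#' non-negative and peak at exactly 1 at the parameterised latency; the HPR
#' kernel is biphasic (difference of two gamma components, normalised so its
#' largest absolute excursion is 1). All kernels decay to 0 as `t` grows.
#'
#' @param modality One of `"SCR"`, `"PSR"`, `"HPR"`, `"RAR"`.
#' @param t Numeric vector of times in seconds; values at `t <= 0` return 0
#'   (the response is causal).
#' @param params Kernel parameters as from [default_kernel_params()];
#'   defaults to that modality's defaults.
#' @return Numeric vector of kernel amplitudes.
#' @export
#' @examples
#' canonical_kernel("SCR", c(0, 3, 20))  # 0, 1, ~0
canonical_kernel <- function(modality, t, params = NULL) {
  params <- params %||% default_kernel_params(modality)
  if (modality %in% c("SCR", "PSR", "RAR")) {
    gamma_kernel(t, params$latency_s, params$dispersion_s)
  } else if (modality == "HPR") {
    k <- gamma_kernel(t, params$latency_s, params$dispersion_s) -
      params$w2 * gamma_kernel(t, params$latency2_s, params$dispersion2_s)
    # normalise once on a dense grid so max |kernel| = 1
    tg <- seq(0, params$latency2_s + 8 * params$dispersion2_s, by = 0.01)
    kg <- gamma_kernel(tg, params$latency_s, params$dispersion_s) -
      params$w2 * gamma_kernel(tg, params$latency2_s, params$dispersion2_s)
    k / max(abs(kg))
  } else {
    stop("unknown modality: ", modality, call. = FALSE)
  }
}
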