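## Synthetic decay-curve generation: the mono-exponential signal model
## y(TE) = K * exp(-TE / T2*) (+ optional plateau) observed under Rician
## magnitude noise, which is what a magnitude-reconstructed gradient-echo
## series actually delivers.

#' Parameters of a synthetic mono-exponential decay
#'
#' Bundles the ground-truth signal model for one tissue: amplitude `K`
#' (arbitrary units), relaxation time `T2star` (ms), an additive plateau
#' `noise_floor` (a.u.) emulating rectified background signal at long TE,
#' and the per-channel Gaussian noise SD `sigma` (a.u.) of the Rician
#' magnitude noise model.
#'
#' @param K signal amplitude at TE = 0 (a.u.), > 0.
#' @param T2star effective transverse relaxation time (ms), > 0.
#' @param noise_floor additive plateau level (a.u.), >= 0.
#' @param sigma per-channel Gaussian noise SD (a.u.), >= 0.
#' @return an object of class `decay_params`.
#' @export
#' @examples
#' decay_params(K = 1000, T2star = 5)
decay_params <- function(K, T2star, noise_floor = 0, sigma = 0) {
  if (!is.numeric(K) || length(K) != 1 || !is.finite(K) || K <= 0) {
    t2_stop("`K` must be a single positive number", "t2star_invalid_input")
  }
  if (!is.numeric(T2star) || length(T2star) != 1 || !is.finite(T2star) || T2star <= 0) {
    t2_stop("`T2star` must be a single positive number", "t2star_invalid_input")
  }
  if (!is.numeric(noise_floor) || length(noise_floor) != 1 || noise_floor < 0) {
    t2_stop("`noise_floor` must be >= 0", "t2star_invalid_input")
  }
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma < 0) {
    t2_stop("`sigma` must be >= 0", "t2star_invalid_input")
  }
  structure(list(K = K, T2star = T2star, noise_floor = noise_floor,
                 sigma = sigma),
            class = "decay_params")
}

#' Construct an echo series
#'
#' Pairs an echo-time schedule with measured (or simulated) mean signal
#' intensities for one ROI.
#'
#' @param tes echo times (ms), strictly increasing, all > 0.
#' @param signals non-negative signal intensities (a.u.), same length.
#' @return a data frame of class `echo_series` with columns `te_ms`, `signal`.
#' @export
echo_series <- function(tes, signals) {
  tes <- check_echo_train(tes)
  if (length(signals) != length(tes)) {
    t2_stop("`signals` and `tes` must have the same length", "t2star_invalid_input")
  }
  if (!is.numeric(signals) || anyNA(signals) || any(signals < 0)) {
    t2_stop("`signals` must be non-negative numbers (magnitude data)",
            "t2star_invalid_input")
  }
  structure(data.frame(te_ms = tes, signal = as.numeric(signals)),
            class = c("echo_series", "data.frame"))
}

## Rician magnitude sample: |A + g1 + i g2| with g1, g2 ~ N(0, sigma).
rician_sample <- function(clean, sigma) {
  if (sigma <= 0) return(clean)
  n <- length(clean)
  sqrt((clean + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2)
}

#' Simulate a mono-exponential decay curve
#'
#' Generates the noiseless signal `K * exp(-TE / T2star) + noise_floor` at
#' each echo time and, when `sigma > 0`, replaces each value by the magnitude
#' of that value perturbed by two independent zero-mean Gaussian channels of
#' SD `sigma` (Rician noise, the distribution of magnitude MRI data). At long
#' TE where the true signal has decayed away, this produces the familiar
#' Rayleigh noise floor with mean `sigma * sqrt(pi / 2)`.
#'
#' @param tes echo times (ms); see [default_echo_train()].
#' @param params a [decay_params()] object.
#' @param seed optional integer seed; fixing it fixes the output exactly.
#' @return an [echo_series()].
#' @export
#' @examples
#' simulate_decay(default_echo_train(), decay_params(K = 1000, T2star = 10))
simulate_decay <- function(tes, params, seed = NULL) {
  tes <- check_echo_train(tes)
  if (!inherits(params, "decay_params")) {
    t2_stop("`params` must be created with decay_params()", "t2star_invalid_input")
  }
  clean <- params$K * exp(-tes / params$T2star) + params$noise_floor
  signals <- with_seed(seed, rician_sample(clean, params$sigma))
  echo_series(tes, signals)
}
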