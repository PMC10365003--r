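## Internal helpers shared across modules.

#' @keywords internal
t2_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "t2star_error")))
}

#' Run code under a temporary RNG seed
#'
#' Evaluates `expr` with the global RNG seeded at `seed`, then restores the
#' caller's RNG state so simulation helpers do not perturb the session stream.
#' A `NULL` seed evaluates `expr` against the current stream.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    t2_stop("`seed` must be a single finite number or NULL", "t2star_invalid_input")
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # materialise a seed so it can be restored
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero (so 82.05 -> 82.1), the
#' convention used for reported percentages; base `round()` rounds ties to
#' even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(100 * 32 / 39, 1)  # 82.1
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## Echo-train validation. Simulation accepts any positive increasing TE
## vector (>= 1 echo); fitting requires at least `min_len`.
check_echo_train <- function(tes, min_len = 1L, what = "echo train") {
  if (length(tes) < min_len) {
    t2_stop(sprintf("%s must contain at least %d echo time(s)", what, min_len),
            "t2star_invalid_input")
  }
  if (!is.numeric(tes) || anyNA(tes) || any(tes <= 0)) {
    t2_stop(sprintf("%s echo times must be positive numbers", what),
            "t2star_invalid_input")
  }
  if (length(tes) > 1 && any(diff(tes) <= 0)) {
    t2_stop(sprintf("%s echo times must be strictly increasing", what),
            "t2star_invalid_input")
  }
  invisible(as.numeric(tes))
}

#' Default multi-echo gradient-echo echo-time schedule
#'
#' The default schedule mirrors a common 1.5 T abdominal T2* protocol:
#' first echo at 0.8 ms, echo spacing 1.0 ms, 10 echoes (so TEs 0.8 to
#' 9.8 ms). All echo times are in milliseconds.
#'
#' @param first_te first echo time (ms).
#' @param spacing echo spacing (ms).
#' @param n_echoes number of echoes.
#' @return numeric vector of echo times (ms).
#' @export
#' @examples
#' default_echo_train()
default_echo_train <- function(first_te = 0.8, spacing = 1.0, n_echoes = 10L) {
  tes <- seq(first_te, by = spacing, length.out = n_echoes)
  check_echo_train(tes)
}
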