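## ROI-based mono-exponential T2* estimation. The signal model is
## y(TE) = K * exp(-TE / T2*); the fit is initialised by log-linear ordinary
## least squares on the positive signals and refined by unweighted nonlinear
## least squares on the original scale (log-OLS alone over-weights the noisy
## low-signal tail). Late echoes contaminated by the magnitude noise floor
## can be removed by an automated truncation loop.

#' ROI mean signal series from a multi-echo stack
#'
#' Computes, for each echo, the arithmetic mean signal over the in-mask
#' pixels — the quantity that ROI-based T2* software fits.
#'
#' @param stack an [echo_stack()].
#' @param mask logical matrix of the stack's spatial dimensions; at least one
#'   `TRUE` pixel.
#' @return an [echo_series()].
#' @export
roi_mean_series <- function(stack, mask) {
  if (!inherits(stack, "echo_stack")) {
    t2_stop("`stack` must be an echo_stack", "t2star_invalid_input")
  }
  d <- dim(stack$data)
  if (!is.logical(mask) || !identical(dim(mask), d[1:2])) {
    t2_stop("`mask` must be a logical matrix matching the stack's spatial shape",
            "t2star_invalid_input")
  }
  idx <- which(mask)
  if (length(idx) == 0) {
    t2_stop("ROI mask is empty", "t2star_invalid_input")
  }
  means <- vapply(seq_len(d[3]), function(e) mean(stack$data[, , e][idx]), numeric(1))
  echo_series(stack$tes, means)
}

new_fit_result <- function(K_hat, T2star_hat, r_squared, n_used, n_total,
                           converged) {
  structure(list(K_hat = K_hat, T2star_hat = T2star_hat,
                 r_squared = r_squared, n_echoes_used = as.integer(n_used),
                 n_echoes_total = as.integer(n_total),
                 truncated = n_used < n_total, converged = converged),
            class = "t2_fit")
}

#' @export
print.t2_fit <- function(x, ...) {
  cat(sprintf("<t2_fit> T2* = %.4g ms, K = %.4g, r^2 = %.5f, echoes %d/%d%s%s\n",
              x$T2star_hat, x$K_hat, x$r_squared, x$n_echoes_used,
              x$n_echoes_total,
              if (x$truncated) " (truncated)" else "",
              if (!x$converged) " [log-linear fallback]" else ""))
  invisible(x)
}

#' @export
as.data.frame.t2_fit <- function(x, ...) {
  data.frame(K_hat = x$K_hat, T2star_hat = x$T2star_hat,
             r_squared = x$r_squared, n_echoes_used = x$n_echoes_used,
             n_echoes_total = x$n_echoes_total, truncated = x$truncated,
             converged = x$converged)
}

#' Fit the mono-exponential decay model to an echo series
#'
#' Least-squares fit of `y = K * exp(-TE / T2*)`. The fit is initialised
#' from a log-linear regression of `log(y)` on TE over the strictly positive
#' signals and refined by Levenberg-Marquardt nonlinear least squares on the
#' original signal scale (all echoes, including non-positive ones, enter the
#' nonlinear stage). `r_squared` is the coefficient of determination of the
#' exponential model on the signal scale. If the nonlinear optimiser fails,
#' the log-linear estimate is returned with `converged = FALSE`.
#'
#' @param series an [echo_series()] (or data frame with `te_ms`, `signal`)
#'   with at least 3 echoes, at least 3 of them strictly positive.
#' @return an object of class `t2_fit` with components `K_hat`,
#'   `T2star_hat` (ms), `r_squared`, `n_echoes_used`, `n_echoes_total`,
#'   `truncated`, `converged`.
#' @export
#' @examples
#' s <- simulate_decay(default_echo_train(), decay_params(K = 500, T2star = 5))
#' fit_monoexp(s)
fit_monoexp <- function(series) {
  dat <- as_series_df(series)
  te <- dat$te_ms
  y <- dat$signal
  if (length(te) < 3) {
    t2_stop("at least 3 echoes are required for a mono-exponential fit",
            "t2star_invalid_input")
  }
  pos <- y > 0
  if (sum(pos) < 3) {
    t2_stop("at least 3 strictly positive signals are required",
            "t2star_invalid_input")
  }
  ll <- stats::lm.fit(cbind(1, te[pos]), log(y[pos]))
  slope <- ll$coefficients[2]
  if (!is.finite(slope) || slope >= 0) {
    t2_stop("series is not decaying (log-linear slope >= 0); cannot fit",
            "t2star_degenerate_fit")
  }
  K0 <- unname(exp(ll$coefficients[1]))
  T20 <- unname(-1 / slope)
  nls_fit <- tryCatch(
    minpack.lm::nlsLM(y ~ K * exp(-te / T2),
                      start = list(K = K0, T2 = T20),
                      lower = c(K = 1e-12, T2 = 1e-9),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  sst <- sum((y - mean(y))^2)
  if (is.null(nls_fit)) {
    pred <- K0 * exp(-te / T20)
    r2 <- 1 - sum((y - pred)^2) / sst
    return(new_fit_result(K0, T20, r2, length(te), length(te), FALSE))
  }
  co <- stats::coef(nls_fit)
  r2 <- 1 - sum(stats::resid(nls_fit)^2) / sst
  new_fit_result(co[["K"]], co[["T2"]], r2, length(te), length(te), TRUE)
}

as_series_df <- function(series) {
  if (inherits(series, "echo_series")) return(series)
  if (is.data.frame(series) && all(c("te_ms", "signal") %in% names(series))) {
    return(series)
  }
  t2_stop("`series` must be an echo_series (columns te_ms, signal)",
          "t2star_invalid_input")
}

#' Automated echo-truncation policy
#'
#' Controls the truncation loop of [truncated_fit()]: echoes are removed
#' from the long-TE end while the fit's `r_squared` is below `r2_threshold`,
#' at least `min_echoes` remain, fewer than `max_drop` echoes have been
#' dropped, and (when `require_improvement` is `TRUE`, the default) each
#' removal actually improves `r_squared`. The improvement gate distinguishes
#' genuine noise-floor contamination (dropping the plateau sharply improves
#' the fit) from ordinary noise on a shallow decay (dropping echoes does
#' not), so slow-decaying series are not truncated to the minimum.
#'
#' @param r2_threshold minimum acceptable coefficient of determination,
#'   in (0, 1].
#' @param min_echoes minimum number of retained echoes (>= 3).
#' @param max_drop maximum number of removable echoes; `NULL` means
#'   `n_echoes - min_echoes`.
#' @param require_improvement only accept a removal if it raises
#'   `r_squared`.
#' @return an object of class `truncation_policy`.
#' @export
truncation_policy <- function(r2_threshold = 0.995, min_echoes = 3L,
                              max_drop = NULL, require_improvement = TRUE) {
  if (!is.numeric(r2_threshold) || r2_threshold <= 0 || r2_threshold > 1) {
    t2_stop("`r2_threshold` must be in (0, 1]", "t2star_invalid_input")
  }
  if (!is.numeric(min_echoes) || min_echoes < 3) {
    t2_stop("`min_echoes` must be >= 3", "t2star_invalid_input")
  }
  if (!is.null(max_drop) && (!is.numeric(max_drop) || max_drop < 0)) {
    t2_stop("`max_drop` must be >= 0 or NULL", "t2star_invalid_input")
  }
  structure(list(r2_threshold = r2_threshold, min_echoes = as.integer(min_echoes),
                 max_drop = max_drop,
                 require_improvement = isTRUE(require_improvement)),
            class = "truncation_policy")
}

#' Mono-exponential fit with automated truncation of late echoes
#'
#' Fits all echoes, then iteratively removes the longest-TE echo and refits
#' while the policy allows (see [truncation_policy()]). This automates the
#' manual practice of discarding long-TE images whose apparent signal is
#' dominated by the rectified background noise floor — without truncation
#' such series yield spuriously high T2* values.
#'
#' @param series an [echo_series()].
#' @param policy a [truncation_policy()].
#' @return a `t2_fit` whose `truncated` flag indicates whether any echo was
#'   dropped; `n_echoes_used` counts the retained echoes.
#' @export
#' @examples
#' tes <- default_echo_train()
#' s <- simulate_decay(tes, decay_params(K = 2000, T2star = 0.8, noise_floor = 200))
#' truncated_fit(s)   # drops the floor-dominated tail
#' fit_monoexp(s)     # overestimates T2*
truncated_fit <- function(series, policy = truncation_policy()) {
  dat <- as_series_df(series)
  n_total <- nrow(dat)
  if (!inherits(policy, "truncation_policy")) {
    t2_stop("`policy` must be a truncation_policy()", "t2star_invalid_input")
  }
  if (policy$min_echoes > n_total) {
    t2_stop("policy min_echoes exceeds the number of available echoes",
            "t2star_invalid_input")
  }
  max_drop <- if (is.null(policy$max_drop)) n_total - policy$min_echoes else
    min(policy$max_drop, n_total - policy$min_echoes)
  n <- n_total
  cur <- fit_monoexp(dat[seq_len(n), , drop = FALSE])
  dropped <- 0L
  while (cur$r_squared < policy$r2_threshold && n > policy$min_echoes &&
         dropped < max_drop) {
    cand <- tryCatch(fit_monoexp(dat[seq_len(n - 1L), , drop = FALSE]),
                     error = function(e) NULL)
    if (is.null(cand)) break
    if (policy$require_improvement && cand$r_squared <= cur$r_squared) break
    n <- n - 1L
    dropped <- dropped + 1L
    cur <- cand
  }
  new_fit_result(cur$K_hat, cur$T2star_hat, cur$r_squared, n, n_total,
                 cur$converged)
}
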