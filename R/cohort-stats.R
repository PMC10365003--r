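## Cohort-level statistics: Spearman rank correlations with magnitude
## labels, loess scatter smoothing, paired method-agreement confidence
## intervals, and summary tables.

#' Label the magnitude of a correlation coefficient
#'
#' Uses the absolute value: `|r| < 0.4` is weak, `0.4 <= |r| <= 0.6`
#' moderate, `|r| > 0.6` strong. The band edges are assigned inclusively to
#' the moderate band.
#'
#' @param r correlation coefficient(s), `|r| <= 1`.
#' @return character vector of `"weak"`, `"moderate"`, `"strong"`.
#' @export
#' @examples
#' classify_magnitude(c(0.270, 0.504, 0.782))
classify_magnitude <- function(r) {
  if (!is.numeric(r) || any(!is.finite(r)) || any(abs(r) > 1 + 1e-12)) {
    t2_stop("`r` must be a correlation coefficient with |r| <= 1",
            "t2star_invalid_input")
  }
  a <- pmin(abs(r), 1)
  ifelse(a < 0.4, "weak", ifelse(a <= 0.6, "moderate", "strong"))
}

#' Spearman rank correlation with magnitude label
#'
#' Computes Spearman's coefficient as the Pearson correlation of the
#' average-ranked values (ties receive average ranks) over pairwise-complete
#' observations. The two-sided p-value uses the t approximation
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom; for
#' `n <= 10` and untied data an exact permutation p-value is available via
#' `exact = TRUE`.
#'
#' @param x,y numeric vectors of equal length.
#' @param exact use the exact null distribution when feasible.
#' @return an object of class `t2_correlation`: list with `r`, `p_value`,
#'   `n` (pairs used) and `magnitude`.
#' @export
#' @examples
#' spearman_cor(1:10, c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9))
spearman_cor <- function(x, y, exact = FALSE) {
  if (length(x) != length(y)) {
    t2_stop("`x` and `y` must have equal length", "t2star_invalid_input")
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) {
    t2_stop("fewer than 3 complete pairs", "t2star_insufficient_data")
  }
  rx <- rank(x); ry <- rank(y)
  # perfectly concordant/discordant rankings are exactly +/-1; bypass the
  # floating-point round-off of the product-moment formula there
  if (identical(rx, ry)) {
    r <- 1
  } else if (identical(rx, length(ry) + 1 - ry)) {
    r <- -1
  } else {
    r <- stats::cor(rx, ry)
  }
  has_ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  if (exact && n <= 10 && !has_ties) {
    p <- stats::cor.test(x, y, method = "spearman", exact = TRUE)$p.value
  } else if (abs(r) >= 1 - 1e-15) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  structure(list(r = r, p_value = p, n = n, magnitude = classify_magnitude(r)),
            class = "t2_correlation")
}

#' @export
print.t2_correlation <- function(x, ...) {
  cat(sprintf("<t2_correlation> r = %.3f (%s), p = %.4g, n = %d\n",
              x$r, x$magnitude, x$p_value, x$n))
  invisible(x)
}

#' Loess scatter smoothing
#'
#' Locally weighted linear regression with tricube weights: at each
#' evaluation point the bandwidth is the distance to the
#' `ceiling(span * n)`-th nearest observation, weights are
#' `(1 - (d/h)^3)^3` inside the bandwidth, and a weighted degree-1 fit is
#' evaluated. No robustness iterations are applied. The fit is deterministic
#' and exactly reproduces globally linear data.
#'
#' @param x,y numeric vectors, `n >= 5`.
#' @param span smoothing fraction in (0, 1]; default 0.75.
#' @return data frame with `x` (sorted) and `fitted`.
#' @export
#' @examples
#' d <- loess_smooth(1:20, (1:20)^1.5, span = 0.75)
loess_smooth <- function(x, y, span = 0.75) {
  if (length(x) != length(y)) {
    t2_stop("`x` and `y` must have equal length", "t2star_invalid_input")
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 5) {
    t2_stop("at least 5 complete observations are required", "t2star_insufficient_data")
  }
  if (!is.numeric(span) || span <= 0 || span > 1) {
    t2_stop("`span` must be in (0, 1]", "t2star_invalid_input")
  }
  q <- ceiling(span * n)
  if (q < 2) {
    t2_stop("`span` too small for this sample size", "t2star_insufficient_data")
  }
  xs <- sort(x)
  fitted <- vapply(xs, function(x0) {
    d <- abs(x - x0)
    h <- sort(d, partial = q)[q]
    if (h <= 0) return(mean(y[d == 0]))
    w <- ifelse(d < h, (1 - (d / h)^3)^3, 0)
    xc <- x - x0
    sw <- sum(w); swx <- sum(w * xc); swx2 <- sum(w * xc^2)
    swy <- sum(w * y); swxy <- sum(w * xc * y)
    det <- sw * swx2 - swx^2
    if (det <= .Machine$double.eps * abs(sw * swx2)) return(swy / sw)
    (swx2 * swy - swx * swxy) / det
  }, numeric(1))
  data.frame(x = xs, fitted = fitted)
}

#' Paired method-agreement statistics
#'
#' Mean of the paired differences `a - b` with a two-sided paired-t
#' confidence interval — the summary used to compare two measurement methods
#' on the same subjects.
#'
#' @param a,b paired measurements of equal length (`n >= 2` complete pairs).
#' @param conf_level confidence level, default 0.95.
#' @return an object of class `t2_agreement`: `mean_difference`, `ci_low`,
#'   `ci_high`, `conf_level`, `n`.
#' @export
#' @examples
#' method_agreement(c(5, 7, 9), c(4, 5, 9))
method_agreement <- function(a, b, conf_level = 0.95) {
  if (length(a) != length(b)) {
    t2_stop("`a` and `b` must have equal length", "t2star_invalid_input")
  }
  if (!is.numeric(conf_level) || conf_level <= 0 || conf_level >= 1) {
    t2_stop("`conf_level` must be in (0, 1)", "t2star_invalid_input")
  }
  d <- a - b
  d <- d[is.finite(d)]
  n <- length(d)
  if (n < 2) {
    t2_stop("fewer than 2 complete pairs", "t2star_insufficient_data")
  }
  m <- mean(d)
  se <- stats::sd(d) / sqrt(n)
  tq <- stats::qt(1 - (1 - conf_level) / 2, df = n - 1)
  structure(list(mean_difference = m, ci_low = m - tq * se,
                 ci_high = m + tq * se, conf_level = conf_level, n = n),
            class = "t2_agreement")
}

#' @export
print.t2_agreement <- function(x, ...) {
  cat(sprintf("<t2_agreement> mean difference %.3f (%.0f%% CI %.3f to %.3f), n = %d\n",
              x$mean_difference, 100 * x$conf_level, x$ci_low, x$ci_high, x$n))
  invisible(x)
}

#' Cohort summary table
#'
#' Continuous variables are summarised by mean, SD (n - 1 denominator),
#' median, minimum and maximum; categorical variables by counts and
#' percentages (one decimal, rounded half away from zero). Identifier
#' columns named `patient_id` are skipped.
#'
#' @param cohort data frame with at least one row.
#' @return an object of class `t2_summary`: list with `continuous`,
#'   `categorical` data frames and the cohort size `n`.
#' @export
summarize_cohort <- function(cohort) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0) {
    t2_stop("`cohort` must be a data frame with at least one row",
            "t2star_insufficient_data")
  }
  cohort <- cohort[setdiff(names(cohort), "patient_id")]
  n <- nrow(cohort)
  cont <- NULL; cats <- NULL
  for (nm in names(cohort)) {
    v <- cohort[[nm]]
    if (is.numeric(v)) {
      v <- v[is.finite(v)]
      if (length(v) == 0) next
      cont <- rbind(cont, data.frame(
        variable = nm, mean = mean(v),
        sd = if (length(v) > 1) stats::sd(v) else 0,
        median = stats::median(v), min = min(v), max = max(v)))
    } else {
      tab <- table(v, useNA = "no")
      cats <- rbind(cats, data.frame(
        variable = nm, level = names(tab), count = as.integer(tab),
        pct = round_half_up(100 * as.integer(tab) / sum(tab), 1)))
    }
  }
  structure(list(continuous = cont, categorical = cats, n = n),
            class = "t2_summary")
}

#' @export
print.t2_summary <- function(x, ...) {
  cat(sprintf("<t2_summary> n = %d\n", x$n))
  if (!is.null(x$continuous)) print(x$continuous, row.names = FALSE)
  if (!is.null(x$categorical)) print(x$categorical, row.names = FALSE)
  invisible(x)
}

#' Per-stratum Spearman correlation
#'
#' Applies [spearman_cor()] within each stratum (e.g. within each severity
#' grade when comparing two measurement methods). Strata with fewer than 3
#' complete pairs are skipped with a warning.
#'
#' @param x,y paired numeric vectors.
#' @param strata stratum label per observation.
#' @param exact passed to [spearman_cor()].
#' @return data frame with one row per retained stratum: `stratum`, `r`,
#'   `p_value`, `n`, `magnitude`.
#' @export
stratified_spearman <- function(x, y, strata, exact = FALSE) {
  if (length(x) != length(y) || length(x) != length(strata)) {
    t2_stop("`x`, `y` and `strata` must have equal length", "t2star_invalid_input")
  }
  out <- NULL
  for (s in unique(as.character(strata))) {
    i <- which(as.character(strata) == s)
    res <- tryCatch(spearman_cor(x[i], y[i], exact = exact), error = function(e) NULL)
    if (is.null(res)) {
      warning(sprintf("stratum '%s' skipped: fewer than 3 complete pairs", s))
      next
    }
    out <- rbind(out, data.frame(stratum = s, r = res$r, p_value = res$p_value,
                                 n = res$n, magnitude = res$magnitude))
  }
  out
}
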