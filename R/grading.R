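## Iron-overload severity grading: map an organ T2* value onto the ordered
## categories normal / mild / moderate / severe via per-organ threshold
## boundaries. Lower T2* means more iron, so categories become more severe
## as T2* decreases.

severity_levels <- c("normal", "mild", "moderate", "severe")

#' Per-organ severity threshold configuration
#'
#' Three strictly increasing boundaries (ms) per organ split the positive
#' axis into severe `< b_severe`, moderate `[b_severe, b_moderate)`, mild
#' `[b_moderate, b_mild)` and normal `>= b_mild`; a boundary value belongs
#' to the less-severe side. The shipped defaults are commonly used
#' literature values — heart 10/14/20 ms, liver 1.4/2.7/6.3 ms, pancreas
#' 10/20/26 ms — and are configuration, not package-validated constants;
#' override them to match local practice.
#'
#' @param heart,liver,pancreas numeric `c(b_severe, b_moderate, b_mild)`
#'   in ms, strictly increasing, all positive.
#' @return an object of class `threshold_config`.
#' @export
#' @examples
#' threshold_config()
threshold_config <- function(heart = c(10, 14, 20),
                             liver = c(1.4, 2.7, 6.3),
                             pancreas = c(10, 20, 26)) {
  cfg <- list(heart = heart, liver = liver, pancreas = pancreas)
  for (organ in names(cfg)) {
    b <- cfg[[organ]]
    if (length(b) != 3 || !is.numeric(b) || any(b <= 0) || any(diff(b) <= 0)) {
      t2_stop(sprintf("'%s' thresholds must be 3 strictly increasing positive values",
                      organ), "t2star_invalid_input")
    }
    cfg[[organ]] <- as.numeric(b)
  }
  structure(cfg, class = "threshold_config")
}

#' Classify an organ T2* value into a severity category
#'
#' @param organ one of `"heart"`, `"liver"`, `"pancreas"`.
#' @param t2star positive T2* value(s) in ms.
#' @param config a [threshold_config()].
#' @return ordered factor with levels `normal < mild < moderate < severe`.
#' @export
#' @examples
#' classify("liver", c(1.0, 2.0, 5.0, 10.0))
classify <- function(organ, t2star, config = threshold_config()) {
  if (!inherits(config, "threshold_config")) {
    t2_stop("`config` must be a threshold_config()", "t2star_invalid_input")
  }
  organ <- match.arg(organ, names(config))
  if (!is.numeric(t2star) || any(!is.na(t2star) & t2star <= 0)) {
    t2_stop("`t2star` must be positive", "t2star_invalid_input")
  }
  b <- config[[organ]]
  lab <- cut(t2star, breaks = c(0, b, Inf), right = FALSE,
             labels = c("severe", "moderate", "mild", "normal"))
  factor(as.character(lab), levels = severity_levels, ordered = TRUE)
}

#' Grade every organ of a cohort table
#'
#' Adds an ordered `<organ>_grade` column for each organ whose
#' `t2s_<organ>_ms` column is present. Rows with a missing T2* are retained
#' with a missing grade and flagged with a warning. Re-grading an already
#' graded cohort reproduces the same table (the operation is idempotent).
#'
#' @param cohort data frame with `t2s_heart_ms` / `t2s_liver_ms` /
#'   `t2s_pancreas_ms` columns (any subset).
#' @param config a [threshold_config()].
#' @return the cohort with added/overwritten `*_grade` columns.
#' @export
grade_cohort <- function(cohort, config = threshold_config()) {
  if (!is.data.frame(cohort)) {
    t2_stop("`cohort` must be a data frame", "t2star_invalid_input")
  }
  organs <- names(config)
  found <- FALSE
  for (organ in organs) {
    col <- paste0("t2s_", organ, "_ms")
    if (!col %in% names(cohort)) next
    found <- TRUE
    vals <- cohort[[col]]
    if (anyNA(vals)) {
      warning(sprintf("%d row(s) missing %s; grade set to NA", sum(is.na(vals)), col))
    }
    grade <- factor(rep(NA_character_, length(vals)),
                    levels = severity_levels, ordered = TRUE)
    ok <- !is.na(vals)
    grade[ok] <- classify(organ, vals[ok], config)
    cohort[[paste0(organ, "_grade")]] <- grade
  }
  if (!found) {
    t2_stop("no t2s_<organ>_ms columns found in `cohort`", "t2star_invalid_input")
  }
  cohort
}

#' Summarise severity category counts
#'
#' Given per-organ category counts (e.g. transcribed from a published cohort
#' table, or tallied from a graded cohort), computes each category's
#' percentage and the abnormal (non-normal) count and percentage per organ.
#' Percentages are rounded to one decimal, half away from zero.
#'
#' @param counts data frame with columns `organ`, `category`, `count`.
#' @return list with `by_category` (counts plus `pct`) and `by_organ`
#'   (per-organ `n`, `n_abnormal`, `pct_abnormal`).
#' @export
#' @examples
#' counts <- data.frame(organ = "pancreas",
#'                      category = c("normal", "mild", "moderate", "severe"),
#'                      count = c(7, 15, 15, 2))
#' summarize_severity_counts(counts)$by_organ
summarize_severity_counts <- function(counts) {
  need <- c("organ", "category", "count")
  if (!is.data.frame(counts) || !all(need %in% names(counts))) {
    t2_stop("`counts` needs columns organ, category, count", "t2star_invalid_input")
  }
  if (!all(counts$category %in% severity_levels)) {
    t2_stop("`category` values must be normal/mild/moderate/severe",
            "t2star_invalid_input")
  }
  by_cat <- counts
  by_organ <- do.call(rbind, lapply(split(counts, counts$organ), function(d) {
    n <- sum(d$count)
    n_ab <- sum(d$count[d$category != "normal"])
    data.frame(organ = d$organ[1], n = n, n_abnormal = n_ab,
               pct_abnormal = round_half_up(100 * n_ab / n, 1))
  }))
  rownames(by_organ) <- NULL
  by_cat$pct <- round_half_up(
    100 * counts$count / stats::ave(counts$count, counts$organ, FUN = sum), 1)
  list(by_category = by_cat, by_organ = by_organ)
}

#' Read / write a threshold configuration
#'
#' Threshold configurations are stored as YAML with one `c(b_severe,
#' b_moderate, b_mild)` entry per organ.
#'
#' @param path file path.
#' @return [read_threshold_config()] returns a [threshold_config()].
#' @export
read_threshold_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(threshold_config, cfg[intersect(names(cfg), c("heart", "liver", "pancreas"))])
}

#' @rdname read_threshold_config
#' @param config a [threshold_config()] to serialise.
#' @export
write_threshold_config <- function(config, path) {
  if (!inherits(config, "threshold_config")) {
    t2_stop("`config` must be a threshold_config()", "t2star_invalid_input")
  }
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
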