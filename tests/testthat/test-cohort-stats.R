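test_that("Spearman correlation is +/-1 for perfect monotone association", {
  x <- c(1, 3, 4, 7, 12)
  expect_identical(spearman_cor(x, x^3)$r, 1)
  expect_identical(spearman_cor(x, -sqrt(x))$r, -1)
  expect_equal(spearman_cor(x, x^3)$p_value, 0)
})

test_that("tied data match the brute-force average-rank Pearson oracle", {
  x <- c(1, 2, 2, 4)
  y <- c(3, 1, 4, 4)
  expect_equal(spearman_cor(x, y)$r, oracle_spearman(x, y), tolerance = 1e-12)
  set.seed(99)
  for (i in 1:100) {
    n <- sample(4:12, 1)
    x <- sample(1:6, n, replace = TRUE)       # heavy ties
    y <- sample(seq(0, 2, 0.5), n, replace = TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    expect_equal(spearman_cor(x, y)$r, oracle_spearman(x, y), tolerance = 1e-12)
  }
})

test_that("Spearman is invariant under strictly monotone transforms", {
  set.seed(4)
  x <- rlnorm(40); y <- x + rnorm(40, 0, 0.5)
  r0 <- spearman_cor(x, y)$r
  expect_equal(spearman_cor(log(x), y)$r, r0)
  expect_equal(spearman_cor(x, exp(y))$r, r0)
  expect_equal(spearman_cor(x^3, y)$r, r0)
})

test_that("the t-approximation p-value matches the reference implementation", {
  set.seed(12)
  x <- rnorm(25); y <- x + rnorm(25)
  ours <- spearman_cor(x, y)
  ref <- cor.test(x, y, method = "spearman", exact = FALSE)
  expect_equal(ours$r, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)
  # exact permutation p for small untied samples
  x <- c(3, 1, 4, 1.5, 9, 2.6); y <- c(2, 7, 1.8, 2.8, 1.2, 5)
  expect_equal(spearman_cor(x, y, exact = TRUE)$p_value,
               cor.test(x, y, method = "spearman", exact = TRUE)$p.value)
})

test_that("correlations are computed over pairwise-complete observations", {
  x <- c(1, 2, NA, 4, 5)
  y <- c(2, NA, 3, 8, 10)
  res <- spearman_cor(x, y)
  expect_identical(res$n, 3L)
  expect_identical(res$r, 1)
  expect_error(spearman_cor(c(1, NA, NA, 4), c(1, 2, 3, NA)),
               class = "t2star_insufficient_data")
})

test_that("magnitude labels follow the published bands with inclusive edges", {
  expect_identical(classify_magnitude(0.504), "moderate")
  expect_identical(classify_magnitude(0.595), "moderate")
  expect_identical(classify_magnitude(0.782), "strong")
  expect_identical(classify_magnitude(0.270), "weak")
  expect_identical(classify_magnitude(c(0.4, 0.6)), c("moderate", "moderate"))
  expect_identical(classify_magnitude(-0.734), "strong")  # uses |r|
  expect_error(classify_magnitude(1.2), class = "t2star_invalid_input")
})

test_that("loess reproduces exact lines and is duplication-invariant", {
  set.seed(21)
  x <- sort(runif(40, 0, 10))
  y_line <- 2.5 * x - 4
  sm <- loess_smooth(x, y_line, span = 0.6)
  expect_lt(max(abs(sm$fitted - (2.5 * sm$x - 4))), 1e-8)
  # duplicated dataset: identical curve
  y <- sin(x) + rnorm(40, 0, 0.2)
  s1 <- loess_smooth(x, y, span = 0.75)
  s2 <- loess_smooth(c(x, x), c(y, y), span = 0.75)
  expect_equal(s2$fitted[match(s1$x, s2$x)], s1$fitted, tolerance = 1e-12)
})

test_that("loess matches the reference local-regression implementation", {
  # span * n integer so both implementations use the same neighbourhood size
  set.seed(8)
  x <- sort(runif(80, 0, 10))
  y <- sin(x) + rnorm(80, 0, 0.2)
  ours <- loess_smooth(x, y, span = 0.75)
  ref <- predict(loess(y ~ x, span = 0.75, degree = 1, family = "gaussian",
                       surface = "direct"),
                 data.frame(x = ours$x))
  expect_lt(max(abs(ours$fitted - ref)), 1e-6)
})

test_that("loess rejects undersized inputs and bad spans", {
  expect_error(loess_smooth(1:4, 1:4), class = "t2star_insufficient_data")
  expect_error(loess_smooth(1:10, 1:10, span = 0), class = "t2star_invalid_input")
  expect_error(loess_smooth(1:10, 1:10, span = 1.5), class = "t2star_invalid_input")
  expect_error(loess_smooth(1:10, 1:10, span = 0.1), class = "t2star_insufficient_data")
})

test_that("method agreement reproduces hand-computed paired-t intervals", {
  # identical methods: zero difference, degenerate CI
  res <- method_agreement(c(3, 5, 8), c(3, 5, 8))
  expect_equal(res$mean_difference, 0)
  expect_equal(c(res$ci_low, res$ci_high), c(0, 0))
  # constant offset
  a <- c(2, 4, 9)
  res <- method_agreement(a, a + 3)
  expect_equal(res$mean_difference, -3)
  expect_equal(c(res$ci_low, res$ci_high), c(-3, -3))
  # hand-computed three-point example: d = (1, 2, 0), SE = 1/sqrt(3)
  res <- method_agreement(c(5, 7, 9), c(4, 5, 9))
  half <- qt(0.975, 2) / sqrt(3)
  expect_equal(res$mean_difference, 1)
  expect_equal(res$ci_low, 1 - half)
  expect_equal(res$ci_high, 1 + half)
  # cross-check against the reference paired t
  tt <- t.test(c(5, 7, 9), c(4, 5, 9), paired = TRUE)
  expect_equal(c(res$ci_low, res$ci_high), as.numeric(tt$conf.int))
  expect_error(method_agreement(5, 4), class = "t2star_insufficient_data")
})

test_that("agreement CI width shrinks as 1/sqrt(n)", {
  widths <- sapply(c(10, 100, 1000), function(n) {
    set.seed(60 + n)
    d <- rnorm(n, 1, 2)
    res <- method_agreement(d, rep(0, n))
    res$ci_high - res$ci_low
  })
  slope <- coef(lm(log(widths) ~ log(c(10, 100, 1000))))[2]
  expect_equal(unname(slope), -0.5, tolerance = 0.1)
})

test_that("cohort summaries use the n-1 SD and half-away-from-zero percentages", {
  co <- data.frame(v = c(1, 2, 3, 4))
  s <- summarize_cohort(co)
  expect_equal(s$continuous$mean, 2.5)
  expect_equal(s$continuous$sd, 1.290994, tolerance = 1e-6)
  expect_equal(s$continuous$median, 2.5)
  expect_equal(s$continuous$min, 1)
  expect_equal(s$continuous$max, 4)
  # single patient: mean = median = value, SD = 0
  s1 <- summarize_cohort(data.frame(v = 7))
  expect_equal(s1$continuous$mean, 7)
  expect_equal(s1$continuous$median, 7)
  expect_equal(s1$continuous$sd, 0)
  # categorical percentages reproduce 82.1 / 94.9 / 23.1 from 32, 37, 9 of 39
  expect_equal(round_half_up(100 * 32 / 39, 1), 82.1)
  expect_equal(round_half_up(100 * 37 / 39, 1), 94.9)
  expect_equal(round_half_up(100 * 9 / 39, 1), 23.1)
  st <- summarize_cohort(data.frame(g = rep(c("ab", "n"), c(32, 7))))
  expect_equal(st$categorical$pct, c(82.1, 17.9))
  expect_identical(sum(st$categorical$count), 39L)
  expect_error(summarize_cohort(data.frame()), class = "t2star_insufficient_data")
})

test_that("stratified Spearman matches per-stratum brute force", {
  # single stratum: identical to the global statistic
  set.seed(14)
  x <- rnorm(20); y <- x + rnorm(20)
  g <- rep("all", 20)
  res <- stratified_spearman(x, y, g)
  expect_equal(res$r, spearman_cor(x, y)$r)
  # internally monotone strata give r = 1 each
  x2 <- c(1, 2, 3, 10, 11, 12)
  y2 <- c(5, 6, 7, 2, 3, 4)
  res2 <- stratified_spearman(x2, y2, rep(c("a", "b"), each = 3))
  expect_equal(res2$r, c(1, 1))
  # two-stratum fixture vs brute force
  set.seed(15)
  xa <- rnorm(8); ya <- xa + rnorm(8)
  xb <- rnorm(7); yb <- -xb + rnorm(7)
  res3 <- stratified_spearman(c(xa, xb), c(ya, yb), rep(c("a", "b"), c(8, 7)))
  expect_equal(res3$r[res3$stratum == "a"], oracle_spearman(xa, ya), tolerance = 1e-12)
  expect_equal(res3$r[res3$stratum == "b"], oracle_spearman(xb, yb), tolerance = 1e-12)
  # undersized stratum skipped with a warning
  expect_warning(res4 <- stratified_spearman(c(xa, 1, 2), c(ya, 2, 1),
                                             rep(c("a", "tiny"), c(8, 2))),
                 "skipped")
  expect_identical(res4$stratum, "a")
})
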