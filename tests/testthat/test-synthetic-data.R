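test_that("noiseless decay follows the mono-exponential signal equation", {
  # single echo, direct formula
  s <- simulate_decay(0.8, decay_params(K = 100, T2star = 10))
  expect_equal(s$signal, 100 * exp(-0.08))
  # K/e at TE = T2*
  s <- simulate_decay(2.0, decay_params(K = 1000, T2star = 2.0))
  expect_equal(s$signal, 1000 / exp(1), tolerance = 1e-9)
  expect_equal(s$signal, 367.879441, tolerance = 1e-8)
  # strictly decreasing in TE for any noiseless parameters
  for (T2 in c(0.9, 4, 33)) {
    s <- simulate_decay(default_echo_train(), decay_params(K = 250, T2star = T2))
    expect_true(all(diff(s$signal) < 0))
  }
})

test_that("a fixed seed fixes the decay output exactly and restores RNG state", {
  tes <- default_echo_train()
  p <- decay_params(K = 1000, T2star = 5, sigma = 20)
  set.seed(999)
  before <- runif(1)
  set.seed(999)
  a <- simulate_decay(tes, p, seed = 42)
  b <- simulate_decay(tes, p, seed = 42)
  expect_identical(a, b)
  expect_false(identical(a$signal, simulate_decay(tes, p, seed = 43)$signal))
  # seeded simulation must not disturb the ambient RNG stream
  expect_identical(runif(1), before)
})

test_that("invalid decay inputs are rejected", {
  expect_error(simulate_decay(numeric(0), decay_params(1, 1)),
               class = "t2star_invalid_input")
  expect_error(simulate_decay(c(2, 1, 3), decay_params(1, 1)),
               class = "t2star_invalid_input")
  expect_error(decay_params(K = -1, T2star = 5), class = "t2star_invalid_input")
  expect_error(decay_params(K = 1, T2star = 0), class = "t2star_invalid_input")
  expect_error(decay_params(K = 1, T2star = 1, sigma = -2),
               class = "t2star_invalid_input")
})

test_that("phantom regions decay with their own parameters", {
  tes <- default_echo_train()
  up <- uniform_phantom(T2 = 7, K = 800)
  ph <- simulate_phantom(up$spec)
  # sigma = 0: every in-region pixel identical at each echo
  for (e in c(1, 5, 10)) {
    vals <- ph$data[, , e][up$mask]
    expect_equal(max(vals), min(vals))
    expect_equal(vals[1], 800 * exp(-tes[e] / 7))
  }
  # out-of-region pixels are zero when background noise is off
  expect_true(all(ph$data[, , 1][!up$mask] == 0))

  # faster-decaying region is darker at the last echo
  shape <- c(12L, 12L)
  fast <- rect_mask(shape, 2:5, 2:11)
  slow <- rect_mask(shape, 8:11, 2:11)
  spec <- phantom_spec(shape,
                       list(fast = list(mask = fast, params = decay_params(1000, 1)),
                            slow = list(mask = slow, params = decay_params(1000, 20))),
                       tes)
  ph2 <- simulate_phantom(spec)
  last <- ph2$data[, , 10]
  expect_lt(mean(last[fast]), mean(last[slow]))
})

test_that("overlapping phantom regions are rejected", {
  shape <- c(8L, 8L)
  a <- rect_mask(shape, 1:5, 1:5)
  b <- rect_mask(shape, 4:8, 4:8)
  expect_error(
    phantom_spec(shape, list(a = list(mask = a, params = decay_params(1, 1)),
                             b = list(mask = b, params = decay_params(1, 1))),
                 default_echo_train()),
    class = "t2star_invalid_spec")
})

test_that("background magnitude noise has the Rayleigh mean sigma * sqrt(pi/2)", {
  shape <- c(40L, 40L)
  up <- uniform_phantom(T2 = 1, K = 1000, shape = shape)
  spec <- phantom_spec(shape, up$spec$regions, up$spec$tes, background_sigma = 10)
  ph <- simulate_phantom(spec, seed = 7)
  bg <- ph$data[, , 10][!up$spec$regions$tissue$mask]
  expect_equal(mean(bg), 10 * sqrt(pi / 2), tolerance = 0.03)
})

test_that("round-trip through the fitter recovers noiseless ground truth", {
  tes <- default_echo_train()
  for (T2 in c(1, 2, 5, 10, 20, 40)) {
    f <- fit_monoexp(simulate_decay(tes, decay_params(K = 1000, T2star = T2)))
    expect_lt(abs(f$T2star_hat - T2) / T2, 1e-6)
    expect_lt(abs(f$K_hat - 1000) / 1000, 1e-6)
  }
})

test_that("comonotone cohort variables have sample Spearman correlation exactly 1", {
  marg <- list(a = c(list(family = "lnorm"), lnorm_from_moments(10, 5)),
               b = c(list(family = "lnorm"), lnorm_from_moments(30, 10)))
  R <- matrix(1, 2, 2, dimnames = list(names(marg), names(marg)))
  co <- simulate_cohort(cohort_spec(50, marg, R), seed = 5)
  expect_identical(spearman_cor(co$a, co$b)$r, 1)
})

test_that("independent cohort variables have near-zero sample Spearman correlation", {
  marg <- list(a = c(list(family = "lnorm"), lnorm_from_moments(10, 5)),
               b = c(list(family = "lnorm"), lnorm_from_moments(30, 10)))
  R <- diag(2); dimnames(R) <- list(names(marg), names(marg))
  co <- simulate_cohort(cohort_spec(5000, marg, R), seed = 11)
  expect_lt(abs(spearman_cor(co$a, co$b)$r), 0.05)  # null bound ~ 2 / sqrt(n)
})

test_that("cohort marginals match their specification (KS, n = 5000, 10 seeds)", {
  marg <- default_cohort_marginals()
  for (seed in 1:10) {
    co <- simulate_cohort(cohort_spec(5000), seed = seed)
    for (v in names(marg)) {
      p <- suppressWarnings(
        ks.test(co[[v]], "plnorm", marg[[v]]$meanlog, marg[[v]]$sdlog)$p.value)
      expect_gt(p, 0.01)
    }
  }
})

test_that("a non-positive-semidefinite target correlation is rejected", {
  marg <- list(a = list(family = "unif", min = 0, max = 1),
               b = list(family = "unif", min = 0, max = 1),
               cc = list(family = "unif", min = 0, max = 1))
  R <- diag(3); dimnames(R) <- list(names(marg), names(marg))
  R["a", "b"] <- R["b", "a"] <- 0.9
  R["a", "cc"] <- R["cc", "a"] <- 0.9
  R["b", "cc"] <- R["cc", "b"] <- -0.9
  expect_error(simulate_cohort(cohort_spec(10, marg, R), seed = 1),
               class = "t2star_invalid_spec")
})

test_that("cohort simulation is reproducible for a fixed seed", {
  a <- simulate_cohort(cohort_spec(25), seed = 123)
  b <- simulate_cohort(cohort_spec(25), seed = 123)
  expect_identical(a, b)
})
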