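test_that("monoexponential fit recovers noiseless decay parameters exactly", {
  tc <- noiseless_mono_tc(k = 0.01, A = 0.9, plateau = 0.1)
  fit <- fit_monoexp(tc)
  expect_equal(fit$k_obs, 0.01, tolerance = 1e-6)
  expect_equal(fit$plateau, 0.1, tolerance = 1e-6)
  expect_equal(fit$amplitudes, 0.9, tolerance = 1e-6)
  expect_equal(fit$n_components, 1L)
  # fitted curve reproduces the data to within the reported rss
  expect_lte(sum((fit$fitted - tc$fraction_intact)^2), fit$rss + 1e-12)
})

test_that("degenerate and undersized time courses are rejected", {
  expect_error(fit_monoexp(time_course(0:9, rep(1, 10))), "degenerate")
  expect_error(fit_monoexp(time_course(0:2, c(1, 0.7, 0.5))), "insufficient")
  expect_error(fit_biexp(time_course(0:4, exp(-0.1 * (0:4)))), "insufficient")
})

test_that("monoexponential fit of biexponential truth leaves excess residual", {
  times <- c(0, 2, 5, 10, 20, 50, 100, 200, 400, 800, 1500, 3000)
  tc <- noiseless_bi_tc(k1 = 0.1, k2 = 0.001, A1 = 0.5, A2 = 0.5,
                        times = times)
  f1 <- fit_monoexp(tc)
  f2 <- fit_biexp(tc)
  expect_gt(f1$rss, f2$rss)
  expect_gt(f1$rss, 1e-4)   # the single exponential genuinely cannot bend twice
  expect_lt(f2$rss, 1e-12)
})

test_that("biexponential fit recovers well-separated rates, sorted descending", {
  fit <- fit_biexp(noiseless_bi_tc(k1 = 1, k2 = 0.01))
  expect_equal(fit$rates, c(1, 0.01), tolerance = 1e-4)
  expect_equal(fit$k_obs, fit$rates[1])
  expect_true(all(diff(fit$rates) < 0))
})

test_that("k_obs is the faster rate irrespective of amplitude split", {
  for (amps in list(c(0.5, 0.5), c(0.9, 0.1), c(0.2, 0.8))) {
    fit <- fit_biexp(noiseless_bi_tc(k1 = 1, k2 = 0.01,
                                     A1 = amps[1], A2 = amps[2]))
    expect_equal(fit$k_obs, 1, tolerance = 1e-3)
  }
})

test_that("rates on the fast-construct scale are recoverable from 10 points over 30 s", {
  times <- seq(0, 30, length.out = 10)
  tc <- time_course(times, 0.95 * exp(-0.2 * times) + 0.05)
  fit <- fit_monoexp(tc)
  expect_equal(fit$k_obs, 0.2, tolerance = 1e-5)
})

test_that("model selection is parsimonious on monoexponential truth", {
  tc <- noiseless_mono_tc(times = seq(0, 700, length.out = 12))
  f1 <- fit_monoexp(tc)
  f2 <- fit_biexp(tc)
  sel <- select_model(f1, f2)
  expect_equal(sel$n_components, 1L)
})

test_that("model selection matches a directly computed AICc comparison", {
  times <- c(0, 2, 5, 10, 20, 50, 100, 200, 400, 800, 1500, 3000)
  tc0 <- noiseless_bi_tc(k1 = 0.1, k2 = 0.001, times = times)
  # deterministic "noise": alternate +/- 0.01 so the test needs no RNG
  f <- tc0$fraction_intact + rep(c(0.01, -0.01), length.out = length(times))
  tc <- time_course(times, pmin(pmax(f, 0), 1))
  f1 <- fit_monoexp(tc)
  f2 <- fit_biexp(tc)
  n <- length(times)
  a <- function(rss, p) n * log(rss / n) + 2 * p + 2 * p * (p + 1) / (n - p - 1)
  expect_equal(aicc(f1$rss, n, f1$n_params), a(f1$rss, f1$n_params))
  sel <- select_model(f1, f2, n)
  expect_identical(sel$n_components,
                   if (a(f2$rss, f2$n_params) < a(f1$rss, f1$n_params)) 2L else 1L)
  expect_equal(sel$n_components, 2L)  # rate ratio 100, tiny noise
})

test_that("small-sample correction disqualifies a saturated biexponential", {
  # 6 points, 5 parameters: the correction term diverges, so the simpler
  # model must win regardless of rss
  expect_identical(aicc(1e-6, 6, 5), Inf)
  times <- c(0, 1, 5, 20, 100, 500)
  tc <- noiseless_bi_tc(k1 = 0.5, k2 = 0.005, times = times)
  f1 <- fit_monoexp(tc)
  f2 <- fit_biexp(tc)
  expect_equal(select_model(f1, f2, 6)$n_components, 1L)
})

test_that("fitted decay curves are monotone non-increasing", {
  fit <- fit_biexp(noiseless_bi_tc())
  expect_true(all(diff(fit$fitted) <= 1e-12))
  expect_true(all(fit$amplitudes >= 0) && all(fit$rates > 0))
  expect_lte(sum(fit$amplitudes) + fit$plateau, 1 + 1e-6)
})

test_that("fit with pinned plateau matches the two-point closed-form rate", {
  t <- c(10, 20, 40)
  k_true <- 0.05
  tc <- time_course(t, exp(-k_true * t))
  fit <- fit_monoexp(tc, fix_plateau = TRUE)
  k_closed <- log(tc$fraction_intact[1] / tc$fraction_intact[2]) / (t[2] - t[1])
  expect_equal(fit$k_obs, k_closed, tolerance = 1e-6)
})

test_that("comparing fits from different constructs is a usage error", {
  f1 <- fit_monoexp(noiseless_mono_tc())
  tc_other <- time_course(seq(0, 700, 100),
                          0.1 + 0.9 * exp(-0.01 * seq(0, 700, 100)),
                          construct_id = "other")
  f2 <- fit_biexp(noiseless_bi_tc())
  expect_error(select_model(f1, f2), "same time course")
})

test_that("time units are converted to seconds on construction", {
  tc <- time_course(c(0, 1, 2, 5), c(1, 0.8, 0.65, 0.4), time_unit = "min")
  expect_equal(tc$times, c(0, 60, 120, 300))
})

test_that("F-test selection criterion is available and behaves sanely", {
  times <- c(0, 2, 5, 10, 20, 50, 100, 200, 400, 800, 1500, 3000)
  tc <- noiseless_bi_tc(k1 = 0.1, k2 = 0.001, times = times)
  f1 <- fit_monoexp(tc)
  f2 <- fit_biexp(tc)
  sel <- select_model(f1, f2, length(times), criterion = "ftest")
  expect_equal(sel$n_components, 2L)
})
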