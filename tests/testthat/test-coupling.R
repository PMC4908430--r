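make_records <- function(m, Ea, linker = "pooled", cond = "c1",
                         k_obs = NULL) {
  if (is.null(k_obs)) k_obs <- 1e-9 * exp(-Ea / rt_kcal())
  data.frame(construct_id = sprintf("r%02d", seq_along(m)),
             p12_bp = NA_integer_, p12_bits = NA_real_,
             stability = -m, linker_class = linker, condition_id = cond,
             k_obs = k_obs, E_a_apparent = Ea, is_wt = FALSE,
             stringsAsFactors = FALSE)
}

test_that("noiseless linear coupling is recovered exactly", {
  m <- seq(0.2, 3.5, length.out = 8)
  rec <- make_records(m, Ea = -20 + 0.38 * (-m))
  fit <- linear_coupling_fit(rec)
  expect_equal(fit$slope, 0.38, tolerance = 1e-9)
  expect_equal(fit$slope_magnitude, -0.38, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
})

test_that("uncoupled (flat) activation energies give slope zero", {
  rec <- make_records(seq(0.5, 3, 0.5), Ea = rep(-18, 6))
  fit <- linear_coupling_fit(rec)
  expect_equal(fit$slope, 0, tolerance = 1e-9)
})

test_that("grouped fits recover per-linker slopes; pooled lies between", {
  m <- seq(0.5, 4, length.out = 8)
  recA <- make_records(m, Ea = -20 - 0.38 * m, linker = "L0")
  recB <- make_records(m, Ea = -16 - 0.20 * m, linker = "L3")
  rec <- rbind(recA, recB)
  fits <- linear_coupling_fit(rec, group_by_linker = TRUE)
  expect_equal(fits$L0$slope, 0.38, tolerance = 1e-9)
  expect_equal(fits$L3$slope, 0.20, tolerance = 1e-9)
  pooled <- linear_coupling_fit(rec)
  expect_gt(pooled$slope, 0.20 - 1e-9)
  expect_lt(pooled$slope, 0.38 + 1e-9)
})

test_that("mixing conditions inside a fit group is an error", {
  rec <- make_records(seq(0.5, 3, 0.5), Ea = -18 - 0.3 * seq(0.5, 3, 0.5))
  rec$condition_id <- rep(c("mg1", "mg03"), 3)
  expect_error(linear_coupling_fit(rec), "mixes conditions")
})

test_that("rank-deficient stabilities are rejected", {
  rec <- make_records(rep(2, 4), Ea = c(-18, -18.5, -19, -18.2))
  expect_error(linear_coupling_fit(rec), "rank-deficient")
})

test_that("wild-type rows are excluded by default but can be kept", {
  m <- seq(0.5, 3.5, 0.5)
  rec <- make_records(m, Ea = -20 - 0.38 * m)
  wt <- make_records(10, Ea = -10)  # far off the line
  wt$construct_id <- "WT"
  rec <- rbind(rec, wt)
  expect_equal(linear_coupling_fit(rec)$slope, 0.38, tolerance = 1e-9)
  expect_true(abs(linear_coupling_fit(rec, exclude_wt = FALSE)$slope - 0.38)
              > 0.01)
})

test_that("hinge fit recovers slope and breakpoint of a capped response", {
  m <- seq(0.5, 7, by = 0.5)
  rec <- make_records(m, Ea = -15 - 0.38 * pmin(m, 4))
  fit <- hinge_fit(rec)
  expect_identical(fit$model, "hinge")
  expect_equal(fit$breakpoint, 4.0, tolerance = 0.1)
  expect_equal(fit$slope, 0.38, tolerance = 1e-6)
})

test_that("pure linear data fall back to the linear model", {
  m <- seq(0.5, 6, by = 0.5)
  rec <- make_records(m, Ea = -15 - 0.3 * m)
  fit <- hinge_fit(rec)
  expect_identical(fit$model, "linear")
  expect_true(is.na(fit$breakpoint))
  expect_equal(fit$slope, 0.3, tolerance = 1e-9)
})

test_that("flat data yield slope zero without a spurious hinge", {
  m <- seq(0.5, 6, by = 0.5)
  rec <- make_records(m, Ea = rep(-17, length(m)))
  fit <- hinge_fit(rec)
  expect_identical(fit$model, "linear")
  expect_equal(fit$slope, 0, tolerance = 1e-9)
})

test_that("hinge rss never exceeds linear rss (nested models)", {
  set.seed(11)
  for (rep in 1:5) {
    m <- sort(runif(12, 0, 7))
    Ea <- -15 - 0.38 * pmin(m, 4) + rnorm(12, 0, 0.3)
    rec <- make_records(m, Ea)
    lin <- stats::lm(Ea ~ m)
    hf <- hinge_fit(rec)
    expect_lte(hf$rss, sum(stats::resid(lin)^2) + 1e-9)
  }
})

test_that("slope is equivariant under a constant activation-energy shift", {
  m <- seq(0.5, 3.5, 0.5)
  rec1 <- make_records(m, Ea = -20 - 0.38 * m)
  rec2 <- make_records(m, Ea = -20 - 0.38 * m + 5)
  f1 <- linear_coupling_fit(rec1)
  f2 <- linear_coupling_fit(rec2)
  expect_equal(f1$slope, f2$slope, tolerance = 1e-9)
  expect_equal(f2$intercept - f1$intercept, 5, tolerance = 1e-6)
})

test_that("information-activity fit returns the constructed fold change", {
  bits <- seq(0, 14, 2)
  rec <- data.frame(construct_id = sprintf("b%d", bits), p12_bits = bits,
                    k_obs = 1e-4 * 10^(bits / 10), stability = NA,
                    is_wt = FALSE, stringsAsFactors = FALSE)
  fit <- info_activity_fit(rec)
  expect_equal(fit$fold_per_10bits, 10, tolerance = 1e-9)
  rec$k_obs <- rep(2e-4, length(bits))
  expect_equal(info_activity_fit(rec)$fold_per_10bits, 1, tolerance = 1e-9)
})

test_that("pinch-generated ladders show the expected fold change per 10 bits", {
  # below the cap the forward model is exactly log-linear in bits, with
  # fold = exp(c * 5 * dG_bp / RT) per 10 bits; at the defaults this is ~12
  ns <- noise_spec("lognormal_multiplicative", 0, seed = 1)
  pinch <- pinch_params(c = 0.38, k_chem = 1e9)
  lad <- gen_construct_ladder(0:4, mean_stack_dG = 0.81, pinch = pinch,
                              noise = ns)
  fit <- info_activity_fit(lad)
  expect_equal(fit$fold_per_10bits, exp(0.38 * 5 * 0.81 / rt_kcal()),
               tolerance = 1e-6)
  expect_equal(fit$fold_per_10bits, 12, tolerance = 0.2)
})

test_that("coupling slope is recovered from noisy pinch panels on average", {
  pp <- pinch_params(c = 0.38, k_chem = 1e9)
  slopes <- vapply(1:50, function(s) {
    panel <- simulate_panel(pp, seq(0, 3.5, length.out = 12),
                            noise_sd_logk = 0.3 / rt_kcal(), seed = s)
    linear_coupling_fit(panel_with_Ea(panel))$slope
  }, numeric(1))
  expect_lt(abs(mean(slopes) - 0.38), 0.05)
  expect_gt(stats::sd(slopes), 0)  # noise really propagates
})
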