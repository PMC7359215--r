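test_that("plating efficiency and survival fraction follow the standard definitions", {
  expect_equal(plating_efficiency(50, 100), 50)
  expect_equal(plating_efficiency(0, 100), 0)
  expect_equal(plating_efficiency(37, 200), 18.5)
  expect_error(plating_efficiency(colony_count(1, 0)), NA)
  expect_error(colony_count(0, 5), ">= 1")

  # control normalizes itself to SF = 1 exactly
  ctrl <- colony_count(100, 50)
  pe <- plating_efficiency(ctrl)
  expect_equal(survival_fraction(ctrl, pe), 1.0)
  expect_equal(survival_fraction(25, control_pe = 50, cells_seeded = 100), 0.5)
  expect_equal(survival_fraction(0, control_pe = 50, cells_seeded = 100), 0)
  expect_error(survival_fraction(10, control_pe = 0, cells_seeded = 100),
               "zero control plating efficiency")
})

test_that("the exponential fit recovers noiseless parameters exactly", {
  d <- c(0, 0.5, 1, 2, 4)
  fit <- fit_linear_survival(d, exp(-0.5 * d))
  expect_equal(fit$kappa, 0.5, tolerance = 1e-12)
  expect_equal(fit$kappa_se, 0, tolerance = 1e-8)

  # two-point closed form
  fit2 <- fit_linear_survival(c(0, log(2)), c(1, 0.5))
  expect_equal(fit2$kappa, 1.0, tolerance = 1e-12)

  expect_error(fit_linear_survival(1, 0.5), "underdetermined")
  expect_error(suppressWarnings(fit_linear_survival(c(0, 1), c(0, 0))),
               "underdetermined")
  expect_warning(fit_linear_survival(c(0, 1, 2), c(1, 0.5, 0)), "dropped")
})

test_that("kappa estimation is calibrated on noisy synthetic survival data", {
  set.seed(42)
  p <- survival_model_params(kappa_true = 0.3, noise_cv = 0.05)
  kap <- se <- numeric(200)
  for (i in 1:200) {
    dat <- generate_survival_data(p, seed = 1000 + i)
    f <- fit_linear_survival(dat$dose_gy, dat$sf)
    kap[i] <- f$kappa
    se[i] <- f$kappa_se
  }
  expect_equal(mean(kap), 0.3, tolerance = 0.02)
  expect_equal(mean(se), sd(kap), tolerance = 0.25)
})

test_that("IC50 comes from the SF = 0.5 crossing of the fitted curve", {
  a <- c(0, 0.5e6, 1e6, 2e6, 4e6)
  expect_equal(ic50_from_activity(a, exp(-a * log(2) / 2e6))$ic50_bq, 2e6,
               tolerance = 1e-9)
  expect_equal(ic50_from_activity(c(0, 1e6, 2e6), c(1, 0.5, 0.25))$ic50_bq, 1e6,
               tolerance = 1e-9)
  expect_error(ic50_from_activity(c(0, 1e6), c(1, 0.9)), "bracket")

  # unit invariance: Bq vs MBq differ exactly by the unit factor
  sf <- exp(-a * log(2) / 1.13e6)
  in_bq <- ic50_from_activity(a, sf)$ic50_bq
  in_mbq <- ic50_from_activity(a / 1e6, sf)$ic50_bq
  expect_equal(in_bq, in_mbq * 1e6, tolerance = 1e-9)
})

test_that("IC50 is recovered from noisy curves generated at the published C3 value", {
  true_ic50 <- 1.13e6
  a <- c(0, 0.37e6, 0.74e6, 1.85e6, 3.7e6, 7.4e6)
  set.seed(7)
  est <- replicate(200, {
    sf <- exp(-a * log(2) / true_ic50) *
      rlnorm(length(a), -0.5 * log(1 + 0.05^2), sqrt(log(1 + 0.05^2)))
    sf[1] <- 1
    ic50_from_activity(a, sf, require_bracket = FALSE)$ic50_bq
  })
  expect_equal(mean(est), true_ic50, tolerance = 0.03)
})

test_that("RBE endpoints reduce to their closed forms in kappa", {
  ref <- survival_fit(0.3, 0)
  expect_equal(rbe(ref, survival_fit(0.3, 0))$rbe_05, 1.0)
  expect_equal(rbe(ref, survival_fit(0.3, 0))$rbe_2gy, 1.0)
  expect_equal(rbe(ref, survival_fit(0.6, 0))$rbe_05, 2.0)
  for (kt in c(0.1, 0.45, 1.2)) {
    r <- rbe(ref, survival_fit(kt, 0))
    expect_equal(r$rbe_05, kt / 0.3, tolerance = 1e-15)
    expect_equal(r$rbe_2gy, exp(2 * (kt - 0.3)), tolerance = 1e-15)
  }
})

test_that("delta-method RBE errors agree with a sampling propagation oracle", {
  ref <- survival_fit(0.3, 0.02)
  tst <- survival_fit(0.6, 0.05)
  r <- rbe(ref, tst)
  expect_equal(r$rbe_05, 2.0)
  # independent oracle: direct Monte Carlo draws of the kappa pair
  set.seed(2024)
  kr <- rnorm(1e5, 0.3, 0.02)
  kt <- rnorm(1e5, 0.6, 0.05)
  expect_equal(r$rbe_05_se, sd(kt / kr), tolerance = 0.05)
  expect_equal(r$rbe_2gy_se, sd(exp(2 * (kt - kr))), tolerance = 0.05)
  # package's own sampling propagation matches too
  s <- rbe_sampling_se(ref, tst, n = 1e5, seed = 8)
  expect_equal(r$rbe_05_se, s$rbe_05_se, tolerance = 0.05)
})

test_that("foci summaries report both normalization conventions", {
  trt <- rep(4L, 300)
  ctl <- rep(4L, 300)
  s <- foci_summary(trt, ctl)
  expect_equal(s$normalized_ratio, 1)
  expect_equal(s$normalized_difference, 0)
  expect_equal(s$mean, 4)
  expect_equal(s$sd, 0)

  set.seed(5)
  pois <- rpois(500, 5)
  sp <- foci_summary(pois, rpois(500, 1))
  expect_lt(abs(sp$mean - 5), 3 * sqrt(5 / 500))

  expect_warning(foci_summary(rep(1L, 10), rep(1L, 10)), "200")
  expect_error(foci_summary(integer(0), 1L), "non-empty")
})

test_that("micronucleus yields are per-1000-BN rates with optional normalization", {
  expect_equal(mn_yield(10, 1000)$yield_per_1000, 10)
  expect_equal(mn_yield(7, 350)$yield_per_1000, 20)
  y <- mn_yield(30, 1000, control_yield = 15)
  expect_equal(y$normalized, 2)
  expect_equal(mn_yield(15, 1000, control_yield = 15)$normalized, 1)
  expect_error(mn_yield(5, 0), ">= 1")
})
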