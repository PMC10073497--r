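test_that("static strength summary uses the population convention", {
  s <- static_strength_summary(static_forces_published)
  expect_equal(round(s$mean, 1), 254.5)
  expect_equal(round(s$sd, 1), 29.8)
  expect_equal(s$mean, 254.52)
  expect_equal(s$sd, sqrt(mean((static_forces_published - 254.52)^2)))
  expect_equal(static_strength_summary(c(100, 100, 100))$sd, 0)
  expect_equal(static_strength_summary(c(0, 10))$mean, 5)
  expect_equal(static_strength_summary(c(0, 10))$sd, 5)
  expect_error(static_strength_summary(254.5), "at least two")
})

test_that("predicted lives are capped at N_max and flags propagate", {
  cv <- plate_curve()
  # corrected amplitude inside the window but life beyond the cap
  p3 <- predict_life(plate_case("E03"), cv, "gerber")
  expect_identical(p3$status, "finite")
  expect_gt(p3$raw_life, 1e5)
  expect_equal(p3$reported_life, 1e5)
  p4 <- predict_life(plate_case("E04"), cv, "goodman")
  expect_equal(p4$reported_life, 1e5)
  # corrected amplitude below the endurance stress: infinite life, capped
  p5 <- predict_life(plate_case("E05"), cv, "gerber")
  expect_identical(p5$status, "endurance")
  expect_identical(p5$raw_life, Inf)
  expect_equal(p5$reported_life, 1e5)
  # infeasible mean stress propagates as a flag, not an error
  p1 <- predict_life(plate_case("E01"), cv, "goodman")
  expect_identical(p1$status, "infeasible")
  expect_true(is.na(p1$reported_life))
  # low-cycle flag, with optional extrapolation
  p2 <- predict_life(plate_case("E02"), cv, "goodman")
  expect_identical(p2$status, "low_cycle")
  expect_true(is.na(p2$reported_life))
  p2x <- predict_life(plate_case("E02"), cv, "goodman",
                      extrapolate_low_cycle = TRUE)
  expect_lt(p2x$reported_life, 1e3)
})

test_that("reported life never exceeds the cap and is monotone in peak stress", {
  cv <- plate_curve()
  smax <- seq(480, 850, by = 10)
  reported <- vapply(smax, function(s) {
    predict_life(load_case("x", 40, 15, s, 220.1), cv, "gerber")$reported_life
  }, numeric(1))
  expect_true(all(reported <= 1e5))
  expect_true(all(diff(reported) <= 0))
})

test_that("Goodman predicts no longer life than Gerber, case by case", {
  cv <- plate_curve()
  for (tab in list(elastic_peak_stress,
                   c(E01 = 1007.4, E02 = 854.9, E03 = 658.6,
                     E04 = 526.2, E05 = 593.2, E06 = 525.9))) {
    for (lab in names(tab)) {
      cs <- load_case(lab, 40, 15, tab[[lab]], 220.1)
      pg <- predict_life(cs, cv, "goodman", extrapolate_low_cycle = TRUE)
      pe <- predict_life(cs, cv, "gerber", extrapolate_low_cycle = TRUE)
      if (!is.na(pg$reported_life) && !is.na(pe$reported_life))
        expect_lte(pg$reported_life, pe$reported_life)
    }
  }
})

test_that("Basquin fit reproduces the closed-form normal equations", {
  # the three failure points of the published campaign
  obs <- fatigue_observations(c(127.3, 63.6, 44.5), c(1230, 23262, 78567))
  fit <- fit_basquin(obs)
  oracle <- oracle_loglog_fit(obs$force, obs$life)
  expect_equal(fit$exponent, oracle$exponent, tolerance = 1e-12)
  expect_equal(fit$exponent, -0.2497, tolerance = 5e-4)
  expect_equal(fit$coefficient, oracle$coefficient, tolerance = 1e-10)

  # random datasets up to 10 points
  set.seed(13)
  for (i in 1:20) {
    n <- sample(3:10, 1)
    force <- exp(runif(n, 2, 6))
    life <- exp(runif(n, 5, 12))
    fit <- fit_basquin(fatigue_observations(force, life), min_failures = 3)
    oracle <- oracle_loglog_fit(force, life)
    expect_equal(fit$exponent, oracle$exponent, tolerance = 1e-8)
    expect_equal(fit$coefficient, oracle$coefficient, tolerance = 1e-8)
    expect_equal(fit$r_squared, oracle$r_squared, tolerance = 1e-8)
    expect_equal(fit$slope_p_value, oracle$p_value, tolerance = 1e-8)
  }
})

test_that("noise-free data is recovered exactly and replicates are handled", {
  life <- 10^seq(3, 5, length.out = 6)
  obs <- fatigue_observations(500 * life^(-0.1), life)
  fit <- fit_basquin(obs)
  expect_equal(fit$exponent, -0.1, tolerance = 1e-10)
  expect_equal(fit$coefficient, 500, tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  # identical replicate forces with different lives: fit still defined
  rep_obs <- fatigue_observations(c(50, 50, 80), c(2e4, 6e4, 5e3))
  fit2 <- fit_basquin(rep_obs)
  expect_true(fit2$slope_p_value >= 0 && fit2$slope_p_value <= 1)
})

test_that("runout policies and degenerate inputs behave as specified", {
  obs <- fatigue_observations(
    campaign_forces_published, campaign_lives_published,
    censored = campaign_lives_published >= 1e5
  )
  fit_all <- fit_basquin(obs, "as_failure")
  expect_equal(fit_all$n_used, 6)
  fit_fail <- fit_basquin(obs, "exclude")
  expect_equal(fit_fail$n_used, 3)
  expect_error(fit_basquin(obs, min_failures = 4), "insufficient")
  expect_error(
    fit_basquin(fatigue_observations(c(10, 20, 30), c(100, 100, 100))),
    "degenerate"
  )
})

test_that("fatigue limit is the fitted line at the cap", {
  # exact two-anchor line through (1e3, 100 N) and (1e5, 50 N)
  beta <- log10(50 / 100) / 2
  life <- c(1e3, 1e4, 1e5)
  obs <- fatigue_observations(100 * (life / 1e3)^beta, life)
  expect_equal(fatigue_limit(fit_basquin(obs), 1e5), 50, tolerance = 1e-9)

  # full published campaign, runouts kept at the cap
  campaign <- fit_basquin(fatigue_observations(
    campaign_forces_published, campaign_lives_published,
    censored = campaign_lives_published >= 1e5
  ), "as_failure")
  lim <- fatigue_limit(campaign, 1e5)
  expect_equal(lim, 40.3, tolerance = 0.005)
  # within 5% of the experimentally reported 40.92 N
  expect_lt(abs(lim - 40.92) / 40.92, 0.05)

  # noiseless population with a true 40 N limit at 1e5 cycles
  life <- 10^seq(3.2, 5, length.out = 8)
  obs40 <- fatigue_observations(40 * (life / 1e5)^(-0.25), life)
  expect_equal(fatigue_limit(fit_basquin(obs40), 1e5), 40, tolerance = 1e-6)
})
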