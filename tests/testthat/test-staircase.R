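test_that("initial force is the configured fraction of mean static strength", {
  cfg <- campaign_config()
  f0 <- initial_force(static_forces_published, cfg)
  expect_equal(f0, 127.26)
  expect_equal(report_force(f0, cfg), 127.3)
  cfg80 <- campaign_config(start_fraction = 0.8)
  expect_equal(report_force(initial_force(static_forces_published, cfg80),
                            cfg80), 203.6)
  expect_equal(initial_force(100, cfg), 50)
  expect_error(initial_force(numeric(0), cfg), "insufficient")
})

test_that("next force follows the banded multipliers and bisection rule", {
  cfg <- campaign_config()
  hist1 <- data.frame(force_exact = 127.26, outcome = "failure")
  # early failure (<10% of the cap): halve
  f2 <- next_force(127.26, "failure", 1230, hist1, cfg)
  expect_equal(f2, 63.63)
  expect_equal(report_force(f2, cfg), 63.6)
  # intermediate failure (10-50%): times 0.7
  f3 <- next_force(f2, "failure", 23262, hist1, cfg)
  expect_equal(report_force(f3, cfg), 44.5)
  # late failure (>=50%): times 0.8
  f4 <- next_force(f3, "failure", 78567, hist1, cfg)
  expect_equal(report_force(f4, cfg), 35.6)
  # runout: bisect toward the lowest failing force so far
  hist <- data.frame(force_exact = c(127.26, f2, f3),
                     outcome = rep("failure", 3))
  f5 <- next_force(f4, "runout", 1e5, hist, cfg)
  expect_equal(f5, (f4 + f3) / 2)
  expect_equal(report_force(f5, cfg), 40.1)
  # runout with no prior failure: configured increase
  empty <- data.frame(force_exact = numeric(0), outcome = character(0))
  expect_equal(next_force(100, "runout", 1e5, empty, cfg), 125)
})

test_that("replaying the published campaign reproduces the force sequence", {
  rec <- run_campaign(replay_oracle(campaign_lives_published),
                      static_forces_published, campaign_config())
  expect_identical(rec$status, "completed")
  expect_equal(nrow(rec$specimens), 6)
  expect_equal(rec$specimens$force_reported, campaign_forces_published)
  expect_equal(sum(rec$specimens$outcome == "runout"), 3)
  # bit-for-bit determinism of the replay
  rec2 <- run_campaign(replay_oracle(campaign_lives_published),
                       static_forces_published, campaign_config())
  expect_identical(rec$specimens, rec2$specimens)
})

test_that("the stop rule and exhaustion status govern termination", {
  cfg <- campaign_config(stop_survivals = 3, max_specimens = 10)
  always_runout <- function(force) list(life = 1e5, outcome = "runout")
  rec <- run_campaign(always_runout, 200, cfg)
  expect_identical(rec$status, "completed")
  expect_equal(nrow(rec$specimens), 3)
  always_fail <- function(force) list(life = 500, outcome = "failure")
  rec2 <- run_campaign(always_fail, 200, cfg)
  expect_identical(rec2$status, "exhausted")
  expect_equal(nrow(rec2$specimens), 10)
})

test_that("forces decrease after failures and bisection stays bracketed", {
  pop <- virtual_population(life_scatter = 0.35)
  cfg <- campaign_config(max_specimens = 40)
  for (seed in 1:10) {
    rec <- generate_campaign_dataset(pop, cfg, seed = seed)
    sp <- rec$specimens
    for (i in seq_len(nrow(sp) - 1)) {
      if (sp$outcome[i] == "failure") {
        expect_lt(sp$force_exact[i + 1], sp$force_exact[i])
      } else {
        failed_before <- sp$force_exact[seq_len(i)][sp$outcome[seq_len(i)] == "failure"]
        if (length(failed_before)) {
          expect_gt(sp$force_exact[i + 1], sp$force_exact[i])
          expect_lt(sp$force_exact[i + 1], min(failed_before))
        }
      }
    }
  }
})

test_that("zero-scatter campaigns bracket the true limit within one bisection", {
  pop <- virtual_population(life_scatter = 0)
  rec <- generate_campaign_dataset(pop, campaign_config(), seed = 1)
  truth <- true_fatigue_limit(pop)
  sp <- rec$specimens
  last_runout <- max(sp$force_exact[sp$outcome == "runout"])
  lowest_failure <- min(sp$force_exact[sp$outcome == "failure"])
  # the surviving forces and the lowest failing force bracket the limit,
  # and the final bracket is no wider than one bisection of the previous one
  expect_lt(last_runout, truth)
  expect_gt(lowest_failure, truth)
  first_runout <- sp$force_exact[sp$outcome == "runout"][1]
  expect_lte(lowest_failure - last_runout,
             (lowest_failure - first_runout) / 2 + 1e-9)
})

test_that("sufficiency test flags informative campaigns and passes nulls", {
  rec <- run_campaign(replay_oracle(campaign_lives_published),
                      static_forces_published, campaign_config())
  p <- sufficiency_test(rec)
  oracle <- oracle_loglog_fit(rec$specimens$force_exact, rec$specimens$life)
  expect_equal(p, oracle$p_value, tolerance = 1e-10)
  expect_lt(p, 0.05)

  # exactly collinear log-log points: zero residual, decisive slope
  life <- c(1e3, 1e4, 5e4)
  coll <- structure(
    list(specimens = data.frame(specimen = c("a", "b", "c"),
                                force_exact = 100 * life^(-0.2),
                                force_reported = NA_real_,
                                outcome = "failure", life = life),
         status = "completed", config = campaign_config()),
    class = "campaign_record"
  )
  expect_lt(sufficiency_test(coll), 0.05)

  # lives independent of force: slope p-value behaves like a uniform null
  set.seed(99)
  pvals <- replicate(60, {
    force <- c(127.3, 63.6, 31.8, 15.9, 8)
    lives <- exp(runif(5, 7, 11))
    fit_basquin(fatigue_observations(force, lives))$slope_p_value
  })
  expect_gt(mean(pvals > 0.05), 0.7)
  expect_gt(stats::median(pvals), 0.1)
})

test_that("configuration invariants are enforced", {
  expect_error(campaign_config(band_multipliers = c(0.5, 0.4, 0.8)),
               "non-decreasing")
  expect_error(campaign_config(band_thresholds = c(0.5, 0.1)), "increasing")
  expect_error(campaign_config(stop_survivals = 0), "stop_survivals")
  expect_error(campaign_config(report_rounding = 0), "report_rounding")
})
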