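test_that("clearance rate, coefficient and pump-flow conversions agree with the operating conditions", {
  # published coefficients for the basal and reflex turnover rates
  expect_equal(beta_from_rate(0.11), 0.117)
  expect_equal(beta_from_rate(0.16), 0.174)
  expect_equal(beta_from_rate(0), 0)
  expect_equal(beta_from_rate(0.5, rounded = FALSE), log(2))

  # pump flows against the 300 uL donor load
  expect_equal(flow_for_rate(0.16, 300), 48)
  expect_equal(flow_for_rate(0.11, 300), 33)
  expect_equal(flow_for_rate(0, 300), 0)

  # physiological anchors: 1.1 uL/min basal tear flow over 7-10 uL
  expect_equal(rate_for_flow(1.1, 10), 0.11)
  expect_equal(round(rate_for_flow(1.1, 7), 3), 0.157)
  expect_equal(rate_for_flow(48, 300), 0.16)

  expect_error(beta_from_rate(1), "whole volume")
  expect_error(beta_from_rate(-0.1), "whole volume")
  expect_error(flow_for_rate(0.1, 0), "positive")
  expect_error(rate_for_flow(1.1, -5), "positive")
})

test_that("discrete per-minute compounding reproduces the tabulated percentages", {
  pct <- 100 * discrete_volume(0.11, 300, 0:3) / 300
  expect_equal(round_half_up(pct, 2), c(100, 89, 79.21, 70.50))
  expect_equal(discrete_volume(0.11, 300, 1), 267)
  expect_equal(discrete_volume(0.3, 123, 0), 123)
  expect_error(discrete_volume(0.11, 300, -1), "non-negative")
  expect_error(discrete_volume(0.11, 300, 1.5), "non-negative")
})

test_that("single- and two-stage schedules evaluate the piecewise exponential correctly", {
  s11 <- clearance_schedule(0.11, 15, v0 = 300)
  s16 <- clearance_schedule(0.16, 15, v0 = 300)
  expect_equal(percent_remaining(s11, 15), 17.29)
  expect_equal(percent_remaining(s16, 15), 7.35)
  expect_equal(percent_remaining(s11, 0), 100)
  expect_equal(volume_at(s11, 0), 300)

  two <- paper_schedule()
  expect_equal(volume_at(two, 2), 211.83, tolerance = 0.2 / 211.83)
  expect_equal(percent_remaining(two, 15), 15.43)
  # predict() is an alias for volume_at on the schedule object
  expect_identical(predict(two, c(0, 2, 15)), volume_at(two, c(0, 2, 15)))
  expect_equal(unname(coef(two)), c(0.174, 0.117))

  expect_error(volume_at(two, -1), "horizon")
  expect_error(volume_at(two, 15.01), "horizon")
  expect_error(clearance_schedule(c(0.16, 0.11), c(Inf, 2)), "unbounded")
  expect_error(clearance_schedule(0.11, 15, v0 = 0), "positive")
  expect_error(clearance_schedule(0.11, -2), "positive")

  # an unbounded final regime evaluates at any t but needs t_end to simulate
  open <- clearance_schedule(c(0.16, 0.11), c(2, Inf), v0 = 300)
  expect_equal(volume_at(open, 15), volume_at(two, 15))
  expect_error(simulate_trajectory(open), "t_end")
})

test_that("trajectory simulation matches the closed form and balances mass", {
  two <- paper_schedule()
  traj <- simulate_trajectory(two, dt = 0.001)
  v15 <- traj$volume_uL[traj$time_min == 15]
  closed <- 211.8297 * exp(-0.117 * 13)
  expect_lt(abs(v15 - closed) / closed, 0.001)
  expect_equal(traj$volume_uL + traj$drained_uL, rep(300, nrow(traj)))
  expect_equal(traj$volume_uL[1], 300)

  none <- clearance_schedule(0, 15, v0 = 250)
  flat <- simulate_trajectory(none, dt = 0.5)
  expect_true(all(flat$volume_uL == 250))
  expect_true(all(flat$drained_uL == 0))
  expect_error(simulate_trajectory(two, dt = 0), "positive")

  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(traj, path)
  back <- read.csv(path)
  expect_equal(names(back), c("time_min", "volume_uL", "percent", "drained_uL"))
  expect_equal(nrow(back), nrow(traj))
})

test_that("exposure AUC uses the piecewise closed form", {
  expect_equal(auc_volume(clearance_schedule(0, 15, v0 = 300), 15), 4500)
  s <- clearance_schedule(0.11, 15, v0 = 300)
  expect_equal(auc_volume(s, 15), 300 * (1 - exp(-0.117 * 15)) / 0.117)
  expect_equal(auc_volume(s, 0), 0)
  # fine-trapezoid cross-check on the two-stage schedule
  two <- paper_schedule()
  tr <- simulate_trajectory(two, dt = 1e-4)
  trap <- sum(diff(tr$time_min) *
                (head(tr$volume_uL, -1) + tail(tr$volume_uL, -1)) / 2)
  expect_equal(auc_volume(two, 15), trap, tolerance = 1e-6)
  expect_error(auc_volume(two, -1), "horizon")
})

test_that("fit_beta recovers the generating coefficient", {
  t <- 0:15
  fit <- fit_beta(t, 300 * exp(-0.117 * t))
  expect_equal(unname(coef(fit)), 0.117, tolerance = 1e-9)
  expect_equal(fit$v0, 300, tolerance = 1e-6)
  expect_equal(unname(coef(fit_beta(t, rep(300, 16)))), 0)
  expect_error(fit_beta(0:1, c(300, 200)), "at least 3")
  expect_error(fit_beta(0:3, c(300, 200, -1, 50)), "positive")
})

test_that("schedules parse from compact text and config files", {
  s <- parse_schedule("16:2,11:13", v0 = 300)
  expect_equal(percent_remaining(s, 15), 15.43)
  expect_equal(s$flows, c(48, 33))
  open <- parse_schedule("11:inf", v0 = 300)
  expect_false(is.finite(sum(open$durations)))
  expect_error(parse_schedule("16-2"), "percent:duration")

  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("v0: 300", "regimes:",
               "  - rate_percent: 16", "    duration: 2",
               "  - rate_percent: 11", "    duration: 13"), yml)
  s2 <- schedule_from_config(yml)
  expect_equal(volume_at(s2, 15), volume_at(s, 15))

  js <- withr::local_tempfile(fileext = ".json")
  writeLines('{"v0": 300, "regimes": [{"rate_percent": 11, "duration": 15}]}', js)
  expect_equal(percent_remaining(schedule_from_config(js), 15), 17.29)
  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("v0: 300", bad)
  expect_error(schedule_from_config(bad), "regimes")
})
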