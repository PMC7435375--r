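test_that("zero event rates give an all-open stream with zero indicators", {
  sim <- simulate_stream(simulation_params(
    plan = data.frame(label = "Still", duration_s = 120),
    regimes = list(Still = regime_params(blink_rate = 0, yawn_rate = 0)),
    seed = 1))
  rec <- sim$stream$records
  expect_false(any(rec$left_closed) || any(rec$mouth_open))
  ind <- sliding_indicators(sim$stream)
  expect_true(all(ind$perclos == 0) && all(ind$ecd == 0) && all(ind$aot == 0))
})

test_that("a saturated closure regime pins PERCLOS at 1 and ECD at the window", {
  # mean closure duration fills the whole cycle -> permanently closed
  sat <- regime_params(blink_rate = 0, sustained_rate = 1,
                       sustained_duration_mean_s = 60)
  sim <- simulate_stream(simulation_params(
    plan = data.frame(label = "Sat", duration_s = 60),
    regimes = list(Sat = sat), seed = 2))
  ind <- sliding_indicators(sim$stream)
  expect_equal(ind$perclos, 1)
  expect_equal(ind$ecd, 60)
  expect_equal(expected_perclos(sat), 1)
})

test_that("simulation is reproducible under a fixed seed", {
  p <- simulation_params(plan = data.frame(label = "Drowsy", duration_s = 90), seed = 77)
  s1 <- simulate_stream(p)
  s2 <- simulate_stream(p)
  expect_identical(s1$stream$records, s2$stream$records)
  expect_identical(s1$truth, s2$truth)
})

test_that("expected PERCLOS follows the renewal closed-time fraction", {
  expect_equal(expected_perclos(regime_params(blink_rate = 12,
                                              blink_duration_mean_s = 0.25)), 0.05)
  expect_equal(expected_perclos(regime_params(blink_rate = 0, yawn_rate = 0)), 0)
  # saturation: closures longer than the cycle clamp toward 1
  expect_equal(expected_perclos(regime_params(blink_rate = 2,
                                              blink_duration_mean_s = 45)), 1)
  # independent blink + sustained processes combine as a union
  rg <- regime_params(blink_rate = 12, blink_duration_mean_s = 0.25,
                      sustained_rate = 3, sustained_duration_mean_s = 4)
  expect_equal(expected_perclos(rg), 1 - 0.95 * 0.8)
})

test_that("long-run windowed PERCLOS sits within 3 SE of its expectation", {
  # analytic SE from the 2-state Markov autocovariance: var of the time-mean
  # over T seconds is ~ 2 f (1-f) / (theta T), theta = 1/mean_on + 1/mean_off
  check_regime <- function(rg, mean_on, cycle, seed) {
    sim <- simulate_stream(simulation_params(
      plan = data.frame(label = "R", duration_s = 1800),
      regimes = list(R = rg), seed = seed))
    ind <- sliding_indicators(sim$stream)
    f <- expected_perclos(rg)
    theta <- 1 / mean_on + 1 / (cycle - mean_on)
    se <- sqrt(2 * f * (1 - f) / (theta * 1800))
    expect_lt(abs(mean(ind$perclos) - f), 3 * se)
  }
  check_regime(regime_params(blink_rate = 15, blink_duration_mean_s = 0.2),
               0.2, 4, seed = 11)
  check_regime(regime_params(blink_rate = 0, sustained_rate = 3,
                             sustained_duration_mean_s = 5),
               5, 20, seed = 12)
})

test_that("truth labels partition the stream's time exactly", {
  sim <- simulate_stream(simulation_params(
    plan = data.frame(label = c("Normal", "Drowsy", "Severe"),
                      duration_s = c(70, 45, 65)), seed = 3))
  expect_equal(sim$truth$t, 1:180)
  expect_equal(as.vector(table(sim$truth$label)[c("Normal", "Drowsy", "Severe")]),
               c(70, 45, 65))
  # per-second pipeline output aligns to truth with no gaps
  ind <- sliding_indicators(sim$stream)
  expect_true(all(ind$t %in% sim$truth$t))
})

test_that("noiseless continuous rendering is exactly recoverable", {
  sim <- simulate_stream(simulation_params(
    plan = data.frame(label = "Drowsy", duration_s = 90), seed = 21))
  cont <- render_continuous(sim$stream)
  expect_false(is_binarized(cont))
  prof <- calibrate(cont)
  bin <- binarize_stream(cont, prof)
  expect_identical(bin$records$left_closed, sim$stream$records$left_closed)
  expect_identical(bin$records$right_closed, sim$stream$records$right_closed)
  expect_identical(bin$records$mouth_open, sim$stream$records$mouth_open)
})

test_that("moderate rendering noise still recovers almost all frames", {
  sim <- simulate_stream(simulation_params(
    plan = data.frame(label = "Drowsy", duration_s = 300), seed = 22))
  cont <- render_continuous(sim$stream, noise_frac = 0.05, seed = 23)
  prof <- calibrate(cont)
  bin <- binarize_stream(cont, prof)
  truth_closed <- sim$stream$records$left_closed & sim$stream$records$right_closed
  got_closed <- bin$records$left_closed & bin$records$right_closed
  agree <- mean(got_closed == truth_closed & bin$records$mouth_open ==
                  sim$stream$records$mouth_open)
  expect_gte(agree, 0.99)
})

test_that("scaling the rendering gains scales references, not states", {
  sim <- simulate_stream(simulation_params(
    plan = data.frame(label = "Drowsy", duration_s = 90), seed = 24))
  c1 <- render_continuous(sim$stream, open_gap_left = 12, open_gap_right = 12)
  c2 <- render_continuous(sim$stream, open_gap_left = 24, open_gap_right = 24)
  p1 <- calibrate(c1); p2 <- calibrate(c2)
  expect_equal(p2$open_gap_ref_left, 2 * p1$open_gap_ref_left)
  expect_identical(binarize_stream(c1, p1)$records$left_closed,
                   binarize_stream(c2, p2)$records$left_closed)
})

test_that("plans are validated", {
  expect_error(simulation_params(plan = data.frame(label = "X", duration_s = 60)),
               "without a regime")
  expect_error(simulation_params(plan = data.frame(label = "Normal", duration_s = -1)),
               "positive")
  expect_error(simulation_params(plan = data.frame(label = character(0),
                                                   duration_s = numeric(0))),
               "empty")
})
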