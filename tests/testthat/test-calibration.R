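make_cont_stream <- function(n = 1800, fps = 30, left = 10, right = 11, mar = 0.4) {
  state_stream(data.frame(t = (seq_len(n) - 1) / fps,
                          left_gap = rep_len(left, n),
                          right_gap = rep_len(right, n),
                          mar = rep_len(mar, n)),
               nominal_fps = fps)
}

test_that("calibration collects 1800 values per signal at 60 s / 30 fps", {
  s <- make_cont_stream()
  prof <- calibrate(s)
  expect_equal(unname(prof$n_values), c(1800L, 1800L, 1800L))
  expect_equal(unname(prof$k_top), c(90L, 90L, 90L))  # ceil(0.05 * 1800)
  # constant signal: reference equals the constant exactly
  expect_equal(prof$open_gap_ref_left, 10)
  expect_equal(prof$open_gap_ref_right, 11)
})

test_that("top-fraction averaging matches a brute-force sort oracle", {
  set.seed(42)
  for (n in c(97, 600, 1800)) {
    vals <- runif(n, 5, 15)
    s <- state_stream(data.frame(t = (seq_len(n) - 1) / 30,
                                 left_gap = vals, right_gap = vals, mar = 0.3),
                      nominal_fps = 30)
    prof <- calibrate(s, duration_s = n / 30, top_fraction = 0.05)
    k <- ceiling(0.05 * n)
    expect_equal(prof$open_gap_ref_left, mean(sort(vals, decreasing = TRUE)[1:k]))
    # permutation invariance (order statistic + mean)
    perm <- sample(n)
    s2 <- state_stream(data.frame(t = (seq_len(n) - 1) / 30,
                                  left_gap = vals[perm], right_gap = vals[perm],
                                  mar = 0.3),
                       nominal_fps = 30)
    prof2 <- calibrate(s2, duration_s = n / 30, top_fraction = 0.05)
    expect_equal(prof2$open_gap_ref_left, prof$open_gap_ref_left)
  }
})

test_that("frame classification applies the 20% and 0.7 rules", {
  prof <- calibrate(make_cont_stream(left = 10, right = 10))
  # both eyes below 20% of reference -> closed
  expect_true(classify_frame(list(left_gap = 1.9, right_gap = 1.5), prof)["eyes_closed"])
  # one eye wide open -> not closed under the AND combination
  expect_false(classify_frame(list(left_gap = 1.9, right_gap = 5.0), prof)["eyes_closed"])
  # strict mar > 0.7
  expect_true(classify_frame(list(left_gap = 9, right_gap = 9, mar = 0.71), prof)["mouth_open"])
  expect_false(classify_frame(list(left_gap = 9, right_gap = 9, mar = 0.70), prof)["mouth_open"])
  # per-eye AND vs OR combination, brute force over the four flag combinations
  prof_any <- calibrate(make_cont_stream(left = 10, right = 10), eye_combine = "any")
  for (lc in c(TRUE, FALSE)) for (rc in c(TRUE, FALSE)) {
    rec <- list(left_gap = if (lc) 1 else 9, right_gap = if (rc) 1 else 9)
    expect_equal(unname(classify_frame(rec, prof)["eyes_closed"]), lc && rc)
    expect_equal(unname(classify_frame(rec, prof_any)["eyes_closed"]), lc || rc)
  }
  expect_error(classify_frame(list(left_gap = 5, right_gap = 5)), "calibrat")
})

test_that("gap scaling rescales references and leaves classifications unchanged", {
  set.seed(7)
  n <- 1800
  gaps <- runif(n, 2, 12)
  mk <- function(c_) state_stream(
    data.frame(t = (seq_len(n) - 1) / 30, left_gap = c_ * gaps,
               right_gap = c_ * gaps, mar = 0.3),
    nominal_fps = 30)
  p1 <- calibrate(mk(1)); p3 <- calibrate(mk(3))
  expect_equal(p3$open_gap_ref_left, 3 * p1$open_gap_ref_left)
  b1 <- binarize_stream(mk(1), p1)$records$left_closed
  b3 <- binarize_stream(mk(3), p3)$records$left_closed
  expect_identical(b1, b3)
})

test_that("binarize_stream matches per-frame classification and is idempotent", {
  sim <- simulate_stream(simulation_params(
    plan = data.frame(label = "Drowsy", duration_s = 70), seed = 5))
  cont <- render_continuous(sim$stream)
  prof <- calibrate(cont)
  bin <- binarize_stream(cont, prof)
  expect_true(is_binarized(bin))
  # frame-wise oracle: loop of classify_frame
  for (i in seq(1, nrow(cont$records), by = 97)) {
    cls <- classify_frame(as.list(cont$records[i, ]), prof)
    expect_equal(unname(bin$records$mouth_open[i]), unname(cls["mouth_open"]))
    expect_equal(unname(bin$records$left_closed[i] & bin$records$right_closed[i]),
                 unname(cls["eyes_closed"]))
  }
  # idempotence / fixed point
  expect_identical(binarize_stream(bin, prof), bin)
  cls1 <- classify_frame(as.list(bin$records[1, ]), prof)
  expect_identical(unname(cls1["eyes_closed"]),
                   unname(bin$records$left_closed[1] & bin$records$right_closed[1]))
})

test_that("calibration errors on short or measurement-free streams", {
  expect_error(calibrate(make_cont_stream(n = 900)), "insufficient")
  bin <- make_binary_stream(rep(FALSE, 1800))
  expect_error(calibrate(bin), "impossible|no continuous")
})

test_that("profiles round-trip through YAML", {
  prof <- calibrate(make_cont_stream(left = 9.5, right = 10.5, mar = 0.45))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_profile(prof, path)
  p2 <- read_profile(path)
  expect_equal(p2$open_gap_ref_left, prof$open_gap_ref_left)
  expect_equal(p2$open_gap_ref_right, prof$open_gap_ref_right)
  expect_equal(p2$mar_open_threshold, prof$mar_open_threshold)
  expect_equal(p2$eye_combine, prof$eye_combine)
})
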