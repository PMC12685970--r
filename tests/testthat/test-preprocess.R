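test_that("short gaps are linearly interpolated and flagged; long and boundary gaps are not", {
  rec <- make_rec(c(1, NA, NA, 2), valid = c(TRUE, FALSE, FALSE, TRUE))
  out <- interpolate_gaps(rec, preprocess_params(max_gap_ms = 75, margin_ms = 0.5))
  expect_equal(out$x, c(1, 1 + 1/3, 1 + 2/3, 2), tolerance = 1e-12)
  expect_equal(out$valid, rep(TRUE, 4))
  expect_equal(out$interpolated, c(FALSE, TRUE, TRUE, FALSE))

  # a 100-ms gap exceeds the 75-ms default and stays invalid
  n_gap <- 100
  valid <- c(rep(TRUE, 50), rep(FALSE, n_gap), rep(TRUE, 50))
  x <- ifelse(valid, 1, NA)
  out2 <- interpolate_gaps(make_rec(x, valid = valid), preprocess_params())
  expect_equal(sum(!out2$valid), n_gap)

  # boundary gap: no flanking anchor, untouched
  out3 <- interpolate_gaps(make_rec(c(NA, NA, 1, 1),
                                    valid = c(FALSE, FALSE, TRUE, TRUE)))
  expect_equal(out3$valid, c(FALSE, FALSE, TRUE, TRUE))
})

test_that("interpolation anchors average the valid margin on each side of the gap", {
  # flanks {0.9, 1.1} and {1.9, 2.1}: anchors must be their means 1.0 and 2.0
  x <- c(0.9, 1.1, NA, NA, NA, 1.9, 2.1)
  valid <- !is.na(x)
  rec <- make_rec(x, valid = valid)
  out <- interpolate_gaps(rec, preprocess_params(max_gap_ms = 75, margin_ms = 1.5))
  # independent oracle: mean-then-interpolate by hand
  a0 <- mean(c(0.9, 1.1)); a1 <- mean(c(1.9, 2.1))
  t <- rec$time_ms
  expected <- a0 + (t[3:5] - t[2]) / (t[6] - t[2]) * (a1 - a0)
  expect_equal(out$x[3:5], expected, tolerance = 1e-12)
})

test_that("interpolation preserves sample count, timestamps, valid originals, and is idempotent", {
  sim <- simulate_gaze(sim_spec(random_fixation_plan(4, seed = 9), rate_hz = 500,
                                noise_rms_deg = 0.3, loss_prob = 0.1, seed = 9))
  rec <- sim$recording
  out <- interpolate_gaps(rec)
  expect_equal(nrow(out), nrow(rec))
  expect_equal(out$time_ms, rec$time_ms)
  expect_equal(out$x[rec$valid], rec$x[rec$valid])
  expect_lte(mean(!out$valid), mean(!rec$valid))
  expect_identical(interpolate_gaps(out), out)
})

test_that("median smoothing rejects a singleton spike, average spreads it", {
  const <- make_rec(rep(2, 50))
  expect_equal(smooth_gaze(const)$x, rep(2, 50))

  spike <- make_rec(c(0, 0, 10, 0, 0))
  med <- smooth_gaze(spike, preprocess_params(smooth_window_ms = 3,
                                              smooth_method = "median"))
  expect_equal(med$x[3], 0)
  avg <- smooth_gaze(spike, preprocess_params(smooth_window_ms = 3,
                                              smooth_method = "average"))
  expect_equal(avg$x[3], 10 / 3)
})

test_that("smoothing windows never bridge invalid samples", {
  x <- c(0, 0, 0, NA, 10, 10, 10)
  valid <- !is.na(x)
  out <- smooth_gaze(make_rec(x, valid = valid),
                     preprocess_params(smooth_window_ms = 5,
                                       smooth_method = "average"))
  expect_equal(out$x[valid], c(0, 0, 0, 10, 10, 10))  # no cross-gap mixing
  expect_equal(out$valid, valid)
  expect_equal(out$time_ms, (0:6))
})

test_that("longer smoothing windows make a gaze step less abrupt", {
  x <- c(rep(0, 100), rep(5, 100))
  peak_vel <- vapply(c(5, 15, 45), function(w) {
    rec <- smooth_gaze(make_rec(x), preprocess_params(smooth_window_ms = w,
                                                      smooth_method = "average"))
    max(compute_velocity(rec)$velocity_dps, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(peak_vel) < 0))
})

test_that("downsampling block-averages valid samples and keeps block-first timestamps", {
  n <- 101
  rec <- make_rec(rep(1.5, n), rate_hz = 1200)
  out <- downsample_gaze(rec, 600)
  expect_equal(nrow(out), ceiling(n / 2))
  expect_equal(unique(out$x), 1.5)
  expect_equal(out$time_ms, rec$time_ms[seq(1, n, by = 2)])

  rec2 <- make_rec(c(1, 3), valid = c(TRUE, FALSE), rate_hz = 1000)
  out2 <- downsample_gaze(rec2, 500)
  expect_equal(out2$x, 1)          # mean over the valid subset only
  expect_true(out2$valid)

  expect_error(downsample_gaze(rec, 2400), class = "gazekit_input_error")
})
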