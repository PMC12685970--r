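test_that("read_gaze_table maps columns, invalidates blank coordinates, and is deterministic", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("ts,gx,gy", "0,1.0,2.0", "1,1.1,2.1", "2,,2.2", "3,1.3,2.3"), path)
  cmap <- list(t = "ts", x = "gx", y = "gy")
  rec <- read_gaze_table(path, column_map = cmap, unit = "deg")
  expect_s3_class(rec, "gaze_recording")
  expect_equal(nrow(rec), 4)                      # order and count preserved
  expect_equal(rec$valid, c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(rec$time_ms, 0:3)
  rec2 <- read_gaze_table(path, column_map = cmap, unit = "deg")
  expect_identical(rec, rec2)
})

test_that("timestamps in seconds are scaled to ms and re-based to zero", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t,x,y", "10.000,0,0", "10.001,1,0", "10.002,2,0"), path)
  rec <- read_gaze_table(path, unit = "deg", time_unit = "s")
  expect_equal(rec$time_ms, c(0, 1, 2))
})

test_that("reader errors name the missing column and the offending timestamp", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t,x,y", "0,0,0", "1,1,1"), path)
  expect_error(read_gaze_table(path, column_map = list(t = "t", x = "gx", y = "y"),
                               unit = "deg"),
               regexp = "gx", class = "gazekit_config_error")
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t,x,y", "0,0,0", "2,1,1", "1,2,2"), path2)
  expect_error(read_gaze_table(path2, unit = "deg"),
               regexp = "3", class = "gazekit_input_error")
})

test_that("binocular column maps average valid eyes and fall back to one eye", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t,xl,yl,xr,yr",
               "0,1,1,3,3",     # both valid -> mean
               "1,2,2,,",       # right missing -> left
               "2,,,4,4",       # left missing -> right
               "3,,,,"),        # neither -> invalid
             path)
  rec <- read_gaze_table(path, column_map = list(
    t = "t", x_left = "xl", y_left = "yl", x_right = "xr", y_right = "yr"),
    unit = "deg")
  expect_equal(rec$x, c(2, 2, 4, NA))
  expect_equal(rec$valid, c(TRUE, TRUE, TRUE, FALSE))
})

test_that("pixel/degree conversion is exact about the screen center and invertible", {
  g <- screen_geometry(65, 52.7, 29.6, 1920, 1080)
  center <- make_rec(960, 540, unit = "px", geometry = g)
  deg <- pixels_to_degrees(center)
  expect_equal(deg$x, 0)
  expect_equal(deg$y, 0)
  # a point 65 * tan(1 deg) cm right of center subtends exactly 1 degree
  px_per_cm <- 1920 / 52.7
  p <- make_rec(960 + 65 * tan(pi / 180) * px_per_cm, 540, unit = "px",
                geometry = g)
  expect_equal(pixels_to_degrees(p)$x, 1, tolerance = 1e-12)
  # round trip on a random trace
  px <- withr::with_seed(5, make_rec(runif(200, 0, 1920), runif(200, 0, 1080),
                                     unit = "px", geometry = g))
  rt <- degrees_to_pixels(pixels_to_degrees(px))
  expect_lt(max(abs(rt$x - px$x)), 1e-9)
  expect_lt(max(abs(rt$y - px$y)), 1e-9)
  expect_equal(rt$valid, px$valid)
  # conversion without geometry is a configuration error
  expect_error(pixels_to_degrees(make_rec(0, 0, unit = "px")),
               class = "gazekit_config_error")
})

test_that("screen-proportion input converts through pixels", {
  g <- screen_geometry(65, 52.7, 29.6, 1920, 1080)
  rec <- make_rec(0.5, 0.5, unit = "prop", geometry = g)
  expect_equal(pixels_to_degrees(rec)$x, 0)
  expect_equal(proportion_to_pixels(rec)$x, 960)
})

test_that("sampling-rate estimation uses the median interval and resists dropped samples", {
  expect_equal(estimate_sampling_rate(make_rec(rep(0, 100), rate_hz = 1200)),
               1200, tolerance = 1)
  rec <- as_gaze_recording(data.frame(time_ms = 0:3, x = 0, y = 0), "deg")
  expect_equal(estimate_sampling_rate(rec), 1000)
  t_drop <- c(0:49, 51:100)  # one dropped sample in a 1 ms grid
  rec2 <- as_gaze_recording(data.frame(time_ms = t_drop, x = 0, y = 0), "deg")
  expect_equal(estimate_sampling_rate(rec2), 1000)
  expect_error(estimate_sampling_rate(make_rec(0)), class = "gazekit_input_error")
})

test_that("event tables round-trip through CSV including the empty set", {
  sim <- simulate_gaze(sim_spec(random_fixation_plan(3, seed = 2),
                                rate_hz = 500, seed = 2))
  ev <- classify_ivt(sim$recording)
  path <- withr::local_tempfile(fileext = ".csv")
  write_events_table(ev, path)
  back <- read_events_table(path)
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(ev),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(sum(back$kind == "fixation"), 3)
  empty <- ev[0, ]
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_events_table(empty, path2)
  expect_equal(nrow(read_events_table(path2)), 0)
})
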