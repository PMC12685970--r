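test_that("point membership uses inclusive boundaries for both shapes", {
  r <- aoi_rectangle("box", -1, -2, 3, 4)
  expect_true(point_in_aoi(1, 1, r))        # interior
  expect_true(point_in_aoi(-1, -2, r))      # corner, inclusive
  expect_true(point_in_aoi(3, 4, r))
  expect_false(point_in_aoi(3.001, 4, r))
  e <- aoi_ellipse("disc", 0, 0, 2, 1)
  expect_true(point_in_aoi(0, 0, e))
  expect_true(point_in_aoi(2, 0, e))        # on the boundary
  expect_false(point_in_aoi(2 * 1.001, 0, e))
  expect_error(point_in_aoi(0, 0, r, unit = "px"), class = "gazekit_unit_error")
})

test_that("AOI construction and JSON round trips validate their inputs", {
  expect_error(aoi_rectangle("bad", 1, 0, 0, 1), class = "gazekit_param_error")
  expect_error(aoi_ellipse("bad", 0, 0, -1, 1), class = "gazekit_param_error")
  aois <- dplyr::bind_rows(aoi_rectangle("left", -10, -5, -2, 5),
                           aoi_ellipse("right", 6, 0, 3, 4))
  path <- withr::local_tempfile(fileext = ".json")
  write_aois(aois, path)
  back <- read_aois(path)
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(aois))
  dup <- dplyr::bind_rows(aoi_rectangle("a", 0, 0, 1, 1),
                          aoi_rectangle("a", 2, 2, 3, 3))
  expect_error(aoi_test(make_events(0, 100), dup), class = "gazekit_param_error")
})

test_that("fixation-mode statistics count, clip, and time first entries", {
  aois <- aoi_rectangle("face", -1, -1, 1, 1)
  ev <- make_events(onset = c(100), offset = c(400), x = 0, y = 0)
  st <- aoi_test(ev, aois, segment = c(0, 1000))
  face <- st[st$name == "face", ]
  expect_equal(face$n_fixations, 1)
  expect_equal(face$total_fixation_time_ms, 300)
  expect_equal(face$latency_first_inside_ms, 100)

  # nothing inside: latency is missing, never zero
  far <- make_events(100, 400, x = 5, y = 5)
  st2 <- aoi_test(far, aois, segment = c(0, 1000))
  expect_equal(st2$n_fixations[st2$name == "face"], 0)
  expect_true(is.na(st2$latency_first_inside_ms[st2$name == "face"]))
  expect_equal(st2$latency_first_inside_ms[st2$name == "(outside)"], 100)

  # clipping: shrinking the segment never increases any accumulated statistic
  ev3 <- make_events(c(100, 600), c(400, 900), x = 0, y = 0)
  full <- aoi_test(ev3, aois, segment = c(0, 1000))
  narrow <- aoi_test(ev3, aois, segment = c(200, 700))
  expect_lte(narrow$total_fixation_time_ms[1], full$total_fixation_time_ms[1])
  expect_lte(narrow$n_fixations[1], full$n_fixations[1])
  expect_error(aoi_test(ev3, aois, segment = c(500, 500)),
               class = "gazekit_input_error")
})

test_that("fixations that began before the segment add clipped time but no latency", {
  aois <- aoi_rectangle("face", -1, -1, 1, 1)
  ev <- make_events(onset = c(-200, 600), offset = c(300, 800), x = 0, y = 0)
  st <- aoi_test(ev, aois, segment = c(0, 1000))
  face <- st[st$name == "face", ]
  expect_equal(face$total_fixation_time_ms, 300 + 200)
  expect_equal(face$latency_first_inside_ms, 600)
})

test_that("sample-mode dwell proportions partition across disjoint AOIs", {
  n <- 1000
  x <- c(rep(0, 250), rep(5, 500), rep(-5, 250))
  rec <- make_rec(x, rep(0, n))
  aois <- dplyr::bind_rows(aoi_rectangle("center", -1, -1, 1, 1),
                           aoi_rectangle("right", 4, -1, 6, 1))
  st <- aoi_test(rec, aois)
  expect_equal(st$dwell_proportion[st$name == "center"], 0.25)
  expect_equal(st$dwell_proportion[st$name == "right"], 0.5)
  expect_equal(st$dwell_proportion[st$name == "(outside)"], 0.25)
  expect_equal(sum(st$dwell_proportion), 1)
  # invalid samples are excluded from the denominator
  rec2 <- make_rec(x, rep(0, n), valid = c(rep(TRUE, 500), rep(FALSE, 500)))
  st2 <- aoi_test(rec2, aois)
  expect_equal(st2$n_samples[1], 500)
})

test_that("sample-mode dwell is stable under downsampling of noise-free data", {
  x <- c(rep(0, 240), rep(5, 480), rep(-5, 240))
  rec <- make_rec(x, rate_hz = 1200)
  aois <- aoi_rectangle("right", 4, -1, 6, 1)
  d1 <- aoi_test(rec, aois)$dwell_proportion[1]
  d2 <- aoi_test(downsample_gaze(rec, 300), aois)$dwell_proportion[1]
  expect_equal(d1, d2, tolerance = 0.01)
})

test_that("sample-based membership strategies need the recording and differ from centroid", {
  # centroid inside the AOI, but most samples outside
  x <- c(rep(-3, 120), rep(3.4, 180))
  rec <- make_rec(x)
  ev <- make_events(0, 299, x = mean(x), y = 0)
  aois <- aoi_rectangle("mid", -1, -1, 2, 1)
  cen <- aoi_test(ev, aois, segment = c(0, 300), membership = "centroid")
  expect_equal(cen$n_fixations[1], 1)
  expect_error(aoi_test(ev, aois, segment = c(0, 300),
                        membership = "majority-sample"),
               class = "gazekit_config_error")
  maj <- aoi_test(ev, aois, segment = c(0, 300),
                  membership = "majority-sample", rec = rec)
  expect_equal(maj$n_fixations[1], 0)
})
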