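test_that("close fixations merge when both criteria hold, and only then", {
  ev <- make_events(onset = c(0, 340), offset = c(300, 600),
                    x = c(0, 0.3), y = c(0, 0))
  merged <- merge_adjacent_fixations(ev, max_dist_deg = 0.5, max_gap_ms = 75)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$onset_ms, 0)
  expect_equal(merged$offset_ms, 600)
  expect_equal(merged$sample_time_ms, 560)   # constituent time, not the span

  far <- make_events(onset = c(0, 340), offset = c(300, 600),
                     x = c(0, 2), y = c(0, 0))
  expect_equal(nrow(merge_adjacent_fixations(far, max_dist_deg = 0.5,
                                             max_gap_ms = 75)), 2)
  slow <- make_events(onset = c(0, 400), offset = c(300, 600),
                      x = c(0, 0.3), y = c(0, 0))
  expect_equal(nrow(merge_adjacent_fixations(slow, max_dist_deg = 0.5,
                                             max_gap_ms = 75)), 2)
  expect_error(merge_adjacent_fixations(ev, max_dist_deg = -1),
               class = "gazekit_param_error")
})

test_that("chained merging of short fixation clusters matches an exhaustive oracle", {
  # six short fixations in two spatial clusters around one saccade; the first
  # is separated by a long pause, so three fixations must remain
  onsets  <- c(0,  400, 480, 700, 790, 880)
  offsets <- c(80, 460, 560, 770, 860, 950)
  xs      <- c(0.05, -0.1, 0.1, 5.0, 5.15, 4.9)
  ev <- make_events(onsets, offsets, x = xs, y = rep(0, 6))
  merged <- merge_adjacent_fixations(ev, max_dist_deg = 1.5, max_gap_ms = 200)

  # exhaustive pairwise merge simulation (chronological, re-test after merge)
  fx <- data.frame(on = onsets, off = offsets, x = xs,
                   st = offsets - onsets)
  i <- 1
  while (i < nrow(fx)) {
    gap <- fx$on[i + 1] - fx$off[i]
    d <- abs(fx$x[i + 1] - fx$x[i])
    if (d <= 1.5 && gap <= 200) {
      w <- c(fx$off[i] - fx$on[i], fx$off[i + 1] - fx$on[i + 1])
      fx$x[i] <- weighted.mean(fx$x[c(i, i + 1)], w)
      fx$off[i] <- fx$off[i + 1]
      fx$st[i] <- fx$st[i] + fx$st[i + 1]
      fx <- fx[-(i + 1), ]
    } else i <- i + 1
  }
  expect_equal(nrow(merged), nrow(fx))
  expect_equal(nrow(merged), 3)
  expect_equal(merged$onset_ms, fx$on)
  expect_equal(merged$offset_ms, fx$off)
  expect_equal(merged$x, fx$x, tolerance = 1e-9)
  # summed within-fixation sample time is conserved
  expect_equal(sum(merged$sample_time_ms), sum(offsets - onsets))
})

test_that("merging with a recording recomputes missing proportion over the span", {
  x <- c(rep(0, 200), rep(NA, 30), rep(0.2, 200))
  rec <- make_rec(x, valid = !is.na(x))
  ev <- make_events(c(0, 230), c(199, 429), x = c(0, 0.2), y = c(0, 0))
  merged <- merge_adjacent_fixations(ev, rec = rec, max_dist_deg = 0.5,
                                     max_gap_ms = 75)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$prop_missing, 30 / 430, tolerance = 1e-9)
  # constituent sample time is the sum of the two inputs' sample times
  expect_equal(merged$sample_time_ms, 199 + 199, tolerance = 1e-9)
})

test_that("merging removes saccades engulfed by the merged span", {
  # a small 0.5-deg saccade at ~33 deg/s between two nearby fixations
  x <- c(rep(0, 200), 0.033 * (1:15), rep(0.495, 200))
  rec <- make_rec(x)
  ev <- classify_ivt(rec)
  expect_equal(sum(ev$kind == "fixation"), 2)
  expect_equal(sum(ev$kind == "saccade"), 1)
  merged <- merge_adjacent_fixations(ev, rec = rec, max_dist_deg = 0.5,
                                     max_gap_ms = 75)
  fx <- merged[merged$kind == "fixation", ]
  expect_equal(nrow(fx), 1)
  expect_equal(sum(merged$kind == "saccade"), 0)
})

test_that("merging is idempotent, never increases counts, never shortens mean duration", {
  for (seed in 1:10) {
    ev <- withr::with_seed(seed, {
      n <- sample(4:12, 1)
      dur <- runif(n, 30, 250)
      gap <- runif(n, 1, 300)
      on <- cumsum(gap + c(0, dur[-n]))
      make_events(on, on + dur, x = runif(n, -3, 3), y = runif(n, -3, 3))
    })
    m1 <- merge_adjacent_fixations(ev, max_dist_deg = 1, max_gap_ms = 100)
    m2 <- merge_adjacent_fixations(m1, max_dist_deg = 1, max_gap_ms = 100)
    expect_equal(tibble::as_tibble(m2), tibble::as_tibble(m1))
    expect_lte(nrow(m1), nrow(ev))
    expect_gte(mean(m1$duration_ms), mean(ev$duration_ms))
    expect_equal(sum(m1$sample_time_ms), sum(ev$sample_time_ms))
  }
})

test_that("trimming shrinks fixations symmetrically and drops the over-trimmed", {
  ev <- make_events(c(0, 500, 1000), c(300, 530, 1300))
  expect_identical(trim_fixations(ev, trim_ms = 0), ev)
  tr <- trim_fixations(ev, trim_ms = 20)
  expect_equal(nrow(tr), 2)                 # the 30-ms fixation is gone
  expect_equal(tr$duration_ms, c(260, 260))
  expect_equal(tr$onset_ms, c(20, 1020))
  # with a recording, the centroid is recomputed on the trimmed span
  x <- c(0.4 * (1:20) / 20, rep(1, 260), rev(0.4 * (1:20) / 20))
  rec <- make_rec(c(x, rep(NA, 10)), valid = c(rep(TRUE, 300), rep(FALSE, 10)))
  ev2 <- make_events(0, 299, x = mean(x))
  tr2 <- trim_fixations(ev2, rec = rec, trim_ms = 20)
  expect_equal(tr2$x, 1, tolerance = 1e-9)
})

test_that("discard rules filter fixations and saccades independently", {
  fx <- make_events(c(0, 100, 300), c(40, 180, 500))
  expect_equal(nrow(drop_fixations(fx, min_duration_ms = 60)), 2)
  pm <- make_events(c(0, 100), c(80, 200), prop_missing = c(0.1, 0.9))
  expect_equal(nrow(drop_fixations(pm, min_duration_ms = 0,
                                   max_prop_missing = 0.5)), 1)
  empty <- fx[0, ]
  expect_equal(nrow(drop_fixations(empty)), 0)
})

test_that("trim-then-drop equals dropping on trimmed durations", {
  for (seed in 1:5) {
    ev <- withr::with_seed(seed, {
      n <- 8
      dur <- runif(n, 20, 200)
      gap <- runif(n, 50, 400)
      on <- cumsum(gap + c(0, dur[-n]))
      make_events(on, on + dur)
    })
    a <- drop_fixations(trim_fixations(ev, trim_ms = 15), min_duration_ms = 60)
    b <- trim_fixations(ev, trim_ms = 15)
    b <- b[b$duration_ms >= 60, ]
    expect_equal(tibble::as_tibble(a), tibble::as_tibble(b))
  }
})
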