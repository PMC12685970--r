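test_that("data loss is the proportion of originally-missing samples, surviving interpolation", {
  valid <- c(rep(TRUE, 90), rep(FALSE, 10))
  rec <- make_rec(ifelse(valid, 1, NA), valid = valid)
  expect_equal(proportion_data_loss(rec), 0.10)
  expect_equal(proportion_data_loss(make_rec(rep(1, 50))), 0)
  # a 50-ms interpolated gap still counts as lost
  x <- c(rep(0, 100), rep(NA, 50), rep(0, 100))
  rec2 <- make_rec(x, valid = !is.na(x))
  filled <- interpolate_gaps(rec2)
  expect_equal(mean(!filled$valid), 0)            # recovered for analysis
  expect_equal(proportion_data_loss(filled), 50 / 250)  # but still lost
  expect_error(proportion_data_loss(make_rec(numeric(0), numeric(0))),
               class = "gazekit_input_error")
})

test_that("RMS precision matches closed forms and the 2-sigma law", {
  expect_equal(rmsd_precision(make_rec(rep(3, 100), rep(-1, 100))), 0)
  # x alternating +/- 0.1 about a point: every displacement is 0.2
  alt <- make_rec(rep(c(0.1, -0.1), 50))
  expect_equal(rmsd_precision(alt), 0.2, tolerance = 1e-12)
  # i.i.d. isotropic N(0, sigma^2) noise: RMSD -> 2 sigma
  sigma <- 0.1
  noise <- withr::with_seed(99, make_rec(rnorm(1e5, sd = sigma),
                                         rnorm(1e5, sd = sigma)))
  expect_equal(rmsd_precision(noise), 2 * sigma, tolerance = 0.02)
  # undefined without a consecutive valid pair
  rec <- make_rec(c(1, NA, 1), valid = c(TRUE, FALSE, TRUE))
  expect_warning(out <- rmsd_precision(rec, span = c(0, 2)), "undefined")
  expect_true(is.na(out))
})

test_that("RMS precision is invariant under translation and rotation", {
  rec <- withr::with_seed(7, make_rec(rnorm(500, sd = 0.2), rnorm(500, sd = 0.2)))
  base <- rmsd_precision(rec)
  shifted <- rec; shifted$x <- rec$x + 10; shifted$y <- rec$y - 4
  expect_equal(rmsd_precision(shifted), base)
  th <- 1.1
  rot <- rec
  rot$x <- cos(th) * rec$x - sin(th) * rec$y
  rot$y <- sin(th) * rec$x + cos(th) * rec$y
  expect_equal(rmsd_precision(rot), base, tolerance = 1e-12)
})

test_that("an event stream compared with itself gives exactly zero timing statistics", {
  for (seed in 1:5) {
    ev <- classify_ivt(preprocess_gaze(random_trace(seed, noise = 0.1)$recording))
    expect_gt(nrow(fixations(ev)), 0)
    cmp <- compare_event_streams(ev, ev)
    expect_identical(cmp$rto_onset_ms, 0)
    expect_identical(cmp$rtd_onset_ms, 0)
    expect_identical(cmp$rto_offset_ms, 0)
    expect_identical(cmp$rtd_offset_ms, 0)
    expect_identical(cmp$n_unmatched_a, 0L)
    expect_identical(cmp$n_unmatched_b, 0L)
  }
})

test_that("a uniform onset shift within the margin appears as RTO with zero RTD", {
  a <- make_events(seq(0, 2000, by = 400), seq(0, 2000, by = 400) + 250)
  b <- a
  b$onset_ms <- b$onset_ms + 5
  b$duration_ms <- b$offset_ms - b$onset_ms
  cmp <- compare_event_streams(a, b, margin_ms = 15)
  expect_equal(cmp$rto_onset_ms, 5)
  expect_equal(cmp$rtd_onset_ms, 0)
  expect_equal(cmp$rto_offset_ms, 0)
  expect_equal(cmp$n_matched, nrow(a))
})

test_that("jittered matching reproduces a brute-force first-match oracle", {
  for (seed in 1:5) {
    dat <- withr::with_seed(seed, {
      on <- cumsum(runif(20, 250, 450))
      off <- on + runif(20, 150, 350)
      jit_on <- rnorm(20, 0, 3); jit_off <- rnorm(20, 0, 3)
      list(on = on, off = off, jon = jit_on, joff = jit_off)
    })
    a <- make_events(dat$on, dat$off)
    b <- make_events(dat$on + dat$jon, dat$off + dat$joff)
    cmp <- compare_event_streams(a, b, margin_ms = 15)

    used <- rep(FALSE, 20); don <- c(); doff <- c()
    for (i in 1:20) {
      for (j in 1:20) {
        if (!used[j] &&
            dat$on[j] + dat$jon[j] >= dat$on[i] - 15 &&
            dat$off[j] + dat$joff[j] <= dat$off[i] + 15) {
          used[j] <- TRUE
          don <- c(don, dat$jon[j] + dat$on[j] - dat$on[i])
          doff <- c(doff, dat$joff[j] + dat$off[j] - dat$off[i])
          break
        }
      }
    }
    expect_equal(cmp$n_matched, length(don))
    expect_equal(cmp$rto_onset_ms, mean(don))
    expect_equal(cmp$rtd_onset_ms, sd(don))
    expect_equal(cmp$rto_offset_ms, mean(doff))
  }
})

test_that("the algorithm summary reports the descriptive fixation columns", {
  ev <- make_events(c(0, 300), c(100, 600), algorithm = "ivt")
  s <- summarize_algorithms(ev)
  expect_equal(s$n_fixations, 2L)
  expect_equal(s$mean_duration_ms, 200)
  expect_equal(s$sd_duration_ms, 141.4214, tolerance = 1e-4)
  expect_equal(s$total_fixation_time_ms, 400)

  empty <- ev[0, ]
  attr(empty, "params") <- NULL
  s2 <- summarize_algorithms(list(ev, empty))
  expect_equal(nrow(s2), 1)   # same algorithm label collapses

  two <- summarize_algorithms(list(ev, make_events(0, 100, algorithm = "idt")))
  expect_equal(sort(two$algorithm), c("idt", "ivt"))
})

test_that("fixation-recovery F1 is 1 on self and 0 against disjoint truth", {
  ev <- make_events(c(0, 500), c(300, 900))
  expect_equal(event_recovery_f1(ev, ev)$f1, 1)
  other <- make_events(c(2000, 2500), c(2300, 2900))
  expect_equal(event_recovery_f1(ev, other)$f1, 0)
})
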