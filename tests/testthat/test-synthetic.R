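test_that("the ground-truth table mirrors the plan: n fixations, n-1 saccades", {
  plan <- tibble::tibble(x_deg = c(0, 4, -3, 2, 6), y_deg = c(0, 1, 2, -2, 0),
                         duration_ms = c(200, 250, 180, 300, 220))
  sim <- simulate_gaze(sim_spec(plan, rate_hz = 1000, seed = 1))
  expect_equal(sum(sim$truth_events$kind == "fixation"), 5)
  expect_equal(sum(sim$truth_events$kind == "saccade"), 4)
  expect_equal(nrow(sim$recording),
               length(sim$truth_samples$label))
  # labels partition the recording
  expect_true(all(sim$truth_samples$label %in% c("fixation", "saccade", "lost")))
  # truth amplitudes match the plan geometry
  amps <- sqrt(diff(plan$x_deg)^2 + diff(plan$y_deg)^2)
  expect_equal(sim$truth_events$amplitude_deg[sim$truth_events$kind == "saccade"],
               amps)
})

test_that("simulation is bit-identical under a seed and differs across seeds", {
  spec <- sim_spec(random_fixation_plan(4, seed = 5), noise_rms_deg = 0.2,
                   loss_prob = 0.1, seed = 5)
  a <- simulate_gaze(spec)
  b <- simulate_gaze(spec)
  expect_identical(a$recording, b$recording)
  spec2 <- sim_spec(random_fixation_plan(4, seed = 5), noise_rms_deg = 0.2,
                    loss_prob = 0.1, seed = 6)
  expect_false(identical(simulate_gaze(spec2)$recording$x, a$recording$x))
})

test_that("noise is calibrated so measured RMSD equals the requested value", {
  plan <- tibble::tibble(x_deg = 0, y_deg = 0, duration_ms = 1e5)
  sim <- simulate_gaze(sim_spec(plan, rate_hz = 1000, noise_rms_deg = 0.2,
                                seed = 3))
  expect_equal(rmsd_precision(sim$recording), 0.2, tolerance = 0.02)
})

test_that("random loss recovers the requested probability at large n", {
  plan <- tibble::tibble(x_deg = 0, y_deg = 0, duration_ms = 1e5)
  sim <- simulate_gaze(sim_spec(plan, rate_hz = 1000, loss_prob = 0.6, seed = 4))
  expect_equal(proportion_data_loss(sim$recording), 0.6, tolerance = 0.01)
})

test_that("simulated saccades exceed 100 deg/s peak velocity from 2 deg amplitude", {
  for (amp in c(2, 5, 10)) {
    plan <- tibble::tibble(x_deg = c(0, amp), y_deg = 0,
                           duration_ms = c(200, 200))
    sim <- simulate_gaze(sim_spec(plan, rate_hz = 1000, seed = 1))
    v <- compute_velocity(sim$recording)$velocity_dps
    expect_gt(max(v, na.rm = TRUE), 100)
  }
})

test_that("with zero noise the velocity classifier reproduces the truth table", {
  plan <- random_fixation_plan(5, seed = 21)
  sim <- simulate_gaze(sim_spec(plan, rate_hz = 1000, seed = 21))
  ev <- classify_ivt(sim$recording)
  tf <- sim$truth_events[sim$truth_events$kind == "fixation", ]
  fx <- fixations(ev)
  expect_equal(nrow(fx), nrow(tf))
  # the raised-cosine profile spends up to two 1-ms samples below the
  # 30 deg/s threshold at each saccade tail, so boundaries agree to 2 samples
  expect_true(all(abs(fx$onset_ms - tf$onset_ms) <= 2))
  expect_true(all(abs(fx$offset_ms - tf$offset_ms) <= 2))
  expect_equal(fx$x, tf$x, tolerance = 1e-3)
})

test_that("overlapping loss runs are rejected", {
  plan <- tibble::tibble(x_deg = 0, y_deg = 0, duration_ms = 1000)
  runs <- tibble::tibble(start_ms = c(100, 150), duration_ms = c(100, 50))
  expect_error(simulate_gaze(sim_spec(plan, loss_runs = runs)),
               class = "gazekit_input_error")
})

test_that("the packaged presets land in their stated quality regimes", {
  clean <- simulate_gaze(sim_spec_preset("clean-1200hz", seed = 2))
  # measure precision inside the longest fixation, away from saccades
  tf <- clean$truth_events[clean$truth_events$kind == "fixation", ]
  longest <- tf[which.max(tf$duration_ms), ]
  expect_equal(rmsd_precision(clean$recording,
                              span = c(longest$onset_ms, longest$offset_ms)),
               0.12, tolerance = 0.08)
  expect_lt(proportion_data_loss(clean$recording), 0.05)
  lossy <- simulate_gaze(sim_spec_preset("noisy-lossy", seed = 2))
  expect_gt(proportion_data_loss(lossy$recording), 0.45)
  expect_lt(proportion_data_loss(lossy$recording), 0.75)
})
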