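# Shared fixtures and independent oracles. Oracles are deliberately written
# as plain loops, independent of the vectorized package implementations they
# check.

make_rec <- function(x, y = rep(0, length(x)), rate_hz = 1000, valid = NULL,
                     unit = "deg", geometry = NULL) {
  n <- length(x)
  as_gaze_recording(
    tibble::tibble(time_ms = (seq_len(n) - 1) * 1000 / rate_hz,
                   x = x, y = y,
                   valid = valid %||% rep(TRUE, n)),
    unit = unit, geometry = geometry)
}

truth_as_event_set <- function(sim) {
  df <- tibble::as_tibble(sim$truth_events)
  df$algorithm <- "truth"
  gazekit:::new_event_set(df, algorithm = "truth")
}

make_events <- function(onset, offset, x = 0, y = 0, kind = "fixation",
                        algorithm = "manual", prop_missing = 0) {
  n <- length(onset)
  df <- tibble::tibble(
    kind = rep_len(kind, n), onset_ms = onset, offset_ms = offset,
    duration_ms = offset - onset, x = rep_len(x, n), y = rep_len(y, n),
    amplitude_deg = NA_real_, peak_velocity_dps = NA_real_,
    rmsd_deg = 0, prop_missing = rep_len(prop_missing, n),
    n_samples = as.integer(round(offset - onset)),
    sample_time_ms = offset - onset,
    algorithm = rep_len(algorithm, n))
  gazekit:::new_event_set(df, algorithm = algorithm)
}

# Random simulated scanpath with parameters drawn from a seed; used by the
# property suites.
random_trace <- function(seed, rate_hz = NULL, noise = NULL, loss = NULL,
                         n_fix = NULL) {
  pars <- withr::with_seed(seed, list(
    rate = rate_hz %||% sample(c(250, 500, 1000, 1200), 1),
    nf = n_fix %||% sample(3:6, 1),
    noise = noise %||% runif(1, 0, 0.5),
    loss = loss %||% 0))
  plan <- random_fixation_plan(pars$nf, seed = seed + 1000)
  simulate_gaze(sim_spec(plan, rate_hz = pars$rate,
                         noise_rms_deg = pars$noise,
                         loss_prob = pars$loss, seed = seed))
}

# ---- I2MC brute-force oracle -------------------------------------------
# Hand-coded Lloyd two-means with deterministic half-mean seeds, mirroring
# the algorithm definition (not the package code).
oracle_lloyd <- function(xy) {
  nv <- nrow(xy)
  half <- floor(nv / 2)
  c1 <- colMeans(xy[seq_len(half), , drop = FALSE])
  c2 <- colMeans(xy[(half + 1):nv, , drop = FALSE])
  if (sum((c1 - c2)^2) < 1e-18) return(NULL)
  assign <- integer(nv)
  for (it in 1:100) {
    d1 <- (xy[, 1] - c1[1])^2 + (xy[, 2] - c1[2])^2
    d2 <- (xy[, 1] - c2[1])^2 + (xy[, 2] - c2[2])^2
    newa <- ifelse(d2 < d1, 2L, 1L)
    if (!any(newa == 1L) || !any(newa == 2L)) return(NULL)
    if (identical(newa, assign)) break
    assign <- newa
    c1 <- colMeans(xy[assign == 1L, , drop = FALSE])
    c2 <- colMeans(xy[assign == 2L, , drop = FALSE])
  }
  assign
}

oracle_downsample <- function(t, x, y, valid, k) {
  n <- length(t)
  nb <- ceiling(n / k)
  ot <- numeric(nb); ox <- numeric(nb); oy <- numeric(nb); ov <- logical(nb)
  for (b in seq_len(nb)) {
    idx <- ((b - 1) * k + 1):min(n, b * k)
    ok <- idx[valid[idx]]
    ot[b] <- t[idx[1]]
    ov[b] <- length(ok) > 0
    ox[b] <- if (length(ok) > 0) mean(x[ok]) else NA_real_
    oy[b] <- if (length(ok) > 0) mean(y[ok]) else NA_real_
  }
  list(t = ot, x = ox, y = oy, valid = ov)
}

# Full windowed two-means transition weights, brute force.
oracle_i2mc_weights <- function(rec, params = i2mc_params()) {
  t <- rec$time_ms; n <- nrow(rec)
  num <- numeric(n); den <- numeric(n)
  starts <- seq(t[1], t[n] - params$window_ms, by = params$step_ms)
  for (k in c(1L, params$downsample_factors)) {
    if (k == 1L) {
      vt <- t; vx <- rec$x; vy <- rec$y; vv <- rec$valid
    } else {
      d <- oracle_downsample(t, rec$x, rec$y, rec$valid, k)
      vt <- d$t; vx <- d$x; vy <- d$y; vv <- d$valid
    }
    for (s in starts) {
      win <- which(vt >= s - 1e-9 & vt < s + params$window_ms - 1e-9)
      if (length(win) < 2) next
      ok <- win[vv[win]]
      if (length(ok) < 4 ||
          length(ok) / length(win) < params$min_valid_prop_window) next
      n0 <- (win[1] - 1L) * k + 1L
      n1 <- min(n, win[length(win)] * k)
      den[n0:n1] <- den[n0:n1] + 1
      cl <- oracle_lloyd(cbind(vx[ok], vy[ok]))
      if (is.null(cl)) next
      sw <- which(diff(cl) != 0) + 1L
      if (length(sw) == 0) next
      for (pos in sw) {
        j <- ok[pos]
        nat <- min(n, (j - 1L) * k + 1L)
        num[nat] <- num[nat] + 1 / length(sw)
      }
    }
  }
  ifelse(den > 0, num / den, NA_real_)
}

oracle_i2mc_transition_times <- function(rec, params = i2mc_params()) {
  w <- oracle_i2mc_weights(rec, params)
  cutoff <- mean(w, na.rm = TRUE) + params$weight_cutoff_sd * sd(w, na.rm = TRUE)
  rec$time_ms[!is.na(w) & w > cutoff]
}

# Directed Hausdorff-style distance between two sets of times.
max_set_distance <- function(a, b) {
  if (length(a) == 0 && length(b) == 0) return(0)
  if (length(a) == 0 || length(b) == 0) return(Inf)
  max(max(vapply(a, function(p) min(abs(b - p)), numeric(1))),
      max(vapply(b, function(p) min(abs(a - p)), numeric(1))))
}
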