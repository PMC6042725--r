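# Kinematic preprocessing: calibration, rotation, filtering, angles,
# dives, phases, strokes, speed and lunges.

test_that("pressure calibration is the documented affine transform", {
  rec <- flat_record(10, depth = NULL,
                     pressure = c(rep(5, 5), 10, rep(5, 4)))
  out <- pressure_to_depth(rec, offset = 5, scale = 2)
  expect_equal(out$depth[6], 10)          # (10 - 5) * 2
  expect_equal(out$depth[1], 0)
  # identity calibration
  rec2 <- flat_record(10, depth = NULL, pressure = rep(3, 10))
  expect_equal(pressure_to_depth(rec2, 0, 1)$depth, rep(3, 10))
  expect_error(pressure_to_depth(rec, offset = 5, scale = -1), "positive")
  expect_error(pressure_to_depth(rec, offset = NA, scale = 1), "finite")
  expect_error(pressure_to_depth(flat_record(10), 0, 1), "no pressure")
})

test_that("whale-frame rotation is orthonormal and invertible", {
  rec <- flat_record(20)
  rec$accel <- matrix(rnorm(60, sd = 3), ncol = 3)
  # identity
  out <- rotate_to_whale_frame(rec, diag(3))
  expect_equal(out$accel, rec$accel)
  # 90 degree yaw moves the sway axis onto surge
  R <- rotation_matrix(yaw = pi / 2)
  out <- rotate_to_whale_frame(rec, R)
  expect_equal(out$accel[, 1], -rec$accel[, 2], tolerance = 1e-12)
  # norms preserved
  expect_equal(sqrt(rowSums(out$accel^2)), sqrt(rowSums(rec$accel^2)),
               tolerance = 1e-9)
  # round trip
  back <- rotate_to_whale_frame(out, t(R))
  expect_equal(back$accel, rec$accel, tolerance = 1e-12)
  expect_error(rotate_to_whale_frame(rec, matrix(1, 3, 3)), "orthonormal")
})

test_that("auto orientation recovers a known mounting within 5 degrees", {
  cfg <- scenario_config(n_whales = 1, dives_per_whale = 2, accel_rate = 8,
                         mean_depth_range = c(80, 120),
                         mount_roll = 0.25, mount_pitch = -0.2)
  tr <- draw_population(cfg, seed = 3)
  sim <- simulate_tag_record(tr, cfg, whale = 1, seed = 13)
  Rest <- estimate_tag_orientation(sim$record)
  Rm <- sim$annotations$mounting
  # Rest must undo the mounting: Rest %*% t(Rm) close to identity
  for (ax in 1:3) {
    e <- double(3); e[ax] <- 1
    recovered <- Rest %*% (t(Rm) %*% e)
    ang <- acos(min(1, sum(recovered * e)))
    expect_lt(ang, 5 * pi / 180)
  }
  # no surface data -> error
  rec_deep <- flat_record(30, depth = rep(50, 30))
  expect_error(estimate_tag_orientation(rec_deep), "no surface")
})

test_that("low/high frequency split reconstructs input and separates tones", {
  fs <- 5
  t <- seq(0, 400, by = 1 / fs)
  # constant input: low = input, high = 0
  const3 <- matrix(rep(c(1, -2, 9.8), each = length(t)), ncol = 3)
  sp <- separate_acceleration(const3, fs)
  expect_equal(sp$low, const3, tolerance = 1e-6)
  expect_lt(max(abs(sp$high)), 1e-6)
  # exact reconstruction is structural
  x <- matrix(rnorm(3 * length(t)), ncol = 3)
  sp2 <- separate_acceleration(x, fs)
  expect_lt(max(abs(sp2$low + sp2$high - x)), 1e-9)
  # a 1 Hz tone ends up almost entirely in the high component
  tone <- matrix(c(sin(2 * pi * 1 * t), rep(0, 2 * length(t))), ncol = 3)
  sp3 <- separate_acceleration(tone, fs, cutoff_hz = 0.13)
  expect_gt(var(sp3$high[, 1]) / var(tone[, 1]), 0.99)
  # two-tone separation: 0.01 Hz drift vs 0.5 Hz stroking
  slow <- sin(2 * pi * 0.01 * t); fast <- 0.5 * sin(2 * pi * 0.5 * t)
  sp4 <- separate_acceleration(cbind(slow + fast, 0, 0), fs,
                               cutoff_hz = 0.135)
  expect_lt(var(sp4$low[, 1] - slow) / var(slow), 0.05)
  expect_lt(var(sp4$high[, 1] - fast) / var(fast), 0.05)
  # attenuation at twice the cutoff is at least 20 dB
  f2 <- 0.27
  tone2 <- cbind(sin(2 * pi * f2 * t), 0, 0)
  sp5 <- separate_acceleration(tone2, fs, cutoff_hz = 0.135)
  expect_lt(10 * log10(var(sp5$low[, 1]) / var(tone2[, 1])), -20)
  expect_error(separate_acceleration(x, fs, cutoff_hz = 3), "Nyquist")
})

test_that("pitch and roll follow the gravity-vector convention", {
  g <- 9.8
  # gravity on the dorso-ventral axis: level swimming
  pr <- compute_pitch_roll(matrix(c(0, 0, g), 1))
  expect_equal(pr$pitch, 0); expect_equal(pr$roll, 0)
  # gravity entirely on the surge axis, nose down
  pr <- compute_pitch_roll(matrix(c(-g, 0, 0), 1))
  expect_equal(pr$pitch, -pi / 2)
  # 30 degree nose-up
  pr <- compute_pitch_roll(matrix(c(g * sin(pi / 6), 0, g * cos(pi / 6)), 1))
  expect_equal(pr$pitch, pi / 6, tolerance = 1e-12)
  # near-zero norm: undefined, not fabricated
  pr <- compute_pitch_roll(matrix(c(0.01, 0, 0.01), 1))
  expect_true(is.na(pr$pitch) && is.na(pr$roll))
  expect_true(all(abs(stats::na.omit(compute_pitch_roll(
    matrix(rnorm(300) * 5, ncol = 3))$pitch)) <= pi / 2))
})

test_that("dive detection finds maximal submergences deeper than 10 m", {
  t <- 0:100
  # below threshold: no dives
  d1 <- 9.9 * sin(pi * t / 100)
  expect_equal(nrow(detect_dives(t, pmax(d1, 0))), 0)
  # single V to 50 m
  d2 <- pmax(0, 50 - abs(t - 50))
  dv <- detect_dives(t, d2)
  expect_equal(nrow(dv), 1)
  expect_equal(dv$max_depth, 50)
  # two excursions split by a 0.5 m surfacing
  d3 <- c(pmax(0, 30 - abs(t[1:45] - 22)), rep(0.5, 11),
          pmax(0, 30 - abs(t[57:101] - 79)))
  dv3 <- detect_dives(t, d3)
  expect_equal(nrow(dv3), 2)
  # idempotent under added surface-only samples
  t4 <- c(t, 101:150); d4 <- c(d2, rep(0, 50))
  dv4 <- detect_dives(t4, d4)
  expect_equal(dv4$start_time, dv$start_time)
  expect_equal(dv4$max_depth, dv$max_depth)
})

test_that("dive phases split on smoothed pitch crossings", {
  t <- 0:200
  # V dive: pitch -45 then +45, bottom empty
  pitchV <- c(rep(-45, 100), rep(45, 101)) * pi / 180
  depthV <- c(seq(10, 110, length.out = 100), seq(110, 10, length.out = 101))
  ph <- segment_dive_phases(t, depthV, pitchV)
  expect_false("bottom" %in% ph$phase)
  expect_lte(ph$end_time[ph$phase == "descent"],
             ph$start_time[ph$phase == "ascent"])
  # U dive with a 100 s flat bottom
  pitchU <- c(rep(-40, 50), rep(0, 100), rep(40, 51)) * pi / 180
  depthU <- c(seq(10, 80, length.out = 50), rep(80, 100),
              seq(80, 10, length.out = 51))
  phU <- segment_dive_phases(t, depthU, pitchU)
  bott <- phU[phU$phase == "bottom", ]
  expect_equal(bott$end_time - bott$start_time, 100, tolerance = 10)
  expect_false(any(phU$flagged))
  # degenerate: pitch never crosses the thresholds
  phD <- segment_dive_phases(t, depthU, rep(30 * pi / 180, 201))
  expect_true(all(phD$flagged))
  expect_false("bottom" %in% phD$phase)
  expect_equal(phD$end_time[phD$phase == "descent"],
               t[which.max(depthU)])
})

test_that("stroke detection thresholds the high-frequency envelope", {
  fs <- 8; t <- seq(0, 200, by = 1 / fs); n <- length(t)
  zero <- matrix(0, n, 3)
  st <- detect_strokes(zero, t, threshold = 0.15)
  expect_false(any(st$stroking))
  expect_equal(nrow(st$glides), 1)
  expect_equal(st$glides$duration, max(t) - min(t))
  # continuous 0.5 Hz oscillation at amplitude 0.3 with threshold 0.2:
  # no glide anywhere
  osc <- matrix(c(0.3 * sin(2 * pi * 0.5 * t), rep(0, 2 * n)), ncol = 3)
  st2 <- detect_strokes(osc, t, threshold = 0.2)
  expect_true(all(st2$stroking))
  expect_equal(nrow(st2$glides), 0)
  # 20 s on / 20 s off bursts: glide intervals match off periods within
  # one envelope window
  burst <- as.numeric(floor(t / 20) %% 2 == 0)
  sig <- matrix(c(0.3 * sin(2 * pi * 0.5 * t) * burst, rep(0, 2 * n)),
                ncol = 3)
  st3 <- detect_strokes(sig, t, threshold = 0.15)
  offs <- seq(20, 180, by = 40)
  expect_equal(nrow(st3$glides), length(offs))
  expect_true(all(abs(st3$glides$start_time - offs) <= 2))
  expect_true(all(abs(st3$glides$end_time - (offs + 20)) <= 2))
})

test_that("impeller calibration recovers slope and intercept", {
  # identity case: rotation equals depth-derived speed exactly, with the
  # descent rate varying so the regression has spread
  set.seed(6)
  t <- 0:499
  pitch <- rep(-pi / 2, 500)           # straight down
  v_true <- rep(seq(0.5, 2.5, length.out = 100), each = 5)
  depth <- cumsum(v_true)
  rot <- v_true + rnorm(500, 0, 1e-4)
  cal <- calibrate_impeller_speed(t, depth, pitch, rot)
  expect_equal(cal$slope, 1, tolerance = 0.01)
  expect_equal(cal$intercept, 0, tolerance = 0.02)
  expect_equal(cal$speed, pmax(0, cal$slope * rot + cal$intercept))
  # zero rotation: no usable spread
  expect_error(
    calibrate_impeller_speed(t, depth, pitch, rep(0, 500)),
    "no spread")
  # too few steep intervals: error names the count
  expect_error(
    calibrate_impeller_speed(t, depth, rep(0.1, 500), rot),
    "0 qualifying")
  # generator truth: recovered within 2 percent
  cfg <- scenario_config(n_whales = 1, dives_per_whale = 3, accel_rate = 8,
                         mean_depth_range = c(120, 160))
  tr <- draw_population(cfg, seed = 5)
  sim <- simulate_tag_record(tr, cfg, whale = 1, seed = 11)
  kin <- preprocess_tag(sim$record, orientation = "auto",
                        lunge_method = "none")
  expect_equal(kin$settings$calibration$slope, cfg$impeller_slope,
               tolerance = 0.02)
})

test_that("depth-rate speed uses |dz/dt| / |sin pitch| above the pitch floor", {
  t <- 0:10
  depth <- t * 1.0                      # 1 m/s down
  sp <- speed_from_depth_rate(t, depth, rep(-pi / 2, 11))
  expect_equal(sp[5], 1.0, tolerance = 1e-9)
  sp2 <- speed_from_depth_rate(t, depth, rep(-30.5 * pi / 180, 11))
  expect_equal(sp2[5], 1 / sin(30.5 * pi / 180), tolerance = 1e-9)
  # too shallow: undefined
  sp3 <- speed_from_depth_rate(t, depth, rep(5 * pi / 180, 11))
  expect_true(all(is.na(sp3)))
  sp4 <- speed_from_depth_rate(t, depth, rep(30 * pi / 180, 11))
  expect_true(all(is.na(sp4)))          # floor is strict
})

test_that("lunge detection flags speed peaks with rapid deceleration", {
  t <- 0:599
  base <- rep(1.5, 600)
  expect_length(detect_lunges(t, speed = base, method = "speed-peak"), 0)
  # one spike to mean + ~3 sd with a sharp drop
  s1 <- base + 0.05 * sin(t / 20)
  s1[300:303] <- c(2.5, 3.2, 2.0, 1.2)
  l1 <- detect_lunges(t, speed = s1, method = "speed-peak")
  expect_length(l1, 1)
  expect_equal(l1, 301, tolerance = 2)
  # two spikes 100 s apart
  s2 <- s1; s2[400:403] <- c(2.5, 3.2, 2.0, 1.2)
  l2 <- detect_lunges(t, speed = s2, method = "speed-peak")
  expect_length(l2, 2)
  expect_equal(diff(l2), 100, tolerance = 3)
  # jerk method sees an acceleration transient
  acc <- matrix(0, 600, 3)
  acc[300, 1] <- 5
  l3 <- detect_lunges(t, accel = acc, method = "jerk-peak",
                      jerk_threshold = 2)
  expect_length(l3, 1)
  expect_error(detect_lunges(t, speed = base, method = "nonsense"))
})
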