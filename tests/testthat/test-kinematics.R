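test_that("angle conventions: collinear is zero, quarter turns are signed 90", {
  t3 <- data.frame(frame = 0:2, time_s = (0:2) / 250,
                   snout_x = 2, snout_y = 0, vent_x = 1, vent_y = 0,
                   tailtip_x = 0, tailtip_y = 0)
  a <- compute_angles(t3)
  expect_equal(a$tail_angle_deg, rep(0, 3))
  expect_equal(a$body_angle_deg, rep(0, 3))
  # tail tip raised to +y: rotating the tail vector from caudal (-x) to +y
  # is a -90 degree (clockwise) rotation under the CCW-positive convention
  t3$tailtip_x <- 1; t3$tailtip_y <- 1
  expect_equal(compute_angles(t3)$tail_angle_deg, rep(-90, 3))
  t3$tailtip_y <- -1
  expect_equal(compute_angles(t3)$tail_angle_deg, rep(90, 3))
  # coincident landmarks are an error naming the frame
  t3$tailtip_x <- 1; t3$tailtip_y <- 0
  expect_error(compute_angles(t3), "frame")
})

test_that("angles are invariant to rigid transforms of the camera frame", {
  set.seed(14)
  s <- synth_tracks("inertial", n_swings = 3, noise_px = 0, seed = 1)
  a0 <- compute_angles(s$tracks)
  for (rep in 1:5) {
    th <- runif(1, -pi, pi)
    sc <- runif(1, 0.2, 5)
    off <- rnorm(2, 0, 100)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    tr <- s$tracks
    for (lm in c("snout", "vent", "tailtip")) {
      xy <- sc * t(R %*% t(as.matrix(tr[, paste0(lm, c("_x", "_y"))])))
      tr[[paste0(lm, "_x")]] <- xy[, 1] + off[1]
      tr[[paste0(lm, "_y")]] <- xy[, 2] + off[2]
    }
    a1 <- compute_angles(tr)
    expect_close(a1$tail_angle_deg, a0$tail_angle_deg, 1e-8)
    d <- (a1$body_angle_deg - a0$body_angle_deg) - rad2deg_pub(th)
    expect_close(d - round(d / 360) * 360, 0, 1e-8)
  }
})

test_that("track CSV round-trips losslessly and readers validate structure", {
  s <- synth_tracks("mixed", n_swings = 4, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_tracks(s$tracks, path)
  back <- read_tracks(path)
  expect_equal(as.data.frame(back)[names(back)],
               as.data.frame(s$tracks)[names(back)], tolerance = 1e-12)
  # duplicated frame -> error naming the frame
  dup <- s$tracks; dup$frame[5] <- dup$frame[4]
  write.csv(as.data.frame(dup), path, row.names = FALSE)
  expect_error(read_tracks(path), as.character(dup$frame[4]))
  # missing columns
  bad <- s$tracks; bad$vent_x <- NULL
  write.csv(as.data.frame(bad), path, row.names = FALSE)
  expect_error(read_tracks(path), "vent_x")
})

test_that("DeepLabCut-style three-row headers are flattened on load", {
  s <- synth_tracks("inertial", n_swings = 2, seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  n <- nrow(s$tracks)
  lines <- c(
    paste(c("scorer", rep("model", 9)), collapse = ","),
    paste(c("bodyparts", rep(c("snout", "vent", "tail_tip"), each = 3)),
          collapse = ","),
    paste(c("coords", rep(c("x", "y", "likelihood"), 3)), collapse = ","))
  body <- apply(cbind(s$tracks$frame,
                      s$tracks$snout_x, s$tracks$snout_y, 0.99,
                      s$tracks$vent_x, s$tracks$vent_y, 0.99,
                      s$tracks$tailtip_x, s$tracks$tailtip_y, 0.99),
                1, paste, collapse = ",")
  writeLines(c(lines, body), path)
  d <- read_tracks(path, frame_rate = 250)
  expect_equal(d$snout_x, s$tracks$snout_x, tolerance = 1e-9)
  expect_equal(d$tailtip_y, s$tracks$tailtip_y, tolerance = 1e-9)
  expect_equal(d$confidence_vent, rep(0.99, n))
})

test_that("pixel calibration scales coordinates by mean body length", {
  s <- synth_tracks("inertial", n_swings = 2, noise_px = 0, seed = 6)
  path <- withr::local_tempfile(fileext = ".csv")
  write_tracks(s$tracks, path)
  d <- read_tracks(path, body_length = 0.051)
  bl <- mean(sqrt((d$snout_x - d$vent_x)^2 + (d$snout_y - d$vent_y)^2))
  expect_equal(bl, 0.051, tolerance = 1e-9)
})

test_that("pure inertial coupling shows zero lag; programmed aero lags are recovered", {
  s <- synth_tracks("inertial", noise_px = 0, seed = 2)
  lag <- cross_correlate(compute_angles(s$tracks))
  expect_lt(abs(lag$lag_s), 0.5 / s$truth$fps)       # within half a frame
  expect_lt(lag$peak_correlation, -0.99)             # anti-correlated
  expect_true(all(abs(lag$curve$correlation) <= 1 + 1e-12))
  s2 <- synth_tracks("aero", lag_s = 0.024, noise_px = 0.5, seed = 8)
  lag2 <- cross_correlate(compute_angles(s2$tracks))
  expect_lt(abs(lag2$lag_s - 0.024), 1 / s2$truth$fps)
})

test_that("lag recovery over 50 seeds of noisy aero tracks errs by at most one frame (median)", {
  set.seed(100)
  errs <- vapply(1:50, function(s) {
    true_lag <- runif(1, 0.008, 0.040)
    sim <- synth_tracks("aero", lag_s = true_lag, noise_px = 1, fps = 250,
                        seed = s)
    lag <- cross_correlate(compute_angles(sim$tracks), max_lag = 0.1)
    abs(lag$lag_s - true_lag)
  }, numeric(1))
  expect_lte(median(errs), 0.004)
})

test_that("mixed-mode lag interpolates between the pure pathways", {
  lags <- vapply(c(0.9, 0.5, 0.1), function(w) {
    s <- synth_tracks("mixed", mix_weight = w, lag_s = 0.032, noise_px = 0,
                      seed = 20)
    cross_correlate(compute_angles(s$tracks), max_lag = 0.1)$lag_s
  }, numeric(1))
  expect_true(all(lags >= -0.002 & lags <= 0.0321))
  expect_true(all(diff(lags) > 0))    # less inertial weight -> longer lag
})

test_that("white-noise angle pairs show no significant lag or correlation", {
  set.seed(33)
  n <- 500
  angles <- data.frame(time_s = (0:(n - 1)) / 250,
                       body_angle_deg = rnorm(n),
                       tail_angle_deg = rnorm(n))
  class(angles) <- c("angle_series", "data.frame")
  lag <- cross_correlate(angles, max_lag = 0.1)
  # permutation null for the peak correlation magnitude
  null_peaks <- vapply(1:100, function(i) {
    shuffled <- angles
    shuffled$body_angle_deg <- sample(angles$body_angle_deg)
    max(abs(cross_correlate(shuffled, max_lag = 0.1)$curve$correlation))
  }, numeric(1))
  expect_lt(abs(lag$peak_correlation), quantile(null_peaks, 0.99))
})

test_that("insufficient series are rejected", {
  short <- data.frame(time_s = seq(0, 0.1, by = 0.004),
                      body_angle_deg = 1:26, tail_angle_deg = 26:1)
  expect_error(cross_correlate(short, max_lag = 0.2), "insufficient")
})

test_that("swing segmentation counts single sweeps, sine periods and synthetic swings", {
  tt <- seq(0, 1, by = 1 / 250)
  mono <- data.frame(time_s = tt,
                     tail_angle_deg = 90 * pmin(1, tt / 0.5),
                     body_angle_deg = 0)
  expect_equal(nrow(segment_swings(mono)), 1)
  sine <- data.frame(time_s = seq(0, 3, by = 1 / 250))
  sine$tail_angle_deg <- 60 * sin(2 * pi * sine$time_s)    # 3 periods
  sine$body_angle_deg <- -0.15 * sine$tail_angle_deg
  # 6 interior extrema -> 5 full half-period sweeps plus the two boundary
  # quarter sweeps, all above the amplitude threshold
  expect_equal(nrow(segment_swings(sine)), 7)
  s <- synth_tracks("inertial", n_swings = 7, noise_px = 0.3, seed = 4)
  swings <- segment_swings(compute_angles(s$tracks))
  expect_equal(nrow(swings), s$truth$swing_count)
})

test_that("swing regression recovers exact linear coupling with R^2 = 1", {
  s <- synth_tracks("inertial", n_swings = 7, noise_px = 0, seed = 10)
  swings <- segment_swings(compute_angles(s$tracks))
  reg <- swing_regression(swings)
  expect_equal(reg$n, nrow(swings))
  expect_equal(reg$r_squared, 1, tolerance = 1e-9)
  expect_equal(reg$slope, -s$truth$coupling, tolerance = 1e-6)
  expect_error(swing_regression(swings[1:2, ]), "3 swings")
  degen <- swings; degen$dtail_deg <- 120
  expect_error(swing_regression(degen), "degenerate")
})

test_that("the full pipeline on disturbed mixed tracks lands in the animal regime", {
  # generator settings emulating the wind-tunnel observations: dominant but
  # incomplete inertial coupling, an aerodynamic pathway, pixel noise, and
  # smooth extraneous body rotations (feet/posture aerodynamics) that keep
  # the swing regression well below a perfect fit
  r2 <- vapply(1:20, function(s) {
    sim <- synth_tracks("mixed", n_swings = 7, mix_weight = 0.6,
                        lag_s = 0.02, noise_px = 1,
                        body_disturbance_deg = 14, seed = s)
    swings <- segment_swings(compute_angles(sim$tracks))
    if (nrow(swings) < 3) return(NA_real_)
    swing_regression(swings)$r_squared
  }, numeric(1))
  expect_lt(abs(median(r2, na.rm = TRUE) - 0.57), 0.15)
})

test_that("synthetic tracks are deterministic under a fixed seed", {
  a <- synth_tracks("mixed", seed = 77)
  b <- synth_tracks("mixed", seed = 77)
  expect_identical(a, b)
})
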