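test_that("VDS is the signed perpendicular point-line distance", {
  n <- 5
  kp <- c("withers", "eye")
  mk <- function(xw, yw) manual_traj(
    matrix(c(rep(xw, n), rep(0, n)), n, 2, dimnames = list(NULL, kp)),
    matrix(c(rep(yw, n), rep(0, n)), n, 2, dimnames = list(NULL, kp)))
  # horizontal groundline at y = 500, keypoint at y = 300 -> 200 px
  gl <- fixed_groundline(0, 500, n)
  expect_equal(compute_vds(mk(100, 300), gl, "withers")$values, rep(200, n))
  # a point on the line -> 0
  expect_equal(compute_vds(mk(100, 500), gl, "withers")$values, rep(0, n))
  # 45-degree line through the origin, point (100, 0) -> 100 / sqrt(2)
  gl45 <- fixed_groundline(45, 0, n)
  expect_equal(compute_vds(mk(100, 0), gl45, "withers")$values,
               rep(100 / sqrt(2), n), tolerance = 1e-9)
  expect_error(compute_vds(mk(0, 0), gl, "croup"), "croup")
})

test_that("withers-height calibration is exact, zoom-invariant and guarded", {
  n <- 100
  kp <- c("withers", "eye")
  x <- matrix(800, n, 2, dimnames = list(NULL, kp))
  y <- matrix(c(rep(200, n), rep(150, n)), n, 2, dimnames = list(NULL, kp))
  traj <- manual_traj(x, y)
  gl <- fixed_groundline(0, 1000, n)  # withers distance 800 px
  v <- compute_vds(traj, gl, "eye")
  cal <- calibrate_vds(v, traj, gl, withers_height = 160)
  expect_equal(cal$scale, 2)                       # 1600 mm / 800 px
  expect_equal(cal$values, rep(850 * 2, n))        # 100 px -> 200 mm analogue
  # doubling every pixel coordinate (zoom) leaves calibrated VDS unchanged
  traj2 <- manual_traj(2 * x, 2 * y)
  gl2 <- fixed_groundline(0, 2000, n)
  cal2 <- calibrate_vds(compute_vds(traj2, gl2, "eye"), traj2, gl2, 160)
  expect_equal(cal2$values, cal$values, tolerance = 1e-9)
  # insufficient withers coverage is an error naming the fraction
  vis <- matrix(TRUE, n, 2, dimnames = list(NULL, kp))
  vis[1:60, "withers"] <- FALSE
  traj3 <- manual_traj(x, y, visible = vis)
  expect_error(calibrate_vds(compute_vds(traj3, gl, "eye"), traj3, gl, 160),
               "40.0%")
})

test_that("calibrated filtered VDS recovers the simulated trunk amplitude", {
  p <- test_params(duration = 20, trunk_amp = 30)
  w <- simulate_gait(p)
  traj <- project_keypoints(w, side_camera())
  an <- analyze_trajectories(traj, p$withers_height, keypoints = "withers")
  v <- an$keypoints$withers$vds
  core <- v$values[!v$warmup]
  amp <- (max(core) - min(core)) / 2
  expect_equal(amp, 30, tolerance = 0.02 * 30)
})

test_that("stride frequency estimation finds f, rejects noise, resists the 2f line", {
  fps <- 30
  t <- seq(0, 20, by = 1 / fps)
  expect_equal(estimate_stride_frequency(sin(2 * pi * 1.25 * t), fps),
               1.25, tolerance = 0.05)
  p <- test_params(duration = 20, noise_sigma = 1, seed = 2)
  traj <- simulate_recording(p, side_camera(), seed = 2)
  hoof <- traj$y[, "hoof_lf"]
  expect_equal(estimate_stride_frequency(hoof, fps), 1.25, tolerance = 0.05)
  set.seed(5)
  expect_error(estimate_stride_frequency(stats::rnorm(600), fps), "peak")
  # trunk-like signal: dominant second harmonic must not be mistaken for f
  trunk <- 30 * cos(2 * pi * 2.5 * t) + 2 * sin(2 * pi * 1.25 * t)
  expect_equal(estimate_stride_frequency(trunk, fps), 1.25, tolerance = 0.05)
})

test_that("the high-pass filter has the textbook Butterworth response", {
  fps <- 30
  f_est <- 1.25
  cutoff <- 0.95 * f_est
  t <- seq(0, 60, by = 1 / fps)
  mk_vds <- function(vals) structure(
    list(values = vals, values_px = vals, visible = rep(TRUE, length(vals)),
         fps = fps, keypoint = "withers", scale = 1, f_est = NA_real_,
         cutoff = NA_real_, filtered = FALSE,
         warmup = rep(FALSE, length(vals)), unit = "mm"), class = "vds")
  # DC is removed completely
  hp <- highpass_vds(mk_vds(rep(7, length(t))), f_est)
  expect_lt(max(abs(hp$values)), 1e-6)
  # two-pass amplitude gain at the cutoff is 1/2
  hp_c <- highpass_vds(mk_vds(sin(2 * pi * cutoff * t)), f_est)
  mid <- 400:1400
  gain_c <- (max(hp_c$values[mid]) - min(hp_c$values[mid])) / 2
  expect_equal(gain_c, 0.5, tolerance = 0.01)
  # a 1 Hz camera-bounce component is attenuated below 45% amplitude
  hp_b <- highpass_vds(mk_vds(sin(2 * pi * 1 * t)), f_est)
  expect_lt((max(hp_b$values[mid]) - min(hp_b$values[mid])) / 2, 0.45)
  # while the 2f trunk component passes essentially untouched
  g <- strideline:::butter_twopass_gain(c(1, 2 * f_est), cutoff, fps)
  expect_lt(sqrt(g[1])^2, 0.45)      # two-pass at 1 Hz
  expect_gt(sqrt(g[2]), 0.99)        # single-pass at 2f
  expect_gt(g[2], 0.98)              # two-pass at 2f
  # cutoff at or above Nyquist is refused
  expect_error(highpass_vds(mk_vds(t), 16), "Nyquist")
})

test_that("filtering is linear and leaves a near-zero mean over whole strides", {
  fps <- 30
  t <- seq(0, 30, by = 1 / fps)
  x1 <- sin(2 * pi * 2.5 * t)
  x2 <- cos(2 * pi * 0.7 * t) + 0.3 * t / max(t)
  hp <- function(x) strideline:::butter_highpass(x, fps, 1.1875)
  expect_equal(hp(2 * x1 + 3 * x2), 2 * hp(x1) + 3 * hp(x2),
               tolerance = 1e-9)
  # round-trip mean: filtered trot VDS averages to ~0 over integer strides
  p <- test_params(duration = 20)
  traj <- project_keypoints(simulate_gait(p), side_camera())
  an <- analyze_trajectories(traj, p$withers_height, keypoints = "withers")
  v <- an$keypoints$withers$vds
  st <- an$keypoints$withers$strides
  st <- st[st$valid, ]
  core <- v$values[st$start[1]:(st$end[nrow(st)] - 1)]
  expect_lt(abs(mean(core)), 0.01 * (max(core) - min(core)))
})

test_that("a short visibility gap barely disturbs neighbouring strides", {
  p <- test_params(duration = 20, trunk_amp = 30, asym_amp = 2.5)
  w <- simulate_gait(p)
  traj <- project_keypoints(w, side_camera())
  an0 <- analyze_trajectories(traj, p$withers_height, keypoints = "withers")
  st0 <- an0$keypoints$withers$strides
  mid_stride <- st0[st0$valid, ][5, ]
  # hide 3 frames of the withers inside stride 5
  traj2 <- traj
  gap <- mid_stride$start + 2:4
  traj2$visible[gap, "withers"] <- FALSE
  an1 <- analyze_trajectories(traj2, p$withers_height, keypoints = "withers")
  st1 <- an1$keypoints$withers$strides
  # the gappy stride is excluded, not imputed
  hit <- st1$start == mid_stride$start
  expect_true(any(hit))
  expect_false(st1$valid[hit])
  expect_equal(st1$reason[hit], "occluded")
  # neighbouring strides' Maxdiff moves by < 0.2 mm
  both <- merge(st0[st0$valid, c("start", "maxdiff")],
                st1[st1$valid, c("start", "maxdiff")], by = "start")
  neigh <- both[abs(both$start - mid_stride$start) <= 2 * mid_stride$dur_frames &
                both$start != mid_stride$start, ]
  expect_gt(nrow(neigh), 1)
  expect_lt(max(abs(neigh$maxdiff.x - neigh$maxdiff.y)), 0.2)
})
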