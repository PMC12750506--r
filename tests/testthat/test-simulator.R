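test_that("trunk keypoints follow the closed-form two-harmonic trajectory", {
  p <- test_params(duration = 4, asym_amp = 2.5, asym_phase = 0.7)
  w <- simulate_gait(p)
  t <- w$time
  f <- p$stride_frequency
  for (kp in c("eye", "withers", "croup")) {
    z0 <- w$xyz[1, kp, "z"] + p$trunk_amp[kp] * cos(0) -
      p$asym_amp[kp] * sin(p$asym_phase)
    expected <- z0 - p$trunk_amp[kp] * cos(4 * pi * f * t) +
      p$asym_amp[kp] * sin(2 * pi * f * t + p$asym_phase)
    expect_equal(w$xyz[, kp, "z"], expected, tolerance = 1e-12)
  }
})

test_that("a symmetric trot has equal stride maxima and minima; asymmetry shows as 2a", {
  # pure second harmonic: both per-stride maxima (and minima) coincide
  sym <- grid_symmetry(A = 30, a = 0, f = 1.25)
  expect_equal(sym$maxdiff, 0, tolerance = 1e-9)
  expect_equal(sym$mindiff, 0, tolerance = 1e-9)
  # stride-frequency component of amplitude a: Maxdiff ~ 2a at zero phase
  asym <- grid_symmetry(A = 30, a = 2.5, f = 1.25, psi = 0)
  expect_equal(asym$maxdiff, 5.0, tolerance = 0.01)
  expect_equal(asym$mindiff, 0.0, tolerance = 0.01)
  # the package oracle agrees with the independent grid search
  p <- test_params(trunk_amp = 30, asym_amp = 2.5)
  orc <- oracle_symmetry(p, "withers")
  expect_equal(orc$maxdiff, asym$maxdiff, tolerance = 1e-3)
  expect_equal(orc$mindiff, asym$mindiff, tolerance = 1e-3)
  # quarter-phase asymmetry moves the effect onto the minima
  orc2 <- oracle_symmetry(gait_params(asym_amp = 2.5, asym_phase = pi / 2),
                          "withers")
  expect_equal(orc2$mindiff, 5.0, tolerance = 0.01)
  expect_lt(abs(orc2$maxdiff), 0.01)
})

test_that("stance flags realise the duty factor up to frame quantization", {
  p <- test_params(duration = 16, duty_factor = 0.45)
  w <- simulate_gait(p)
  for (leg in c("lf", "rf", "lh", "rh")) {
    # one frame of quantization per 24-frame stride period
    expect_lt(abs(mean(w$stance[, leg]) - 0.45), 1 / 24)
    # hooves exactly on the ground during stance
    expect_equal(max(abs(w$xyz[w$stance[, leg], paste0("hoof_", leg), "z"])), 0)
  }
})

test_that("pinhole projection matches the similar-triangles oracle", {
  cam <- camera_model("test", distance_from_midline = 300, view_angle = 90,
                      height = 100, focal_length = 600,
                      image_size = c(1920, 1080))
  p <- test_params(duration = 0.2)
  w <- simulate_gait(p)
  # plant two probe points: one on the optical axis, one on the ground
  w$xyz[, "eye", ] <- matrix(rep(c(0, 0, 1000), each = nrow(w$xyz)), ncol = 3)
  w$xyz[, "back", ] <- 0
  traj <- project_keypoints(w, cam)
  expect_equal(unname(traj$x[1, "eye"]), 960, tolerance = 1e-9)
  expect_equal(unname(traj$y[1, "eye"]), 540, tolerance = 1e-9)
  # ground point straight across: f * h / d = 600 * 1000 / 3000 = 200 px down
  expect_equal(unname(traj$y[1, "back"]) - 540, 200, tolerance = 1e-9)
  expect_equal(unname(traj$x[1, "back"]), 960, tolerance = 1e-9)
})

test_that("static cameras give constant pixels, handheld cameras move", {
  p <- test_params(duration = 2)
  w <- simulate_gait(p)
  w$xyz[, "back", ] <- matrix(rep(c(100, 0, 400), each = nrow(w$xyz)), ncol = 3)
  static <- project_keypoints(w, side_camera())
  expect_equal(diff(range(static$x[, "back"])), 0)
  expect_equal(diff(range(static$y[, "back"])), 0)
  glt <- true_groundline(w, side_camera())
  expect_equal(diff(range(glt$angle)), 0)
  expect_equal(diff(range(glt$offset)), 0)
  hh <- default_cameras()[["cam7"]]
  moving <- project_keypoints(w, hh)
  expect_gt(diff(range(moving$y[, "back"])), 1)
  glh <- true_groundline(w, hh)
  expect_gt(diff(range(glh$offset)), 0)
})

test_that("stance hooves project exactly onto the true groundline", {
  p <- test_params(duration = 10)
  w <- simulate_gait(p)
  for (cam in default_cameras()[c("cam3", "cam1", "cam6")]) {
    traj <- project_keypoints(w, cam)
    glt <- true_groundline(w, cam)
    ln <- strideline:::gl_line(glt)
    for (leg in c("lf", "rh")) {
      st <- w$stance[, leg]
      h <- paste0("hoof_", leg)
      res <- (ln$b[st] * traj$x[st, h] - traj$y[st, h] + ln$c[st]) /
        sqrt(1 + ln$b[st]^2)
      expect_lt(max(abs(res)), 1e-6)
    }
  }
})

test_that("corruption is an identity at zero settings and binomial in occlusion", {
  p <- test_params(duration = 5)
  traj <- project_keypoints(simulate_gait(p), side_camera())
  expect_identical(corrupt_trajectories(traj, 0, 0, seed = 3), traj)
  # binomial occlusion count on ~1e5 keypoint-frames
  nkf <- 6250L * 16L
  big <- manual_traj(
    x = matrix(stats::runif(nkf, 0, 1900), 6250, 16,
               dimnames = list(NULL, strideline:::all_keypoints())),
    y = matrix(stats::runif(nkf, 0, 1000), 6250, 16,
               dimnames = list(NULL, strideline:::all_keypoints())))
  cor <- corrupt_trajectories(big, 0, 0.001, seed = 99)
  hidden <- sum(!cor$visible)
  expect_lt(abs(hidden - nkf * 0.001), 3 * sqrt(nkf * 0.001 * 0.999))
})

test_that("simulation and corruption are bit-identical under a fixed seed", {
  p <- test_params(duration = 3, noise_sigma = 1.5, occlusion_rate = 0.01)
  cam <- default_cameras()[["cam7"]]
  t1 <- simulate_recording(p, cam, seed = 42)
  t2 <- simulate_recording(p, cam, seed = 42)
  expect_identical(t1, t2)
  t3 <- simulate_recording(p, cam, seed = 43)
  expect_false(identical(t1$x, t3$x))
})

test_that("invalid gait parameters are rejected with the field named", {
  expect_error(gait_params(duty_factor = 1.2), "duty_factor")
  expect_error(gait_params(stride_frequency = 0), "stride_frequency")
  expect_error(gait_params(trunk_amp = -1), "trunk_amp")
  expect_error(gait_params(noise_sigma = NaN), "noise_sigma")
  expect_error(camera_model("x", view_angle = 0), "view_angle")
  expect_error(camera_model("x", distance_from_midline = -5),
               "distance_from_midline")
})
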