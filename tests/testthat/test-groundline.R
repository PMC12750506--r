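test_that("stance detection recovers the duty factor and overlaps truth", {
  p <- test_params(duration = 20)
  w <- simulate_gait(p)
  traj <- project_keypoints(w, side_camera())
  # the pipeline's two-pass scheme: coarse detection, then detection
  # relative to the estimated groundline
  refine <- function(tr) {
    coarse <- detect_stance(tr)
    detect_stance(tr, groundline = estimate_groundline(tr, coarse))
  }
  ev <- refine(traj)
  n <- nrow(traj$x)
  for (leg in c("lf", "rf", "lh", "rh")) {
    flags <- rep(FALSE, n)
    e <- ev[ev$leg == leg, ]
    for (i in seq_len(nrow(e))) flags[e$start[i]:e$end[i]] <- TRUE
    expect_equal(mean(flags), p$duty_factor, tolerance = 0.03)
  }
  # with 1 px keypoint noise the detected intervals still overlap the
  # generator's stance flags with Jaccard >= 0.9
  noisy <- corrupt_trajectories(traj, 1, 0, seed = 7)
  evn <- refine(noisy)
  for (leg in c("lf", "rh")) {
    flags <- rep(FALSE, n)
    e <- evn[evn$leg == leg, ]
    for (i in seq_len(nrow(e))) flags[e$start[i]:e$end[i]] <- TRUE
    truth <- w$stance[, leg]
    jac <- sum(flags & truth) / sum(flags | truth)
    expect_gte(jac, 0.9)
  }
})

test_that("a hoof that never stops moving yields no stance events", {
  n <- 300
  kp <- strideline:::all_keypoints()
  x <- matrix(500, n, length(kp), dimnames = list(NULL, kp))
  y <- matrix(500, n, length(kp), dimnames = list(NULL, kp))
  t <- (seq_len(n) - 1) / 30
  for (h in strideline:::hoof_keypoints()) y[, h] <- 500 + 100 * sin(2 * pi * 1.5 * t)
  traj <- manual_traj(x, y)
  ev <- detect_stance(traj)
  expect_equal(nrow(ev), 0L)
})

test_that("collinear stance points give the exact line", {
  n <- 61
  kp <- strideline:::all_keypoints()
  x <- matrix(960, n, length(kp), dimnames = list(NULL, kp))
  y <- matrix(200, n, length(kp), dimnames = list(NULL, kp))
  x[, "hoof_lf"] <- seq(300, 1500, length.out = n)
  y[, "hoof_lf"] <- 500
  traj <- manual_traj(x, y)
  st <- data.frame(leg = "lf", start = 1L, end = n,
                   x = mean(x[, "hoof_lf"]), y = 500)
  gl <- estimate_groundline(traj, st)
  expect_equal(gl$angle, rep(0, n), tolerance = 1e-8)
  expect_equal(gl$offset, rep(500, n), tolerance = 1e-6)
  # sloped line y = 0.01 x + 300 -> angle atan(0.01) = 0.573 deg
  y[, "hoof_lf"] <- 0.01 * x[, "hoof_lf"] + 300
  traj2 <- manual_traj(x, y)
  gl2 <- estimate_groundline(traj2, st)
  expect_equal(gl2$angle[30], atan(0.01) * 180 / pi, tolerance = 1e-6)
})

test_that("the robust line fit matches exhaustive two-point L1 minimisation", {
  set.seed(31)
  for (case in 1:8) {
    n <- sample(4:10, 1)
    x <- stats::runif(n, 0, 1000)
    y <- 0.05 * x + 300 + stats::rnorm(n, sd = 3)
    y[sample(n, 1)] <- y[sample(n, 1)] + 40  # gross outlier
    fit <- strideline:::l1_line_fit(x, y)
    oracle <- exhaustive_l1_fit(x, y)
    ang <- atan(fit["b"]) * 180 / pi
    ang_o <- atan(oracle["b"]) * 180 / pi
    expect_lt(abs(ang - ang_o), 0.01)
  }
})

test_that("groundline angle error grows monotonically with keypoint noise", {
  p <- test_params(duration = 10)
  w <- simulate_gait(p)
  traj0 <- project_keypoints(w, side_camera())
  glt <- true_groundline(w, side_camera())
  med_err <- vapply(c(0, 1, 2, 4), function(sg) {
    traj <- corrupt_trajectories(traj0, sg, 0, seed = 11)
    gl <- estimate_groundline(traj, detect_stance(traj))
    stats::median(abs(angle_error(gl, glt)$per_frame))
  }, numeric(1))
  expect_true(all(diff(med_err) >= -1e-9))
})

test_that("rectification is a rigid transform that levels the groundline", {
  p <- test_params(duration = 10)
  w <- simulate_gait(p)
  cam <- default_cameras()[["cam1"]]  # oblique: slanted groundline
  traj <- project_keypoints(w, cam)
  gl <- true_groundline(w, cam)
  rect <- rectify(traj, gl, mode = "per_frame")
  # stance hoof y constant across frames after per-frame rectification
  st <- w$stance[, "lf"]
  expect_lt(diff(range(rect$y[st, "hoof_lf"])), 1e-3)
  # isometry: inter-point distances preserved
  d0 <- sqrt((traj$x[, "eye"] - traj$x[, "croup"])^2 +
             (traj$y[, "eye"] - traj$y[, "croup"])^2)
  d1 <- sqrt((rect$x[, "eye"] - rect$x[, "croup"])^2 +
             (rect$y[, "eye"] - rect$y[, "croup"])^2)
  expect_equal(d1, d0, tolerance = 1e-9)
  # an already horizontal groundline leaves coordinates untouched
  flat <- fixed_groundline(0, 700, nrow(traj$x))
  same <- rectify(traj, flat, mode = "central_frame")
  expect_equal(same$x, traj$x, tolerance = 1e-12)
  expect_equal(same$y, traj$y, tolerance = 1e-12)
  # central-frame mode refuses an invalid central frame
  bad <- gl
  bad$valid[(bad$n + 1L) %/% 2L] <- FALSE
  expect_error(rectify(traj, bad, mode = "central_frame"), "central frame")
})

test_that("angle error is signed per frame with mean/MAE summaries", {
  a <- fixed_groundline(0.573, 100, 50)
  b <- fixed_groundline(0, 100, 50)
  ae <- angle_error(a, b)
  expect_equal(ae$per_frame, rep(0.573, 50))
  expect_equal(ae$mean_signed, 0.573)
  expect_equal(ae$mae, 0.573)
  self <- angle_error(a, a)
  expect_equal(self$mae, 0)
  mixed <- angle_error(new_groundline(c(1, -1), c(0, 0)),
                       new_groundline(c(0, 0), c(0, 0)))
  expect_equal(mixed$mean_signed, 0)
  expect_equal(mixed$mae, 1)
  expect_error(angle_error(a, fixed_groundline(0, 0, 10)), "mismatch")
})

test_that("dynamic groundline matches the true line on clean side views", {
  p <- test_params(duration = 20)
  w <- simulate_gait(p)
  traj <- project_keypoints(w, side_camera())
  gl <- estimate_groundline(traj, detect_stance(traj))
  glt <- true_groundline(w, side_camera())
  expect_lt(angle_error(gl, glt)$mae, 0.05)
})
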