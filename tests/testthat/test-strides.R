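analyze_clean <- function(duration = 20, asym_amp = 0, ...) {
  p <- test_params(duration = duration, asym_amp = asym_amp, ...)
  traj <- project_keypoints(simulate_gait(p), side_camera())
  list(p = p, traj = traj,
       an = analyze_trajectories(traj, p$withers_height, keypoints = "withers"))
}

test_that("stride segmentation yields the expected count with tidy accounting", {
  res <- analyze_clean(duration = 20)
  st <- res$an$keypoints$withers$strides
  # 20 s at 1.25 Hz: 24 onset-to-onset strides; edge and warm-up handling
  # leaves 22 valid ones
  expect_equal(nrow(st[st$valid, ]), 22L)
  cnt <- res$an$counts
  expect_lte(abs(cnt$detected + cnt$excluded - cnt$theoretical), 2)
  # all valid strides share the nominal duration
  expect_true(all(abs(st$dur_frames[st$valid] - 24) <= 1))
})

test_that("noiseless recovery matches the filtered closed-form truth", {
  for (a in c(0, 2.5)) {
    res <- analyze_clean(duration = 20, asym_amp = a)
    v <- res$an$keypoints$withers$strides
    v <- v[v$valid, ]
    orc <- oracle_symmetry(res$p, "withers",
                           cutoff = 0.95 * res$an$f_est)
    expect_equal(mean(v$maxdiff), orc$maxdiff, tolerance = 0.05)
    expect_equal(mean(v$mindiff), orc$mindiff, tolerance = 0.05)
  }
})

test_that("swapping side labels negates both metrics exactly", {
  res <- analyze_clean(duration = 20, asym_amp = 2.5)
  an <- res$an
  v <- an$keypoints$withers$vds
  st <- segment_strides(res$traj, an$stances, v)
  sw <- segment_strides(res$traj, an$stances, v, swap_sides = TRUE)
  expect_equal(sw$maxdiff[st$valid], -st$maxdiff[st$valid])
  expect_equal(sw$mindiff[st$valid], -st$mindiff[st$valid])
})

test_that("a stride with a third prominent peak is refused, not force-fit", {
  fps <- 30
  t <- (0:599) / fps
  vals <- 30 * cos(4 * pi * 1.25 * t)
  vds <- structure(
    list(values = vals, values_px = vals, visible = rep(TRUE, 600),
         fps = fps, keypoint = "withers", scale = 1, f_est = 1.25,
         cutoff = 1.1875, filtered = TRUE, warmup = rep(FALSE, 600),
         unit = "mm"), class = "vds")
  # a clean stride works
  ok <- compute_symmetry(vds, 100, 124)
  expect_equal(ok$maxdiff, 0, tolerance = 0.05)
  # inject a large spike between the two genuine maxima (well separated
  # from both, so it cannot be absorbed into either peak)
  vds$values[115] <- 45
  expect_error(compute_symmetry(vds, 100, 124), "malformed")
})

test_that("occluded strides are excluded with their reason recorded", {
  res <- analyze_clean(duration = 20)
  traj <- res$traj
  st0 <- res$an$keypoints$withers$strides
  target <- st0[st0$valid, ][3, ]
  traj$visible[target$start + 5L, "withers"] <- FALSE
  an <- analyze_trajectories(traj, res$p$withers_height, keypoints = "withers")
  st <- an$keypoints$withers$strides
  row <- st[st$start == target$start, ]
  expect_false(row$valid)
  expect_equal(row$reason, "occluded")
})

test_that("trial splitting follows the 17-stride rule with remainder handling", {
  mk <- function(n) {
    data.frame(stride = 1:n, start = 1:n * 24, end = 1:n * 24 + 24,
               maxdiff = rep_len(c(4, 5, 6), n), mindiff = 0,
               valid = TRUE, reason = "")
  }
  t51 <- split_trials(mk(51), 17)
  expect_equal(nrow(t51), 3)
  expect_true(all(t51$n_strides == 17))
  t60 <- split_trials(mk(60), 17)
  expect_equal(t60$n_strides, c(17, 17, 17, 9))
  t58 <- split_trials(mk(58), 17)  # remainder 7 < 8.5 dropped
  expect_equal(nrow(t58), 3)
  tri <- split_trials(mk(3), 2)
  expect_equal(tri$n_strides, c(2, 1))
  three <- data.frame(stride = 1:3, start = 1:3, end = 2:4,
                      maxdiff = c(4, 5, 6), mindiff = c(1, 1, 1),
                      valid = TRUE, reason = "")
  expect_equal(split_trials(three, 3)$maxdiff, 5)
  expect_error(split_trials(three, 1), "target_len")
})
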