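# Shared fixtures and independent oracles for the test suite. Everything is
# generated in code; no stored data.

# Exhaustive least-absolute-residual line fit: the optimal L1 line passes
# through two of the data points, so trying every pair is an exact oracle
# for small point sets.
exhaustive_l1_fit <- function(x, y) {
  n <- length(x)
  best <- NULL
  best_cost <- Inf
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (abs(x[j] - x[i]) < 1e-9) next
    b <- (y[j] - y[i]) / (x[j] - x[i])
    c0 <- y[i] - b * x[i]
    cost <- sum(abs(y - (b * x + c0)))
    if (cost < best_cost) {
      best_cost <- cost
      best <- c(b = b, c = c0)
    }
  }
  best
}

# Dense-grid extremum search on the closed-form trunk trajectory, written
# independently of the package's oracle: one stride starting at the
# left-fore stance onset (phase 0.875), halves split at T/2.
grid_symmetry <- function(A, a, f, phi = 0, psi = 0, n_grid = 1e4,
                          g1 = 1, g2 = 1) {
  T <- 1 / f
  s <- seq(0, T, length.out = n_grid + 1)[-(n_grid + 1)]
  t <- 0.875 / f + s
  z <- -A * g2 * cos(4 * pi * f * t + phi) + a * g1 * sin(2 * pi * f * t + psi)
  left <- s < T / 2
  list(maxdiff = max(z[left]) - max(z[!left]),
       mindiff = min(z[left]) - min(z[!left]))
}

# a small, fast standard horse for unit tests
test_params <- function(duration = 20, noise_sigma = 0, asym_amp = 0, ...) {
  gait_params(duration = duration, noise_sigma = noise_sigma,
              asym_amp = asym_amp, ...)
}

side_camera <- function() default_cameras()[["cam3"]]

# hand-built trajectory_set around a single keypoint set
manual_traj <- function(x, y, visible = NULL, keypoints = colnames(x),
                        fps = 30) {
  if (is.null(visible)) visible <- matrix(TRUE, nrow(x), ncol(x),
                                          dimnames = dimnames(x))
  strideline:::new_trajectory_set(
    x = x, y = y, visible = visible, keypoints = keypoints, fps = fps,
    time = (seq_len(nrow(x)) - 1) / fps, camera_id = "manual",
    image_size = c(1920, 1080))
}
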