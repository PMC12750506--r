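#' Simulate ground-truth trot kinematics on a treadmill
#'
#' Generates 3D positions (mm) of 16 landmarks for a horse trotting in place
#' on a treadmill, in a right-handed treadmill-fixed frame: x along the
#' direction of travel, y to the horse's left, z up, ground plane z = 0. All
#' landmarks lie in the sagittal plane (y = 0); trotting horses largely
#' single-track and the downstream pipeline is strictly two-dimensional.
#'
#' Trunk landmarks follow the two-harmonic model described in
#' [gait_params()]. Diagonal limb pairs (LF+RH, RF+LH) move in anti-phase;
#' each hoof alternates a stance phase (on the ground, carried backwards at
#' belt speed) and a swing phase (half-sine lift to `hoof_lift` with a
#' constant-velocity forward reset). The left-fore stance onset is placed at
#' stride phase 0.875 so that, with default trunk phases, the four trunk
#' extrema of every stride fall well inside the two stride halves.
#'
#' The operation is fully deterministic: no randomness is involved.
#'
#' @param params A [gait_params()] object.
#' @return An object of class `world_track`: list with `xyz` (frames x
#'   keypoints x 3 array, mm), `stance` (frames x 4 logical matrix, legs
#'   lf/rf/lh/rh), `time` (s), and the originating `params`.
#' @export
simulate_gait <- function(params) {
  if (!inherits(params, "gait_params"))
    stop("'params' must be a gait_params object", call. = FALSE)
  f <- params$stride_frequency
  fps <- params$fps
  n <- round(params$duration * fps)
  if (n < 2L) stop("'duration' too short for the given fps", call. = FALSE)
  t <- (seq_len(n) - 1L) / fps
  wh <- params$withers_height * 10  # mm

  kp <- all_keypoints()
  xyz <- array(0, dim = c(n, length(kp), 3L),
               dimnames = list(NULL, kp, c("x", "y", "z")))

  # trunk: static x positions and two-harmonic vertical trajectories
  trunk_x <- c(eye = 1150, withers = 350, back = -150, croup = -700)
  trunk_z0 <- c(eye = 1.00, withers = 1.00, back = 0.93, croup = 1.00) * wh
  amp_of <- function(k) if (k == "back") params$trunk_amp["withers"] else params$trunk_amp[k]
  asym_of <- function(k) if (k == "back") params$asym_amp["withers"] else params$asym_amp[k]
  ph_of <- function(k) if (k == "back") params$trunk_phase["withers"] else params$trunk_phase[k]
  for (k in trunk_keypoints()) {
    xyz[, k, "x"] <- trunk_x[k]
    xyz[, k, "z"] <- trunk_z0[k] -
      amp_of(k) * cos(4 * pi * f * t + ph_of(k)) +
      asym_of(k) * sin(2 * pi * f * t + params$asym_phase)
  }

  # legs: diagonal pairs in anti-phase; stance onset of LF at phase 0.875
  duty <- params$duty_factor
  belt_mm <- params$belt_speed * 1000
  sweep <- belt_mm * duty / f  # stance travel, mm
  leg_x0 <- c(lf = 450, rf = 450, lh = -650, rh = -650)
  leg_off <- c(lf = 0.875, rf = 0.375, lh = 0.375, rh = 0.875)
  joint_z0 <- c(lf = 420, rf = 420, lh = 480, rh = 480)
  stance <- matrix(FALSE, n, 4L, dimnames = list(NULL, leg_ids()))
  for (leg in leg_ids()) {
    phase <- (f * t - leg_off[leg]) %% 1
    st <- phase < duty
    stance[, leg] <- st
    hx <- hz <- numeric(n)
    s <- phase[st] / duty
    hx[st] <- leg_x0[leg] + sweep / 2 - sweep * s
    hz[st] <- 0
    q <- (phase[!st] - duty) / (1 - duty)
    hx[!st] <- leg_x0[leg] - sweep / 2 + sweep * q
    hz[!st] <- params$hoof_lift * sin(pi * q)
    xyz[, paste0("hoof_", leg), "x"] <- hx
    xyz[, paste0("hoof_", leg), "z"] <- hz
    xyz[, paste0("fetlock_", leg), "x"] <- leg_x0[leg] + 0.75 * (hx - leg_x0[leg])
    xyz[, paste0("fetlock_", leg), "z"] <- 0.85 * hz + 90
    joint <- if (leg %in% c("lf", "rf")) paste0("carpus_", leg) else paste0("tarsus_", leg)
    xyz[, joint, "x"] <- leg_x0[leg] + 0.45 * (hx - leg_x0[leg])
    xyz[, joint, "z"] <- 0.40 * hz + joint_z0[leg]
  }

  structure(list(xyz = xyz, stance = stance, time = t, params = params),
            class = "world_track")
}

#' @export
print.world_track <- function(x, ...) {
  cat(sprintf("World track: %d frames at %g fps, %d keypoints\n",
              length(x$time), x$params$fps, dim(x$xyz)[2]))
  cat(sprintf("  stride frequency %.3g Hz, duty factor %.2f\n",
              x$params$stride_frequency, x$params$duty_factor))
  invisible(x)
}

# Camera basis and per-frame centers (mm). Orientation is fixed; handheld
# motion is a pure translation of the camera center.
camera_geometry <- function(cam, time) {
  v <- cam$view_angle * pi / 180
  dirx <- switch(cam$facing, side = 0, front = -1, rear = 1)
  sy <- if (cam$side == "right") 1 else -1
  axis <- c(dirx * cos(v), sy * sin(v), 0)
  axis <- axis / sqrt(sum(axis^2))
  d <- cam$distance_from_midline * 10
  D <- d / sin(v)
  center <- c(0, 0, cam$height * 10) - D * axis
  cam_x <- cross3(axis, c(0, 0, 1))
  cam_x <- cam_x / sqrt(sum(cam_x^2))
  cam_y <- cross3(axis, cam_x)  # image-down

  n <- length(time)
  centers <- matrix(rep(center, each = n), n, 3L)
  if (cam$handheld && n > 0L) {
    b <- handheld_bounce(cam, time)
    centers[, 3] <- centers[, 3] + b$vertical
    centers <- centers + outer(b$horizontal, cam_x)
  }
  list(axis = axis, cam_x = cam_x, cam_y = cam_y, centers = centers)
}

# Seeded operator bounce: dominant sinusoid at bounce_frequency plus
# low-pass-filtered jitter; deterministic given bounce_seed.
handheld_bounce <- function(cam, time) {
  n <- length(time)
  with_seed(cam$bounce_seed, {
    th <- stats::runif(2, 0, 2 * pi)
    jit <- matrix(stats::rnorm(2 * n), n, 2)
  })
  fps <- if (n > 1L) 1 / stats::median(diff(time)) else 30
  w <- min(0.9, 3 / (fps / 2))
  lp <- signal::butter(2, w, type = "low")
  smooth <- apply(jit, 2, function(col) signal::filtfilt(lp, col))
  smooth <- sweep(smooth, 2, pmax(apply(smooth, 2, stats::sd), 1e-12), "/")
  amp <- cam$bounce_amp
  list(
    vertical = amp * sin(2 * pi * cam$bounce_frequency * time + th[1]) +
      0.15 * amp * smooth[, 1],
    horizontal = 0.6 * amp * sin(2 * pi * cam$bounce_frequency * time + th[2]) +
      0.10 * amp * smooth[, 2]
  )
}

new_trajectory_set <- function(x, y, visible, keypoints, fps, time,
                               camera_id = NA_character_, sync_offset = 0L,
                               image_size = NULL) {
  structure(list(x = x, y = y, visible = visible, keypoints = keypoints,
                 fps = fps, time = time, camera_id = camera_id,
                 sync_offset = as.integer(sync_offset),
                 image_size = image_size),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  vis <- mean(x$visible)
  cat(sprintf("Trajectory set (%s): %d frames at %g fps, %d keypoints, %.1f%% visible\n",
              x$camera_id, nrow(x$x), x$fps, length(x$keypoints), 100 * vis))
  invisible(x)
}

#' Project world kinematics through a pinhole camera
#'
#' Standard pinhole projection of every keypoint into image coordinates
#' (x right, y down, origin at the top-left corner, principal point at the
#' image center). For handheld cameras the camera center is displaced each
#' frame by the seeded bounce; orientation stays fixed. A keypoint-frame is
#' visible unless it projects outside the image or lies behind the camera
#' plane.
#'
#' @param world A [simulate_gait()] result.
#' @param cam A [camera_model()].
#' @return A `trajectory_set`: per-frame pixel coordinates and visibility per
#'   keypoint, plus fps, timestamps and the camera id.
#' @export
project_keypoints <- function(world, cam) {
  if (!inherits(world, "world_track"))
    stop("'world' must be a world_track object", call. = FALSE)
  if (!inherits(cam, "camera_model"))
    stop("'cam' must be a camera_model object", call. = FALSE)
  if (cam$distance_from_midline * 10 < 1500)
    stop("camera is too close to the treadmill: the pose would intersect the horse volume",
         call. = FALSE)
  geo <- camera_geometry(cam, world$time)
  n <- dim(world$xyz)[1]
  kp <- dimnames(world$xyz)[[2]]
  W <- cam$image_size[1]; H <- cam$image_size[2]
  fl <- cam$focal_length
  x <- y <- matrix(NA_real_, n, length(kp), dimnames = list(NULL, kp))
  vis <- matrix(FALSE, n, length(kp), dimnames = list(NULL, kp))
  for (j in seq_along(kp)) {
    P <- world$xyz[, j, ] - geo$centers
    Xc <- P %*% geo$cam_x
    Yc <- P %*% geo$cam_y
    Zc <- P %*% geo$axis
    ok <- Zc > 1e-6
    u <- W / 2 + fl * Xc / Zc
    v <- H / 2 + fl * Yc / Zc
    x[, j] <- u
    y[, j] <- v
    vis[, j] <- ok & u >= 0 & u < W & v >= 0 & v < H
  }
  new_trajectory_set(x, y, vis, kp, world$params$fps, world$time,
                     camera_id = cam$id, image_size = cam$image_size)
}

#' Corrupt a trajectory set with detection noise and occlusion
#'
#' Adds i.i.d. Gaussian pixel noise to the keypoint coordinates and
#' independently flips visibility to `FALSE` with probability
#' `occlusion_rate` per keypoint-frame, emulating detector imprecision and
#' momentary occlusions. Reproducible under `seed`; with zero noise and zero
#' occlusion the input is returned unchanged.
#'
#' @param traj A `trajectory_set`.
#' @param noise_sigma Gaussian pixel noise standard deviation (>= 0).
#' @param occlusion_rate Per keypoint-frame occlusion probability in [0, 1).
#' @param seed Integer seed.
#' @return The corrupted `trajectory_set`.
#' @export
corrupt_trajectories <- function(traj, noise_sigma, occlusion_rate, seed = 1L) {
  stopifnot(inherits(traj, "trajectory_set"))
  check_number(noise_sigma, "noise_sigma", lower = 0)
  check_number(occlusion_rate, "occlusion_rate", lower = 0, upper = 1,
               strict_upper = TRUE)
  if (noise_sigma == 0 && occlusion_rate == 0) return(traj)
  nc <- length(traj$x)
  with_seed(seed, {
    if (noise_sigma > 0) {
      traj$x <- traj$x + matrix(stats::rnorm(nc, sd = noise_sigma), nrow(traj$x))
      traj$y <- traj$y + matrix(stats::rnorm(nc, sd = noise_sigma), nrow(traj$y))
    }
    if (occlusion_rate > 0) {
      hide <- matrix(stats::runif(nc) < occlusion_rate, nrow(traj$visible))
      traj$visible <- traj$visible & !hide
    }
  })
  traj
}

#' Simulate one camera recording of one horse
#'
#' Convenience wrapper: [simulate_gait()], [project_keypoints()] and
#' [corrupt_trajectories()] in sequence, using the noise and occlusion levels
#' stored in `params`.
#'
#' @param params A [gait_params()] object.
#' @param cam A [camera_model()].
#' @param seed Seed for the corruption step (defaults to `params$seed`).
#' @param world Optional precomputed [simulate_gait()] result (reused across
#'   cameras of the same session).
#' @return A `trajectory_set`.
#' @export
simulate_recording <- function(params, cam, seed = params$seed, world = NULL) {
  world <- world %||% simulate_gait(params)
  traj <- project_keypoints(world, cam)
  corrupt_trajectories(traj, params$noise_sigma, params$occlusion_rate, seed)
}

#' Reference groundline from camera geometry
#'
#' Projects the treadmill midline trace of the ground plane (the line y = 0,
#' z = 0 in world coordinates) into image coordinates for every frame. For a
#' static camera the result is constant across frames and plays the role of
#' the marked, fixed groundline control; for a handheld camera the line moves
#' with the camera.
#'
#' @param world A [simulate_gait()] result.
#' @param cam A [camera_model()].
#' @return A [groundline] object with one entry per frame.
#' @export
true_groundline <- function(world, cam) {
  stopifnot(inherits(world, "world_track"), inherits(cam, "camera_model"))
  geo <- camera_geometry(cam, world$time)
  n <- length(world$time)
  fl <- cam$focal_length
  W <- cam$image_size[1]; H <- cam$image_size[2]
  proj <- function(P) {
    Q <- matrix(rep(P, each = n), n, 3L) - geo$centers
    cbind(W / 2 + fl * (Q %*% geo$cam_x) / (Q %*% geo$axis),
          H / 2 + fl * (Q %*% geo$cam_y) / (Q %*% geo$axis))
  }
  p1 <- proj(c(-2000, 0, 0))
  p2 <- proj(c(2000, 0, 0))
  b <- as.vector((p2[, 2] - p1[, 2]) / (p2[, 1] - p1[, 1]))
  cc <- as.vector(p1[, 2] - b * p1[, 1])
  new_groundline(angle = atan(b) * 180 / pi, offset = cc / sqrt(1 + b^2),
                 valid = rep(TRUE, n))
}

#' Ground-truth stride symmetry from the closed-form trunk trajectory
#'
#' Computes the per-stride Maxdiff and Mindiff implied by the simulator's
#' closed-form trunk trajectory, by dense-grid extremum search over one
#' stride (all strides are identical). The stride is delimited by left-fore
#' stance onsets and split into halves exactly as the measurement pipeline
#' does, so the result is the reference value every recovery test compares
#' against.
#'
#' If `cutoff` is given, the exact discrete two-pass (zero-phase) gain of the
#' pipeline's 3rd-order Butterworth high-pass filter is applied to each
#' harmonic before the search, yielding the ground truth for what a filtered
#' pipeline measures; with `cutoff = NULL` the raw kinematic truth is
#' returned.
#'
#' @param params A [gait_params()] object.
#' @param keypoint One of `"eye"`, `"withers"`, `"croup"`.
#' @param cutoff High-pass cutoff frequency in Hz, or `NULL` for unfiltered.
#' @param n_grid Grid points per stride for the extremum search.
#' @return List with `maxdiff`, `mindiff` (mm) and the four extremum values.
#' @export
oracle_symmetry <- function(params, keypoint = "withers", cutoff = NULL,
                            n_grid = 1e4) {
  stopifnot(inherits(params, "gait_params"))
  keypoint <- match.arg(keypoint, c("eye", "withers", "croup"))
  f <- params$stride_frequency
  A <- params$trunk_amp[keypoint]
  a <- params$asym_amp[keypoint]
  phi <- params$trunk_phase[keypoint]
  psi <- params$asym_phase
  g1 <- g2 <- 1
  if (!is.null(cutoff)) {
    g <- butter_twopass_gain(c(f, 2 * f), cutoff, params$fps)
    g1 <- g[1]; g2 <- g[2]
  }
  T <- 1 / f
  t0 <- 0.875 / f  # left-fore stance onset
  s <- seq(0, T, length.out = n_grid + 1L)[-(n_grid + 1L)]
  z <- -A * g2 * cos(4 * pi * f * (t0 + s) + phi) +
    a * g1 * sin(2 * pi * f * (t0 + s) + psi)
  left <- s < T / 2
  out <- list(
    left_max = max(z[left]), right_max = max(z[!left]),
    left_min = min(z[left]), right_min = min(z[!left])
  )
  out$maxdiff <- out$left_max - out$right_max
  out$mindiff <- out$left_min - out$right_min
  out
}

# Exact amplitude gain of two passes (forward-backward) of the discrete
# 3rd-order Butterworth high-pass at the given frequencies (Hz).
butter_twopass_gain <- function(freq, cutoff, fps) {
  bf <- signal::butter(3, cutoff / (fps / 2), type = "high")
  w <- 2 * pi * freq / fps
  H <- vapply(w, function(wi) {
    e <- exp(-1i * wi * (seq_along(bf$b) - 1))
    Mod(sum(bf$b * e) / sum(bf$a * exp(-1i * wi * (seq_along(bf$a) - 1))))
  }, numeric(1))
  H^2
}
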