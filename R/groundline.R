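#' Per-frame image-plane groundline
#'
#' A groundline is the image-plane line representing the ground surface,
#' parameterised per frame by its angle (degrees, counter-clockwise from the
#' image x-axis, in (-90, 90]; positive means the line's image y increases
#' left-to-right, i.e. the slope dy/dx is positive in top-left-origin
#' coordinates) and its signed perpendicular offset from the image origin in
#' pixels. A horizontal line at image row y0 has angle 0 and offset y0.
#'
#' @param angle Per-frame angle in degrees.
#' @param offset Per-frame signed perpendicular offset in px.
#' @param valid Per-frame validity flag.
#' @return An object of class `groundline`.
#' @export
new_groundline <- function(angle, offset, valid = rep(TRUE, length(angle))) {
  stopifnot(length(angle) == length(offset), length(angle) == length(valid))
  if (any(is.finite(angle) & (angle <= -90 | angle > 90)))
    stop("groundline angles must lie in (-90, 90] degrees", call. = FALSE)
  structure(list(angle = as.numeric(angle), offset = as.numeric(offset),
                 valid = as.logical(valid), n = length(angle)),
            class = "groundline")
}

#' Constant (fixed) groundline
#'
#' The fixed-groundline control: one line, replicated over all frames, as
#' when the ground reference is marked once from the treadmill base.
#'
#' @param angle Line angle in degrees.
#' @param offset Signed perpendicular offset in px.
#' @param n_frames Number of frames.
#' @return A `groundline`.
#' @export
fixed_groundline <- function(angle, offset, n_frames) {
  new_groundline(rep(angle, n_frames), rep(offset, n_frames))
}

#' @export
print.groundline <- function(x, ...) {
  cat(sprintf("Groundline: %d frames, %d valid\n", x$n, sum(x$valid)))
  cat(sprintf("  angle: mean %.3f deg (range %.3f to %.3f)\n",
              mean(x$angle), min(x$angle), max(x$angle)))
  cat(sprintf("  offset: mean %.1f px (range %.1f to %.1f)\n",
              mean(x$offset), min(x$offset), max(x$offset)))
  invisible(x)
}

# slope/intercept form y = b x + c of each frame's line
gl_line <- function(gl) {
  b <- tan(gl$angle * pi / 180)
  list(b = b, c = gl$offset * sqrt(1 + b^2))
}

#' Detect stance phases from hoof keypoint trajectories
#'
#' Finds, per leg, maximal frame runs in which the hoof is on the ground.
#' Because a stance hoof still travels with the belt (tens of px/frame
#' horizontally, along a trace that is slanted for oblique views), the
#' motion criterion is applied to the hoof's perpendicular residual to a
#' coarse per-hoof ground trace (a quantile line fit to the hoof's pixel
#' cloud): during stance that residual is constant. A frame is stance when
#' the smoothed residual changes by less than `v_thresh` px/frame and sits
#' within `d_thresh` px of its local lowest point. Runs separated by gaps of
#' at most two frames are merged; runs shorter than `min_stance` frames are
#' discarded. For a perpendicular side view the residual reduces to the
#' vertical pixel coordinate.
#'
#' When a `groundline` estimate is supplied (the pipeline's second pass),
#' the residual is taken relative to that per-frame line instead of the
#' static coarse trace, which keeps detection accurate under camera motion;
#' the proximity test then uses the absolute distance to the line.
#'
#' @param traj A `trajectory_set` containing `hoof_*` keypoints.
#' @param fps Frame rate (defaults to the trajectory's).
#' @param v_thresh Vertical speed threshold, px/frame.
#' @param d_thresh Distance from the local lowest point (or from the
#'   reference groundline), px.
#' @param min_stance Minimum stance length, frames.
#' @param window Rolling window (frames) used for the local lowest point;
#'   should span roughly one stride.
#' @param smooth Moving-average length (frames) applied before
#'   differentiation.
#' @param groundline Optional [groundline] to use as the ground reference.
#' @return A data.frame of stance events: `leg`, `start`, `end` (inclusive
#'   frame indices) and representative hoof pixel coordinates `x`, `y`.
#'   Empty if no stance is found.
#' @export
detect_stance <- function(traj, fps = traj$fps, v_thresh = 1.5, d_thresh = 5,
                          min_stance = 3L, window = 31L, smooth = 3L,
                          groundline = NULL) {
  stopifnot(inherits(traj, "trajectory_set"))
  hooves <- intersect(hoof_keypoints(), traj$keypoints)
  if (length(hooves) == 0L)
    stop("trajectory set contains no hoof keypoints", call. = FALSE)
  out <- list()
  for (h in hooves) {
    vis <- traj$visible[, h]
    yv <- if (is.null(groundline)) {
      hoof_ground_residual(traj$x[, h], traj$y[, h], vis)
    } else {
      -point_line_distance(traj$x[, h], traj$y[, h], groundline)
    }
    yv[!vis] <- NA
    if (all(is.na(yv))) next
    # running median denoises without smearing the touchdown edge
    ys <- stats::runmed(fill_gaps(yv), smooth, endrule = "constant")
    # forward difference: the touchdown frame stops abruptly (large
    # backward step, zero forward step) and still belongs to the stance
    vy <- c(abs(diff(ys)), NA)
    near_ground <- if (is.null(groundline)) {
      ys > rolling_max(ys, window) - d_thresh
    } else {
      abs(ys) < d_thresh
    }
    flag <- !is.na(vy) & vy < v_thresh & near_ground & vis
    # bridge 1-2 frame dropouts inside a stance
    runs <- true_runs(flag)
    if (nrow(runs) > 1L) {
      keep <- rep(TRUE, nrow(runs))
      for (i in 2:nrow(runs)) {
        if (runs[i, "start"] - runs[i - 1L, "end"] <= 3L) {
          runs[i, "start"] <- runs[i - 1L, "start"]
          keep[i - 1L] <- FALSE
        }
      }
      runs <- runs[keep, , drop = FALSE]
    }
    runs <- runs[runs[, "end"] - runs[, "start"] + 1L >= min_stance, ,
                 drop = FALSE]
    if (nrow(runs) == 0L) next
    leg <- sub("hoof_", "", h)
    out[[h]] <- data.frame(
      leg = leg, start = runs[, "start"], end = runs[, "end"],
      x = vapply(seq_len(nrow(runs)), function(i)
        stats::median(traj$x[runs[i, 1]:runs[i, 2], h]), numeric(1)),
      y = vapply(seq_len(nrow(runs)), function(i)
        stats::median(traj$y[runs[i, 1]:runs[i, 2], h]), numeric(1)),
      row.names = NULL
    )
  }
  if (length(out) == 0L)
    return(data.frame(leg = character(), start = integer(), end = integer(),
                      x = numeric(), y = numeric()))
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$leg), ]
  rownames(res) <- NULL
  res
}

# Per-frame support points for the groundline fit: the mean of all
# stance-phase hoof pixels in each frame. Averaging the simultaneous stance
# hooves of a diagonal pair into one support point prevents duplicate-point
# leverage and cancels front/hind perspective asymmetry.
stance_support <- function(traj, stances) {
  n <- nrow(traj$x)
  sx <- sy <- cnt <- numeric(n)
  for (i in seq_len(nrow(stances))) {
    h <- paste0("hoof_", stances$leg[i])
    fr <- stances$start[i]:stances$end[i]
    fr <- fr[traj$visible[fr, h]]
    sx[fr] <- sx[fr] + traj$x[fr, h]
    sy[fr] <- sy[fr] + traj$y[fr, h]
    cnt[fr] <- cnt[fr] + 1
  }
  has <- cnt > 0
  data.frame(frame = which(has), x = sx[has] / cnt[has], y = sy[has] / cnt[has])
}

# Least-absolute-residual line fit y = b x + c via iteratively reweighted
# least squares; returns OLS when residuals vanish (exact collinear input).
# With tau != 0.5 this becomes a quantile line fit (fraction tau of the
# points end up above the line, i.e. at smaller residual y - line).
l1_line_fit <- function(x, y, max_iter = 40L, tol = 1e-12, tau = 0.5) {
  w <- rep(1, length(x))
  b <- c0 <- NA_real_
  for (it in seq_len(max_iter)) {
    sw <- sum(w)
    mx <- sum(w * x) / sw
    my <- sum(w * y) / sw
    vxx <- sum(w * (x - mx)^2)
    if (vxx < 1e-12) return(NULL)  # vertical/degenerate support
    b_new <- sum(w * (x - mx) * (y - my)) / vxx
    c_new <- my - b_new * mx
    if (!is.na(b) && abs(b_new - b) < tol && abs(c_new - c0) < tol) {
      b <- b_new; c0 <- c_new; break
    }
    b <- b_new; c0 <- c_new
    r <- y - (b * x + c0)
    w <- ifelse(r >= 0, tau, 1 - tau) / pmax(abs(r), 1e-6)
  }
  if (tau == 0.5) {
    # polish: the L1 optimum interpolates two data points; try pairs among
    # the smallest-residual points of the IRLS solution
    r <- abs(y - (b * x + c0))
    cost <- sum(r)
    cand <- order(r)[seq_len(min(length(x), 6L))]
    for (i in cand) for (j in cand) {
      if (j <= i || abs(x[j] - x[i]) < 1e-9) next
      b2 <- (y[j] - y[i]) / (x[j] - x[i])
      c2 <- y[i] - b2 * x[i]
      cost2 <- sum(abs(y - (b2 * x + c2)))
      if (cost2 < cost) {
        cost <- cost2; b <- b2; c0 <- c2
      }
    }
  }
  c(b = b, c = c0)
}

# Coarse per-hoof ground trace: a quantile line fit to the hoof's visible
# pixel cloud. The hoof rides this trace during stance and swings above it
# (smaller image y), so the lower envelope (large-y quantile) tracks the
# ground even for oblique views where the trace is slanted. Returns the
# signed perpendicular residual (0 on the trace, negative above it), or the
# raw y coordinate when the cloud is degenerate.
hoof_ground_residual <- function(x, y, vis, tau = 0.75) {
  ok <- vis & !is.na(x) & !is.na(y)
  if (sum(ok) < 10L || diff(range(x[ok])) < 1) return(y)
  fit <- l1_line_fit(x[ok], y[ok], tau = tau)
  if (is.null(fit)) return(y)
  (y - (fit["b"] * x + fit["c"])) / sqrt(1 + fit["b"]^2)
}

#' Estimate the dynamic groundline from stance hoof keypoints
#'
#' For every frame, fits a line by robust (least absolute residual)
#' regression to the stance-phase hoof support points inside a sliding window
#' centered on the frame. Frames whose window holds fewer than two support
#' points with distinct x are marked invalid and filled by linear
#' interpolation of the neighbouring valid line parameters.
#'
#' The fit runs at two time scales. The line's angle — and a baseline
#' offset — come from the sliding `window` (about one stride), which keeps
#' the orientation stable through single-support and suspension moments.
#' The offset is then corrected per frame by the perpendicular residual of
#' the current stance support to that windowed line, smoothed over the short
#' `offset_window`: this lets the line follow fast image translation (a
#' handheld camera's bounce) that a one-stride window would average away,
#' while for a static camera the correction is just a small zero-mean noise
#' term well above the passband of the stride metrics.
#'
#' @param traj A `trajectory_set`.
#' @param stances Stance events from [detect_stance()].
#' @param window Sliding window length in frames (default ~1 stride).
#' @param offset_window Short window (frames) for the per-frame offset
#'   correction; `0` disables the correction.
#' @return A [groundline] with per-frame angle, offset and validity.
#' @export
estimate_groundline <- function(traj, stances, window = 31L,
                                offset_window = 5L) {
  stopifnot(inherits(traj, "trajectory_set"))
  n <- nrow(traj$x)
  sup <- stance_support(traj, stances)
  if (nrow(sup) < 2L)
    stop(sprintf(
      "groundline estimation failed: only %d stance support frames (%d stance events)",
      nrow(sup), nrow(stances)), call. = FALSE)
  half <- (window - 1L) %/% 2L
  lo <- findInterval(seq_len(n) - half - 1L, sup$frame) + 1L
  hi <- findInterval(seq_len(n) + half, sup$frame)

  window_fit <- function(sy) {
    angle <- offset <- rep(NA_real_, n)
    valid <- rep(FALSE, n)
    for (i in seq_len(n)) {
      if (hi[i] - lo[i] + 1L < 2L) next
      fit <- l1_line_fit(sup$x[lo[i]:hi[i]], sy[lo[i]:hi[i]])
      if (is.null(fit)) next
      angle[i] <- atan(fit["b"]) * 180 / pi
      offset[i] <- fit["c"] / sqrt(1 + fit["b"]^2)
      valid[i] <- TRUE
    }
    if (!any(valid)) {
      stop(sprintf(
        "groundline estimation failed: 0 of %d frames had >= 2 stance support points (%d stance events, %d support frames)",
        n, nrow(stances), nrow(sup)), call. = FALSE)
    }
    if (any(!valid)) {
      iv <- which(valid)
      angle <- stats::approx(iv, angle[iv], xout = seq_len(n), rule = 2)$y
      offset <- stats::approx(iv, offset[iv], xout = seq_len(n), rule = 2)$y
    }
    list(angle = angle, offset = offset, valid = valid)
  }
  # The offset track is smoothed by a zero-phase low-pass. Its bandwidth
  # adapts to the camera: when the track shows real band power (a moving,
  # handheld camera) the cutoff fps / (2 * offset_window) keeps near-unit
  # gain for bounce at a few Hz; for a quiet track (static camera) a 1 Hz
  # cutoff is used, which removes tracking noise from the stride passband
  # while still absorbing slow drift. The decision threshold (1.5 px of
  # 0.3-3 Hz band amplitude) sits several noise standard deviations above
  # a static track and far below any visible camera bounce.
  offset_residual <- function(fit, sy) {
    b <- tan(fit$angle[sup$frame] * pi / 180)
    cc <- fit$offset[sup$frame] * sqrt(1 + b^2)
    res <- (sy - (b * sup$x + cc)) / sqrt(1 + b^2)
    res_all <- rep(NA_real_, n)
    res_all[sup$frame] <- res
    res_all <- fill_gaps_spline(res_all)
    fps <- traj$fps %||% 30
    active_cut <- fps / (2 * max(1L, offset_window))
    if (active_cut >= fps / 2 * 0.95) return(res_all)
    slow <- butter_lowpass(res_all, fps, min(0.3, active_cut / 2))
    band_sd <- stats::sd(butter_lowpass(res_all, fps, active_cut) - slow)
    cut <- if (band_sd > 1.5) active_cut else min(1, active_cut)
    butter_lowpass(res_all, fps, cut)
  }

  if (offset_window > 0L) {
    # Fast vertical image motion (a bouncing camera) masquerades as a tilt
    # inside the sliding window, because the stance hooves sweep in x while
    # the line translates. The whole-recording line is immune (the motion
    # averages out over many cycles), so the per-frame translation track is
    # measured about the global line, removed from the support, and the
    # sliding-window fit then sees a translation-free point cloud; the
    # track is finally re-estimated about the local fit and restored as the
    # per-frame offset correction.
    gfit <- l1_line_fit(sup$x, sup$y)
    if (!is.null(gfit)) {
      gb <- unname(gfit["b"])
      gangle <- rep(atan(gb) * 180 / pi, n)
      goffset <- rep(unname(gfit["c"]) / sqrt(1 + gb^2), n)
      res1 <- offset_residual(list(angle = gangle, offset = goffset), sup$y)
      sy2 <- sup$y - res1[sup$frame] * sqrt(1 + gb^2)
      fit <- window_fit(sy2)
      res2 <- offset_residual(fit, sup$y)
      fit$offset <- fit$offset + res2
    } else {
      fit <- window_fit(sup$y)
    }
  } else {
    fit <- window_fit(sup$y)
  }
  new_groundline(fit$angle, fit$offset, fit$valid)
}

#' Rectify image coordinates so the groundline becomes horizontal
#'
#' Applies the rigid rotation about each line's foot point (the perpendicular
#' projection of the image origin onto the line) that maps the groundline to
#' a horizontal line. In `central_frame` mode the transformation of the
#' central frame is applied to every frame — the fixed-groundline control
#' treatment; in `per_frame` mode each frame uses its own line.
#'
#' @param traj A `trajectory_set`.
#' @param gl A [groundline].
#' @param mode `"central_frame"` or `"per_frame"`.
#' @return The rectified `trajectory_set`.
#' @export
rectify <- function(traj, gl, mode = c("central_frame", "per_frame")) {
  mode <- match.arg(mode)
  stopifnot(inherits(traj, "trajectory_set"), inherits(gl, "groundline"))
  n <- nrow(traj$x)
  if (gl$n != n) stop("groundline and trajectory frame counts differ", call. = FALSE)
  if (mode == "central_frame") {
    mid <- (n + 1L) %/% 2L
    if (!gl$valid[mid])
      stop("central frame has no valid groundline; cannot rectify", call. = FALSE)
    ang <- rep(gl$angle[mid], n)
    off <- rep(gl$offset[mid], n)
  } else {
    ang <- gl$angle
    off <- gl$offset
  }
  al <- ang * pi / 180
  fx <- -off * sin(al)
  fy <- off * cos(al)
  ca <- cos(al); sa <- sin(al)
  for (j in seq_along(traj$keypoints)) {
    dx <- traj$x[, j] - fx
    dy <- traj$y[, j] - fy
    traj$x[, j] <- fx + ca * dx + sa * dy
    traj$y[, j] <- fy - sa * dx + ca * dy
  }
  traj
}

#' Signed per-frame groundline angle error
#'
#' Per-frame signed difference `est - ref` in degrees (wrapped into
#' (-90, 90]), with the summary pair (mean signed error and mean absolute
#' error) used for bias and accuracy histograms.
#'
#' @param est Estimated [groundline].
#' @param ref Reference [groundline].
#' @return An object of class `angle_error`: list with `per_frame`,
#'   `mean_signed`, `mae`, `n`.
#' @export
angle_error <- function(est, ref) {
  stopifnot(inherits(est, "groundline"), inherits(ref, "groundline"))
  if (est$n != ref$n)
    stop(sprintf("frame-count mismatch: est has %d frames, ref has %d",
                 est$n, ref$n), call. = FALSE)
  d <- est$angle - ref$angle
  d <- ifelse(d > 90, d - 180, ifelse(d <= -90, d + 180, d))
  structure(list(per_frame = d, mean_signed = mean(d), mae = mean(abs(d)),
                 n = length(d)), class = "angle_error")
}

#' @export
print.angle_error <- function(x, ...) {
  cat(sprintf("Groundline angle error over %d frames:\n", x$n))
  cat(sprintf("  mean signed %.4f deg, MAE %.4f deg, SD %.4f deg\n",
              x$mean_signed, x$mae, stats::sd(x$per_frame)))
  invisible(x)
}
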