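#' Analysis options for the measurement pipeline
#'
#' Collects the tunable thresholds of the pipeline in one place. Defaults
#' are chosen for 30 fps trot recordings at roughly 0.3 px/mm image scale.
#'
#' @param v_thresh Stance vertical-speed threshold, px/frame.
#' @param d_thresh Stance distance-to-lowest-point threshold, px.
#' @param min_stance Minimum stance event length, frames.
#' @param stance_window Rolling window for the local lowest point, frames.
#' @param stance_smooth Moving-average length before differentiation, frames.
#' @param gl_window Groundline fit sliding window, frames (~1 stride).
#' @param gl_offset_window Short window (frames) for the per-frame
#'   groundline offset correction (see [estimate_groundline()]).
#' @param cutoff_factor High-pass cutoff as a fraction of the stride
#'   frequency (0.95 puts the cutoff 5% below the trot frequency).
#' @param warmup_factor Filter warm-up span per edge, units of 1/cutoff s.
#' @param trial_len Strides per trial segment.
#' @param ci_level Confidence level for MAE intervals.
#' @param band Stride-frequency search band, Hz.
#' @param ref_leg Reference forelimb for stride boundaries.
#' @return A list of class `gait_options`.
#' @export
gait_options <- function(v_thresh = 1.5, d_thresh = 5, min_stance = 3L,
                         stance_window = 31L, stance_smooth = 5L,
                         gl_window = 31L, gl_offset_window = 5L,
                         cutoff_factor = 0.95,
                         warmup_factor = 1, trial_len = 17L,
                         ci_level = 0.99, band = c(0.5, 2.5),
                         ref_leg = "hoof_lf") {
  structure(list(v_thresh = v_thresh, d_thresh = d_thresh,
                 min_stance = min_stance, stance_window = stance_window,
                 stance_smooth = stance_smooth, gl_window = gl_window,
                 gl_offset_window = gl_offset_window,
                 cutoff_factor = cutoff_factor, warmup_factor = warmup_factor,
                 trial_len = trial_len, ci_level = ci_level, band = band,
                 ref_leg = ref_leg), class = "gait_options")
}

#' Run the full measurement pipeline on one recording
#'
#' Executes stance detection, groundline estimation (or the fixed-groundline
#' control), VDS computation, withers-height calibration, stride-frequency
#' estimation, zero-phase high-pass filtering, stride segmentation with
#' Maxdiff/Mindiff, and trial aggregation, for each requested trunk
#' keypoint.
#'
#' @param traj A `trajectory_set`.
#' @param withers_height Withers height of the horse in cm.
#' @param groundline `"dynamic"` (estimated per frame from hoof keypoints)
#'   or `"fixed"` (the supplied reference line, applied via the
#'   central-frame transformation).
#' @param ref_groundline A [groundline] required when `groundline = "fixed"`.
#' @param keypoints Trunk keypoints to analyse.
#' @param options A [gait_options()] list.
#' @param f_est Stride frequency in Hz; estimated from the reference hoof
#'   trajectory when `NULL`.
#' @return An object of class `gait_analysis` with elements `groundline`,
#'   `stances`, `f_est`, per-keypoint `vds`, `strides` and `trials`, and a
#'   `counts` summary (frames, strides detected/excluded, theoretical stride
#'   count over the analyzable span).
#' @export
analyze_trajectories <- function(traj, withers_height,
                                 groundline = c("dynamic", "fixed"),
                                 ref_groundline = NULL,
                                 keypoints = c("eye", "withers", "croup"),
                                 options = gait_options(), f_est = NULL) {
  groundline <- match.arg(groundline)
  stopifnot(inherits(traj, "trajectory_set"))
  opts <- options
  detect <- function(ref = NULL) {
    detect_stance(traj, traj$fps, v_thresh = opts$v_thresh,
                  d_thresh = opts$d_thresh, min_stance = opts$min_stance,
                  window = opts$stance_window, smooth = opts$stance_smooth,
                  groundline = ref)
  }
  estimate <- function(st) {
    estimate_groundline(traj, st, window = opts$gl_window,
                        offset_window = opts$gl_offset_window)
  }
  # two passes: a coarse stance/groundline estimate, then stance detection
  # relative to that line (robust to camera motion) and the final fit
  stances <- detect()
  if (nrow(stances) == 0L)
    stop("no stance events detected; cannot analyse recording", call. = FALSE)
  if (groundline == "dynamic") {
    stances <- detect(estimate(stances))
    if (nrow(stances) == 0L)
      stop("no stance events detected; cannot analyse recording", call. = FALSE)
    gl <- estimate(stances)
  } else {
    if (is.null(ref_groundline))
      stop("'ref_groundline' is required when groundline = \"fixed\"", call. = FALSE)
    mid <- (nrow(traj$x) + 1L) %/% 2L
    stances <- detect(ref_groundline)
    gl <- fixed_groundline(ref_groundline$angle[mid], ref_groundline$offset[mid],
                           nrow(traj$x))
  }
  if (is.null(f_est)) {
    hoof <- traj$y[, opts$ref_leg]
    hoof[!traj$visible[, opts$ref_leg]] <- NA
    f_est <- estimate_stride_frequency(hoof, traj$fps, band = opts$band)
  }
  cutoff <- opts$cutoff_factor * f_est
  res <- list()
  for (kp in keypoints) {
    v <- compute_vds(traj, gl, kp)
    v <- calibrate_vds(v, traj, gl, withers_height)
    v <- highpass_vds(v, f_est, cutoff_factor = opts$cutoff_factor,
                      warmup_factor = opts$warmup_factor)
    st <- segment_strides(traj, stances, v, ref_leg = opts$ref_leg)
    res[[kp]] <- list(vds = v, strides = st,
                      trials = split_trials(st, opts$trial_len))
  }
  n <- nrow(traj$x)
  span <- n / traj$fps - 2 * opts$warmup_factor / cutoff
  counts <- data.frame(
    keypoint = keypoints,
    frames = n,
    theoretical = max(0, span * f_est - 1),
    detected = vapply(res, function(r) sum(r$strides$valid), integer(1)),
    excluded = vapply(res, function(r)
      sum(!r$strides$valid & r$strides$reason != "warmup"), integer(1)),
    row.names = NULL
  )
  structure(list(camera_id = traj$camera_id, groundline_mode = groundline,
                 groundline = gl, stances = stances, f_est = f_est,
                 keypoints = res, counts = counts,
                 withers_height = withers_height, options = opts),
            class = "gait_analysis")
}

#' @export
print.gait_analysis <- function(x, ...) {
  cat(sprintf("Gait analysis (%s, %s groundline)\n",
              x$camera_id, x$groundline_mode))
  cat(sprintf("  stride frequency estimate: %.3f Hz\n", x$f_est))
  for (kp in names(x$keypoints)) {
    st <- x$keypoints[[kp]]$strides
    v <- st[st$valid, ]
    if (nrow(v)) {
      cat(sprintf("  %-8s %3d valid strides  Maxdiff %6.2f mm (SD %.2f)  Mindiff %6.2f mm (SD %.2f)\n",
                  kp, nrow(v), mean(v$maxdiff), stats::sd(v$maxdiff),
                  mean(v$mindiff), stats::sd(v$mindiff)))
    } else {
      cat(sprintf("  %-8s no valid strides\n", kp))
    }
  }
  invisible(x)
}

#' @export
summary.gait_analysis <- function(object, ...) {
  print(object)
  cat("\nStride accounting:\n")
  print(object$counts, row.names = FALSE)
  invisible(object)
}
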