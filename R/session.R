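# Multi-camera session simulation and the three-part evaluation battery.

#' A cohort of simulated horses
#'
#' Generates `n` horses with deterministic, seeded variation around the
#' study conditions: stride frequency near 1.25 Hz, belt speed 4.5-5.2 m/s,
#' withers height 154-168 cm, trunk amplitudes around 30 mm, and a spread of
#' injected asymmetries from sound to clearly asymmetric so the agreement
#' plots span a realistic value range.
#'
#' @param n Number of horses.
#' @param duration Recording length per horse, s.
#' @param noise_sigma Keypoint noise, px.
#' @param occlusion_rate Per keypoint-frame occlusion probability.
#' @param seed Master seed.
#' @return A named list of [gait_params()] objects (`horse1`, ...).
#' @export
make_horses <- function(n = 8, duration = 40, noise_sigma = 1,
                        occlusion_rate = 0, seed = 1L) {
  with_seed(seed, {
    freqs <- stats::runif(n, 1.18, 1.32)
    belts <- stats::runif(n, 4.5, 5.2)
    heights <- stats::runif(n, 154, 168)
    amps <- stats::runif(n, 26, 36)
    asyms <- stats::runif(n, 0, 5) * stats::rbinom(n, 1, 0.75)
    phases <- stats::runif(n, 0, 2 * pi)
  })
  horses <- lapply(seq_len(n), function(i) {
    gait_params(
      stride_frequency = freqs[i], belt_speed = belts[i],
      trunk_amp = amps[i] * c(1.15, 1, 1.05),
      asym_amp = asyms[i] * c(1.2, 1, 1.1),
      asym_phase = phases[i], withers_height = heights[i],
      duration = duration, noise_sigma = noise_sigma,
      occlusion_rate = occlusion_rate,
      seed = as.integer((seed * 1009 + i) %% .Machine$integer.max)
    )
  })
  stats::setNames(horses, paste0("horse", seq_len(n)))
}

#' Configuration of a simulated multi-camera experiment
#'
#' @param horses A list of [gait_params()] (or an integer, expanded via
#'   [make_horses()]).
#' @param cameras A named list of [camera_model()]s with unique ids; default
#'   the seven-camera treadmill rig of [default_cameras()].
#' @param handheld_pair Ids of the handheld and the stationary reference
#'   camera for the handheld comparison, or `NULL` to skip it.
#' @param seed Master seed; per-recording corruption seeds are derived from
#'   it deterministically.
#' @param options [gait_options()] for the analysis stages.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(horses = 8, cameras = default_cameras(),
                              handheld_pair = c("cam7", "cam4"),
                              seed = 1L, options = gait_options()) {
  if (is.numeric(horses) && length(horses) == 1L)
    horses <- make_horses(horses, seed = seed)
  stopifnot(all(vapply(horses, inherits, logical(1), "gait_params")))
  stopifnot(all(vapply(cameras, inherits, logical(1), "camera_model")))
  ids <- vapply(cameras, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop(sprintf("duplicate camera id(s): %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  names(cameras) <- ids
  if (is.null(names(horses)) || any(names(horses) == ""))
    names(horses) <- paste0("horse", seq_along(horses))
  if (!is.null(handheld_pair)) {
    missing <- setdiff(handheld_pair, ids)
    if (length(missing))
      stop(sprintf("camera(s) %s referenced by 'handheld_pair' are missing from the session",
                   paste(missing, collapse = ", ")), call. = FALSE)
  }
  structure(list(horses = horses, cameras = cameras,
                 handheld_pair = handheld_pair, seed = as.integer(seed),
                 options = options),
            class = "experiment_config")
}

# deterministic per-recording corruption seed
recording_seed <- function(master, horse_idx, cam_idx) {
  as.integer((as.double(master) * 7919 + horse_idx * 131 + cam_idx * 17) %%
               .Machine$integer.max)
}

#' Run the full camera-agreement evaluation on a simulated session
#'
#' Simulates every horse under every camera of the configuration and runs
#' the three analyses of the evaluation battery:
#' \enumerate{
#'   \item per-frame groundline angle error of the dynamic estimate against
#'     the known fixed reference, per stationary camera and pooled;
#'   \item per-stride Maxdiff/Mindiff agreement between the
#'     dynamic-groundline and fixed-groundline pipelines on the same videos,
#'     pooled over the stationary cameras, per keypoint and overall;
#'   \item stride- and trial-level agreement between the handheld camera and
#'     its stationary reference, per keypoint and pooled,
#' }
#' together with stride-detection failure accounting (detected and excluded
#' strides against the theoretical count, duration times stride frequency).
#'
#' @param config An [experiment_config()].
#' @param verbose Print per-stage progress counts.
#' @return An object of class `gait_session` holding the angle-error
#'   summaries, the agreement tables (shaped one row per keypoint x metric
#'   plus pooled rows), the Bland-Altman objects, and the stride accounting.
#' @export
evaluate_session <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  opts <- config$options
  cams <- config$cameras
  static_ids <- names(cams)[!vapply(cams, `[[`, logical(1), "handheld")]
  kps <- c("eye", "withers", "croup")

  angle_errors <- stats::setNames(vector("list", length(static_ids)), static_ids)
  dyn_fixed <- list()   # per-stride diffs, dynamic vs fixed pipelines
  handheld_pairs <- list()
  accounting <- list()
  analyses <- list()

  for (hi in seq_along(config$horses)) {
    hname <- names(config$horses)[hi]
    p <- config$horses[[hi]]
    world <- simulate_gait(p)
    for (ci in seq_along(cams)) {
      cam <- cams[[ci]]
      traj <- project_keypoints(world, cam)
      traj <- corrupt_trajectories(traj, p$noise_sigma, p$occlusion_rate,
                                   seed = recording_seed(config$seed, hi, ci))
      gl_true <- true_groundline(world, cam)
      dyn <- analyze_trajectories(traj, p$withers_height, "dynamic",
                                  keypoints = kps, options = opts)
      analyses[[paste(hname, cam$id, sep = ".")]] <- dyn
      if (!cam$handheld) {
        ae <- angle_error(dyn$groundline, gl_true)
        angle_errors[[cam$id]] <- c(angle_errors[[cam$id]], list(ae$per_frame))
        fix <- analyze_trajectories(traj, p$withers_height, "fixed",
                                    ref_groundline = gl_true,
                                    keypoints = kps, options = opts,
                                    f_est = dyn$f_est)
        for (kp in kps) {
          m <- match_strides(dyn$keypoints[[kp]]$strides,
                             fix$keypoints[[kp]]$strides)
          if (nrow(m))
            dyn_fixed[[length(dyn_fixed) + 1L]] <-
              cbind(m, keypoint = kp, camera = cam$id, horse = hname)
        }
      }
      acc <- dyn$counts
      acc$horse <- hname
      acc$camera <- cam$id
      accounting[[length(accounting) + 1L]] <- acc
      if (verbose)
        message(sprintf("%s / %s: f = %.3f Hz, %d-%d valid strides",
                        hname, cam$id, dyn$f_est,
                        min(dyn$counts$detected), max(dyn$counts$detected)))
    }
    if (!is.null(config$handheld_pair)) {
      hh <- analyses[[paste(hname, config$handheld_pair[1], sep = ".")]]
      st <- analyses[[paste(hname, config$handheld_pair[2], sep = ".")]]
      for (kp in kps) {
        m <- match_strides(hh$keypoints[[kp]]$strides,
                           st$keypoints[[kp]]$strides)
        if (nrow(m))
          handheld_pairs[[length(handheld_pairs) + 1L]] <-
            cbind(m, keypoint = kp, horse = hname)
      }
    }
  }

  # --- 1. groundline angle evaluation -----------------------------------
  angle_tab <- do.call(rbind, lapply(static_ids, function(id) {
    e <- unlist(angle_errors[[id]])
    data.frame(camera = id, n = length(e), mean_signed = mean(e),
               sd = stats::sd(e), mae = mean(abs(e)))
  }))
  pooled_angle <- unlist(angle_errors)
  angle <- list(
    per_camera = angle_tab,
    pooled = agreement(pooled_angle, ci_level = opts$ci_level,
                       labels = c("estimated", "fixed"))
  )

  # --- 2. estimated vs fixed groundline, per stride ----------------------
  dyn_fixed <- if (length(dyn_fixed)) do.call(rbind, dyn_fixed) else NULL
  gl_tab <- agreement_table(dyn_fixed, kps, opts$ci_level)
  gl_ba <- if (!is.null(dyn_fixed)) {
    list(maxdiff = bland_altman(dyn_fixed$maxdiff_a, dyn_fixed$maxdiff_b,
                                ci_level = opts$ci_level),
         mindiff = bland_altman(dyn_fixed$mindiff_a, dyn_fixed$mindiff_b,
                                ci_level = opts$ci_level))
  }

  # --- 3. handheld vs stationary ----------------------------------------
  handheld_pairs <- if (length(handheld_pairs)) do.call(rbind, handheld_pairs) else NULL
  hh_stride_tab <- agreement_table(handheld_pairs, kps, opts$ci_level)
  hh_trials <- trial_pairs(handheld_pairs, kps, opts$trial_len)
  hh_trial_tab <- agreement_table(hh_trials, kps, opts$ci_level,
                                  count_col = "n_trials")

  accounting <- do.call(rbind, accounting)
  structure(list(
    angle = angle,
    groundline_comparison = list(table = gl_tab, bland_altman = gl_ba,
                                 pairs = dyn_fixed),
    handheld = list(stride_table = hh_stride_tab, trial_table = hh_trial_tab,
                    pairs = handheld_pairs, trials = hh_trials),
    accounting = accounting,
    config = config
  ), class = "gait_session")
}

# Shape agreement results like the keypoint x metric tables: one row per
# keypoint and metric plus pooled "all" rows.
agreement_table <- function(pairs, kps, ci_level, count_col = "n") {
  if (is.null(pairs) || nrow(pairs) < 2L) return(NULL)
  rows <- list()
  for (metric in c("maxdiff", "mindiff")) {
    d_all <- pairs[[paste0(metric, "_a")]] - pairs[[paste0(metric, "_b")]]
    for (kp in kps) {
      sel <- pairs$keypoint == kp
      if (sum(sel) >= 2L) {
        st <- agreement(d_all[sel], ci_level = ci_level)
        rows[[length(rows) + 1L]] <-
          cbind(data.frame(keypoint = kp, metric = metric), as_row.agreement_stats(st))
      }
    }
    st <- agreement(d_all, ci_level = ci_level)
    rows[[length(rows) + 1L]] <-
      cbind(data.frame(keypoint = "all", metric = metric), as_row.agreement_stats(st))
  }
  out <- do.call(rbind, rows)
  names(out)[names(out) == "n"] <- count_col
  out
}

# Collapse matched stride pairs into contiguous trial-level pairs per horse
# and keypoint: trial value = mean over the member strides, per condition.
trial_pairs <- function(pairs, kps, trial_len) {
  if (is.null(pairs)) return(NULL)
  out <- list()
  for (h in unique(pairs$horse)) {
    for (kp in kps) {
      blk <- pairs[pairs$horse == h & pairs$keypoint == kp, ]
      n <- nrow(blk)
      if (n < trial_len / 2) next
      n_full <- n %/% trial_len
      sizes <- rep(trial_len, n_full)
      rem <- n - n_full * trial_len
      if (rem >= trial_len / 2) sizes <- c(sizes, rem)
      stop_at <- cumsum(sizes)
      start_at <- stop_at - sizes + 1L
      for (k in seq_along(sizes)) {
        b <- blk[start_at[k]:stop_at[k], ]
        out[[length(out) + 1L]] <- data.frame(
          horse = h, keypoint = kp, trial = k, n_strides = nrow(b),
          maxdiff_a = mean(b$maxdiff_a), maxdiff_b = mean(b$maxdiff_b),
          mindiff_a = mean(b$mindiff_a), mindiff_b = mean(b$mindiff_b)
        )
      }
    }
  }
  if (length(out)) do.call(rbind, out) else NULL
}

#' Stride-detection failure accounting of a session
#'
#' @param session A [evaluate_session()] result.
#' @param cameras Camera ids to include (default: all).
#' @return A data.frame per keypoint with theoretical, detected and excluded
#'   stride counts and the failure rate `1 - detected / theoretical`.
#' @export
stride_accounting <- function(session, cameras = NULL) {
  acc <- session$accounting
  if (!is.null(cameras)) acc <- acc[acc$camera %in% cameras, ]
  out <- do.call(rbind, lapply(split(acc, acc$keypoint), function(d) {
    data.frame(keypoint = d$keypoint[1],
               theoretical = sum(d$theoretical),
               detected = sum(d$detected),
               excluded = sum(d$excluded),
               failure_rate = 1 - sum(d$detected) / sum(d$theoretical))
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.gait_session <- function(x, digits = 3, ...) {
  cat("Simulated multi-camera gait session\n")
  cat(sprintf("  %d horses x %d cameras\n", length(x$config$horses),
              length(x$config$cameras)))
  cat("\nGroundline angle error (dynamic vs fixed reference):\n")
  print(cbind(x$angle$per_camera[1:2],
              round(x$angle$per_camera[3:5], 4)), row.names = FALSE)
  po <- x$angle$pooled
  cat(sprintf("  pooled: mean %.3f deg, MAE %.3f deg (n = %d)\n",
              po$mean_signed, po$mae, po$n))
  if (!is.null(x$groundline_comparison$table)) {
    cat("\nPer-stride agreement, estimated vs fixed groundline (mm):\n")
    tb <- x$groundline_comparison$table
    print(cbind(tb[1:3], round(tb[4:10], digits)), row.names = FALSE)
  }
  if (!is.null(x$handheld$stride_table)) {
    cat("\nHandheld vs stationary, stride level (mm):\n")
    tb <- x$handheld$stride_table
    print(cbind(tb[1:3], round(tb[4:10], digits)), row.names = FALSE)
  }
  if (!is.null(x$handheld$trial_table)) {
    cat("\nHandheld vs stationary, trial level (mm):\n")
    tb <- x$handheld$trial_table
    print(cbind(tb[1:3], round(tb[4:10], digits)), row.names = FALSE)
  }
  acc <- stride_accounting(x)
  cat("\nStride accounting (all cameras):\n")
  print(cbind(acc[1], round(acc[2:4], 1),
              failure_rate = round(acc$failure_rate, 4)), row.names = FALSE)
  invisible(x)
}
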