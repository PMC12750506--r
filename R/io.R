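# File formats: trajectory and groundline CSV, experiment configs, reports.
# Frames are written 0-based (image convention); in memory R uses 1-based
# indexing throughout.

traj_header <- function(traj) {
  sprintf("# strideline trajectory v1: camera=%s fps=%g width=%g height=%g sync_offset=%d",
          traj$camera_id, traj$fps,
          (traj$image_size %||% c(NA, NA))[1],
          (traj$image_size %||% c(NA, NA))[2],
          traj$sync_offset)
}

#' Write / read keypoint trajectories as CSV
#'
#' Long-format CSV with columns `frame` (0-based), `time_s`, `keypoint`,
#' `x_px`, `y_px`, `visible`, preceded by a versioned comment header that
#' carries camera id, fps, image size and sync offset.
#'
#' @param traj A `trajectory_set`.
#' @param path Output file.
#' @return `write_trajectories` returns `path` invisibly;
#'   `read_trajectories` returns a `trajectory_set`.
#' @export
write_trajectories <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory_set"))
  n <- nrow(traj$x)
  df <- data.frame(
    frame = rep(seq_len(n) - 1L, times = length(traj$keypoints)),
    time_s = rep(traj$time, times = length(traj$keypoints)),
    keypoint = rep(traj$keypoints, each = n),
    x_px = as.vector(traj$x),
    y_px = as.vector(traj$y),
    visible = as.integer(as.vector(traj$visible))
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(traj_header(traj), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  header <- readLines(path, n = 1L)
  if (!startsWith(header, "# strideline trajectory v1:"))
    stop(sprintf("'%s' is not a strideline trajectory CSV (missing v1 header)",
                 path), call. = FALSE)
  meta <- function(key, default = NA) {
    m <- regmatches(header, regexpr(sprintf("%s=[^ ]+", key), header))
    if (length(m)) sub(sprintf("%s=", key), "", m) else default
  }
  df <- utils::read.csv(path, comment.char = "#")
  kp <- unique(df$keypoint)
  n <- nrow(df) / length(kp)
  shape <- function(col) matrix(df[[col]], n, length(kp), dimnames = list(NULL, kp))
  w <- as.numeric(meta("width")); h <- as.numeric(meta("height"))
  new_trajectory_set(
    x = shape("x_px"), y = shape("y_px"),
    visible = shape("visible") > 0, keypoints = kp,
    fps = as.numeric(meta("fps")), time = df$time_s[seq_len(n)],
    camera_id = meta("camera"),
    sync_offset = as.integer(meta("sync_offset", "0")),
    image_size = if (is.finite(w)) c(w, h) else NULL
  )
}

#' Write / read a groundline as CSV
#'
#' Columns `frame` (0-based), `angle_deg`, `offset_px`, `valid`.
#'
#' @param gl A [groundline].
#' @param path File path.
#' @return `write_groundline` returns `path` invisibly; `read_groundline`
#'   returns a [groundline].
#' @export
write_groundline <- function(gl, path) {
  stopifnot(inherits(gl, "groundline"))
  df <- data.frame(frame = seq_len(gl$n) - 1L, angle_deg = gl$angle,
                   offset_px = gl$offset, valid = as.integer(gl$valid))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_groundline
#' @export
read_groundline <- function(path) {
  df <- utils::read.csv(path)
  new_groundline(df$angle_deg, df$offset_px, df$valid > 0)
}

#' Read an experiment configuration from YAML or JSON
#'
#' The file may specify `horses` (an integer cohort size or a list of
#' [gait_params()] fields), `cameras` (a list of [camera_model()] fields;
#' omitted means the default seven-camera rig), `handheld_pair`, `seed`,
#' cohort-level `duration`, `noise_sigma` and `occlusion_rate`, and any
#' [gait_options()] fields under `options`.
#'
#' @param path A `.yaml`/`.yml` or `.json` file.
#' @return An [experiment_config()].
#' @export
read_experiment_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  seed <- as.integer(raw$seed %||% 1L)
  horses <- raw$horses %||% 8
  if (is.list(horses)) {
    horses <- lapply(horses, function(h) do.call(gait_params, h))
  } else {
    horses <- make_horses(as.integer(horses),
                          duration = raw$duration %||% 40,
                          noise_sigma = raw$noise_sigma %||% 1,
                          occlusion_rate = raw$occlusion_rate %||% 0,
                          seed = seed)
  }
  cameras <- if (is.null(raw$cameras)) default_cameras()
             else lapply(raw$cameras, function(cm) do.call(camera_model, cm))
  opts <- if (is.null(raw$options)) gait_options()
          else do.call(gait_options, raw$options)
  hp <- raw$handheld_pair
  if (!is.null(hp)) hp <- as.character(hp)
  experiment_config(horses = horses, cameras = cameras,
                    handheld_pair = hp, seed = seed, options = opts)
}

#' Simulate a session to disk
#'
#' Writes, for every horse and camera, the corrupted keypoint trajectories
#' (`<horse>_<camera>.csv`), the reference groundline from the camera
#' geometry (`<horse>_<camera>_groundline.csv`), and per horse a ground
#' truth sidecar (`<horse>_truth.json`) holding the gait parameters, the
#' camera descriptions and the closed-form per-stride Maxdiff/Mindiff (raw
#' and filter-adjusted). Deterministic under the configuration seed.
#'
#' @param config An [experiment_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
run_simulation <- function(config, outdir) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(outdir, 2) != 0)
    stop(sprintf("output directory '%s' is not writable", outdir), call. = FALSE)
  files <- character(0)
  for (hi in seq_along(config$horses)) {
    hname <- names(config$horses)[hi]
    p <- config$horses[[hi]]
    world <- simulate_gait(p)
    for (ci in seq_along(config$cameras)) {
      cam <- config$cameras[[ci]]
      traj <- corrupt_trajectories(
        project_keypoints(world, cam), p$noise_sigma, p$occlusion_rate,
        seed = recording_seed(config$seed, hi, ci))
      f1 <- file.path(outdir, sprintf("%s_%s.csv", hname, cam$id))
      write_trajectories(traj, f1)
      f2 <- file.path(outdir, sprintf("%s_%s_groundline.csv", hname, cam$id))
      write_groundline(true_groundline(world, cam), f2)
      files <- c(files, f1, f2)
    }
    cutoff <- 0.95 * p$stride_frequency
    truth <- list(
      params = unclass(p),
      cameras = lapply(config$cameras, unclass),
      symmetry_truth = lapply(
        stats::setNames(nm = c("eye", "withers", "croup")),
        function(kp) list(
          raw = oracle_symmetry(p, kp)[c("maxdiff", "mindiff")],
          filtered = oracle_symmetry(p, kp, cutoff = cutoff)[c("maxdiff", "mindiff")]
        ))
    )
    f3 <- file.path(outdir, sprintf("%s_truth.json", hname))
    jsonlite::write_json(truth, f3, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <- c(files, f3)
  }
  invisible(files)
}

#' Analyse a simulated session directory
#'
#' Reads every trajectory CSV written by [run_simulation()], runs the
#' measurement pipeline per recording, and writes per-recording stride and
#' trial tables plus a session report (`report.json`).
#'
#' @param indir Directory produced by [run_simulation()].
#' @param outdir Where to write tables and the report (default `indir`).
#' @param groundline `"dynamic"` or `"fixed"` (the latter uses the stored
#'   reference groundline files).
#' @param options [gait_options()].
#' @param verbose Log per-stage counts.
#' @return The report, invisibly: a data.frame with one row per recording
#'   and keypoint.
#' @export
run_analysis <- function(indir, outdir = indir,
                         groundline = c("dynamic", "fixed"),
                         options = gait_options(), verbose = FALSE) {
  groundline <- match.arg(groundline)
  truth_files <- list.files(indir, "_truth\\.json$", full.names = TRUE)
  if (length(truth_files) == 0L)
    stop(sprintf("no '<horse>_truth.json' files found in '%s'; run the simulation first",
                 indir), call. = FALSE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (tf in truth_files) {
    hname <- sub("_truth\\.json$", "", basename(tf))
    truth <- jsonlite::read_json(tf, simplifyVector = TRUE)
    wh <- truth$params$withers_height
    traj_files <- list.files(indir, sprintf("^%s_cam[0-9]+\\.csv$", hname),
                             full.names = TRUE)
    missing <- length(traj_files) == 0L
    if (missing)
      stop(sprintf("no trajectory CSVs found for horse '%s' in '%s'",
                   hname, indir), call. = FALSE)
    for (f in traj_files) {
      traj <- read_trajectories(f)
      ref <- NULL
      if (groundline == "fixed") {
        glf <- sub("\\.csv$", "_groundline.csv", f)
        if (!file.exists(glf))
          stop(sprintf("missing reference groundline file '%s'", glf),
               call. = FALSE)
        ref <- read_groundline(glf)
      }
      an <- analyze_trajectories(traj, wh, groundline, ref_groundline = ref,
                                 options = options)
      base <- sub("\\.csv$", "", basename(f))
      for (kp in names(an$keypoints)) {
        st <- an$keypoints[[kp]]$strides
        utils::write.csv(st, file.path(outdir, sprintf("%s_%s_strides.csv", base, kp)),
                         row.names = FALSE, quote = FALSE)
        utils::write.csv(an$keypoints[[kp]]$trials,
                         file.path(outdir, sprintf("%s_%s_trials.csv", base, kp)),
                         row.names = FALSE, quote = FALSE)
        v <- st[st$valid, ]
        rows[[length(rows) + 1L]] <- data.frame(
          horse = hname, camera = traj$camera_id, keypoint = kp,
          groundline = groundline, f_est = an$f_est,
          n_strides = nrow(v),
          maxdiff_mean = if (nrow(v)) mean(v$maxdiff) else NA_real_,
          mindiff_mean = if (nrow(v)) mean(v$mindiff) else NA_real_,
          detected = an$counts$detected[an$counts$keypoint == kp],
          excluded = an$counts$excluded[an$counts$keypoint == kp],
          theoretical = an$counts$theoretical[an$counts$keypoint == kp]
        )
      }
      if (verbose)
        message(sprintf("%s: %d frames, %d stance events, f = %.3f Hz",
                        base, nrow(traj$x), nrow(an$stances), an$f_est))
    }
  }
  report <- do.call(rbind, rows)
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(report)
}

#' Compare two session reports metric by metric
#'
#' Joins two [run_analysis()] reports on horse, camera and keypoint and
#' tabulates the differences of the stride metrics, carrying the stride
#' count of every compared cell.
#'
#' @param a,b Reports (data.frames) or paths to `report.json` files.
#' @return A data.frame with per-cell differences `d_maxdiff`, `d_mindiff`,
#'   `d_f_est` and the sample sizes of both sides.
#' @export
compare_reports <- function(a, b) {
  load_report <- function(x) {
    if (is.character(x)) x <- jsonlite::read_json(x, simplifyVector = TRUE)
    as.data.frame(x)
  }
  a <- load_report(a); b <- load_report(b)
  need <- c("horse", "camera", "keypoint", "f_est", "n_strides",
            "maxdiff_mean", "mindiff_mean")
  for (nm in list(c("a", need[!need %in% names(a)]),
                  c("b", need[!need %in% names(b)]))) {
    if (length(nm) > 1L)
      stop(sprintf("report '%s' is missing column(s): %s", nm[1],
                   paste(nm[-1], collapse = ", ")), call. = FALSE)
  }
  m <- merge(a[need], b[need], by = c("horse", "camera", "keypoint"),
             suffixes = c("_a", "_b"))
  data.frame(
    horse = m$horse, camera = m$camera, keypoint = m$keypoint,
    n_a = m$n_strides_a, n_b = m$n_strides_b,
    d_f_est = m$f_est_a - m$f_est_b,
    d_maxdiff = m$maxdiff_mean_a - m$maxdiff_mean_b,
    d_mindiff = m$mindiff_mean_a - m$mindiff_mean_b
  )
}
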