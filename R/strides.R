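# Stride segmentation and the Maxdiff / Mindiff symmetry metrics.

# Well-separated prominent local extrema of v: local maxima (or minima)
# above (below) the mid-range level, merged when closer than min_sep frames.
# Endpoints count as candidates (a window boundary can fall exactly on an
# extremum of the trunk oscillation); when both endpoints qualify they are
# identified cyclically and counted once.
prominent_extrema <- function(v, min_sep, what = c("max", "min")) {
  what <- match.arg(what)
  if (what == "min") v <- -v
  n <- length(v)
  if (n < 3L) return(integer(0))
  idx <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
  level <- min(v) + 0.7 * (max(v) - min(v))
  idx <- idx[v[idx] > level]
  # endpoints qualify only when the boundary sits essentially on an extremum
  edge_level <- min(v) + 0.9 * (max(v) - min(v))
  if (v[1] > v[2] && v[1] > edge_level) idx <- c(1L, idx)
  if (v[n] > v[n - 1] && v[n] > edge_level) idx <- c(idx, n)
  if (length(idx) > 1L && idx[1] == 1L && idx[length(idx)] == n)
    idx <- idx[-length(idx)]
  if (length(idx) <= 1L) return(idx)
  # merge clusters closer than min_sep, keeping the highest
  keep <- integer(0)
  cur <- idx[1]
  for (i in idx[-1]) {
    if (i - cur < min_sep) {
      if (v[i] > v[cur]) cur <- i
    } else {
      keep <- c(keep, cur)
      cur <- i
    }
  }
  c(keep, cur)
}

count_prominent_extrema <- function(v, min_sep, what = c("max", "min")) {
  length(prominent_extrema(v, min_sep, what))
}

# Project detected stance onsets onto a regular grid: robust line fit of
# onset frame against stride index (indices assigned by rounding, so missed
# stances leave holes instead of shearing the grid). Individual onsets
# jitter by a few frames under keypoint noise; on a treadmill the stride
# period is stable, so the fitted grid is the better boundary estimate.
regular_onsets <- function(onsets) {
  if (length(onsets) < 3L) return(onsets)
  T0 <- stats::median(diff(onsets))
  if (!is.finite(T0) || T0 <= 0) return(onsets)
  i <- round((onsets - onsets[1]) / T0)
  if (anyDuplicated(i)) return(onsets)
  fit <- l1_line_fit(i, onsets)
  if (is.null(fit) || fit["b"] <= 0) return(onsets)
  ii <- seq(min(i), max(i))
  as.integer(round(fit["c"] + fit["b"] * ii))
}

# Refine provisional stride boundaries (stance onsets) against the expected
# maxima/minima pattern of the VDS. At trot the four trunk extrema repeat
# every T/4; a stride boundary must sit in the maximum-to-minimum gap so
# that each stride half holds exactly one diagonal's maximum and minimum.
# Stance-onset detection is late by a couple of frames (the hoof decelerates
# into the ground), which can park boundaries right on a minimum; this shift
# re-centers them. The correction is bounded to +/- T/4, so the left/right
# identity fixed by the reference forelimb is preserved.
boundary_shift <- function(trace, onsets, T_frames) {
  min_sep <- max(3L, round(T_frames / 4))
  mx <- prominent_extrema(trace, min_sep, "max")
  mn <- prominent_extrema(trace, min_sep, "min")
  if (length(mx) < 2L || length(mn) < 2L) return(0L)
  half <- T_frames / 2
  # phase of each extremum relative to its preceding stance onset (measuring
  # from actual onsets keeps phases aligned even when the true period is not
  # an integer frame count), folded over the half-stride period
  circ_phase <- function(idx) {
    pos <- findInterval(idx, onsets)
    keep <- pos >= 1L
    p <- (idx[keep] - onsets[pos[keep]])
    keep2 <- p < 1.5 * T_frames
    th <- 2 * pi * (p[keep2] %% half) / half
    if (length(th) == 0L) return(NA_real_)
    (atan2(mean(sin(th)), mean(cos(th))) / (2 * pi)) %% 1 * half
  }
  phi_min <- circ_phase(mn)
  phi_max <- circ_phase(mx)
  if (is.na(phi_min) || is.na(phi_max)) return(0L)
  gap <- (phi_min - phi_max) %% half
  target <- (phi_min - gap / 2) %% half
  delta <- target
  if (delta > half / 2) delta <- delta - half  # wrap into (-T/4, T/4]
  as.integer(round(delta))
}

# Sub-frame extremum refinement: least-squares parabola over +/- halfwin
# samples around the discrete extremum; falls back to the sample value when
# the fit is not concave/convex the right way.
refine_extremum <- function(values, idx, halfwin = 3L, what = c("max", "min")) {
  what <- match.arg(what)
  n <- length(values)
  lo <- max(1L, idx - halfwin)
  hi <- min(n, idx + halfwin)
  xs <- lo:hi
  ys <- values[xs]
  ok <- !is.na(ys)
  if (sum(ok) < 3L) return(values[idx])
  co <- stats::lm.fit(cbind(1, xs[ok] - idx, (xs[ok] - idx)^2), ys[ok])$coefficients
  a2 <- co[3]
  concave_ok <- if (what == "max") a2 < 0 else a2 > 0
  if (!is.finite(a2) || !concave_ok) return(values[idx])
  vertex <- co[1] - co[2]^2 / (4 * a2)
  unname(vertex)
}

#' Maxdiff and Mindiff of one stride
#'
#' Within one stride (a half-open frame interval delimited by successive
#' reference-forelimb stance onsets) the trunk VDS has two local maxima and
#' two local minima, one per diagonal half-cycle. Maxdiff is the
#' left-associated maximum minus the right-associated maximum; Mindiff
#' likewise for the minima. Extrema are located per stride half (first half =
#' left diagonal of the reference forelimb) and refined to sub-frame
#' precision by a local least-squares parabola.
#'
#' A stride whose VDS does not show exactly two prominent maxima and two
#' prominent minima (e.g. a noise spike adding a third peak) is refused.
#'
#' @param vds A filtered `vds`.
#' @param start,end Half-open frame interval `[start, end)` of the stride.
#' @param swap_sides If `TRUE`, the left/right association is exchanged;
#'   both metrics change sign exactly.
#' @param halfwin Half-width (frames) of the parabolic refinement window.
#' @return List with `maxdiff`, `mindiff` (signal units) and the four
#'   extremum values `left_max`, `right_max`, `left_min`, `right_min`.
#' @export
compute_symmetry <- function(vds, start, end, swap_sides = FALSE,
                             halfwin = 3L) {
  stopifnot(inherits(vds, "vds"))
  if (end <= start) stop("'end' must exceed 'start'", call. = FALSE)
  trace <- vds$peaks %||% vds$values
  fr <- start:(end - 1L)
  v <- trace[fr]
  if (anyNA(v))
    stop("stride contains hidden keypoint frames; refusing to compute symmetry",
         call. = FALSE)
  min_sep <- max(3L, round(length(fr) / 4))
  if (count_prominent_extrema(v, min_sep, "max") != 2L ||
      count_prominent_extrema(v, min_sep, "min") != 2L)
    stop("stride is malformed: expected exactly two prominent maxima and two prominent minima",
         call. = FALSE)
  mid <- start + (end - start) / 2
  first <- fr[fr < mid]
  second <- fr[fr >= mid]
  ext <- function(idxs, what) {
    i <- if (what == "max") idxs[which.max(trace[idxs])]
         else idxs[which.min(trace[idxs])]
    refine_extremum(trace, i, halfwin, what)
  }
  lmax <- ext(first, "max"); rmax <- ext(second, "max")
  lmin <- ext(first, "min"); rmin <- ext(second, "min")
  if (swap_sides) {
    tmp <- lmax; lmax <- rmax; rmax <- tmp
    tmp <- lmin; lmin <- rmin; rmin <- tmp
  }
  list(maxdiff = lmax - rmax, mindiff = lmin - rmin,
       left_max = lmax, right_max = rmax, left_min = lmin, right_min = rmin)
}

#' Segment a filtered VDS into strides and compute symmetry metrics
#'
#' Stride boundaries are successive stance onsets of a fixed reference
#' forelimb. A stride is excluded (kept in the table, flagged invalid) when
#' it touches the filter warm-up span, has an irregular duration, contains
#' any frame with the target keypoint hidden, or does not show the expected
#' two-maxima / two-minima shape. Valid strides get Maxdiff and Mindiff from
#' [compute_symmetry()].
#'
#' @param traj The `trajectory_set` (provides keypoint visibility).
#' @param stances Stance events from [detect_stance()].
#' @param vds The filtered, calibrated `vds` of the target keypoint.
#' @param ref_leg Reference forelimb stance keypoint (`"hoof_lf"` or
#'   `"hoof_rf"`).
#' @param swap_sides Exchange the left/right labels (negates both metrics).
#' @return A data.frame of class `stride_table`: one row per stride with
#'   `start`, `end` (half-open), duration, the four extrema, `maxdiff`,
#'   `mindiff` (signal units), `valid` and the exclusion `reason`.
#' @export
segment_strides <- function(traj, stances, vds, ref_leg = "hoof_lf",
                            swap_sides = FALSE) {
  stopifnot(inherits(traj, "trajectory_set"), inherits(vds, "vds"))
  leg <- sub("hoof_", "", ref_leg)
  onsets <- sort(stances$start[stances$leg == leg])
  empty <- data.frame(stride = integer(), start = integer(), end = integer(),
                      keypoint = character(), dur_frames = integer(),
                      left_max = numeric(), right_max = numeric(),
                      left_min = numeric(), right_min = numeric(),
                      maxdiff = numeric(), mindiff = numeric(),
                      valid = logical(), reason = character())
  class(empty) <- c("stride_table", "data.frame")
  if (length(onsets) < 2L) return(empty)
  # regularize onsets, then re-anchor boundaries against the expected
  # extrema pattern of the VDS
  onsets <- regular_onsets(onsets)
  trace <- fill_gaps(vds$peaks %||% vds$values)
  T_frames <- stats::median(diff(onsets))
  onsets <- onsets + boundary_shift(trace, onsets, T_frames)
  n_frames <- length(vds$values)
  onsets <- onsets[onsets >= 1L & onsets <= n_frames]
  if (length(onsets) < 2L) return(empty)
  starts <- onsets[-length(onsets)]
  ends <- onsets[-1]
  durs <- ends - starts
  med_dur <- stats::median(durs)
  rows <- vector("list", length(starts))
  vis <- traj$visible[, vds$keypoint]
  for (i in seq_along(starts)) {
    s <- starts[i]; e <- ends[i]
    fr <- s:(e - 1L)
    reason <- ""
    sym <- list(maxdiff = NA_real_, mindiff = NA_real_, left_max = NA_real_,
                right_max = NA_real_, left_min = NA_real_, right_min = NA_real_)
    if (any(vds$warmup[fr])) {
      reason <- "warmup"
    } else if (durs[i] < 0.6 * med_dur || durs[i] > 1.4 * med_dur) {
      reason <- "irregular"
    } else if (any(!vis[fr])) {
      reason <- "occluded"
    } else {
      sym <- tryCatch(compute_symmetry(vds, s, e, swap_sides = swap_sides),
                      error = function(e) NULL)
      if (is.null(sym)) {
        reason <- "malformed"
        sym <- list(maxdiff = NA_real_, mindiff = NA_real_,
                    left_max = NA_real_, right_max = NA_real_,
                    left_min = NA_real_, right_min = NA_real_)
      }
    }
    rows[[i]] <- data.frame(
      stride = i, start = s, end = e, keypoint = vds$keypoint,
      dur_frames = durs[i], left_max = sym$left_max,
      right_max = sym$right_max, left_min = sym$left_min,
      right_min = sym$right_min, maxdiff = sym$maxdiff,
      mindiff = sym$mindiff, valid = reason == "", reason = reason
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("stride_table", "data.frame")
  out
}

#' @export
print.stride_table <- function(x, ...) {
  cat(sprintf("Stride table (%s): %d strides, %d valid\n",
              if (nrow(x)) x$keypoint[1] else "?", nrow(x), sum(x$valid)))
  if (any(x$valid)) {
    v <- x[x$valid, ]
    cat(sprintf("  Maxdiff: mean %.2f, SD %.2f\n",
                mean(v$maxdiff), stats::sd(v$maxdiff)))
    cat(sprintf("  Mindiff: mean %.2f, SD %.2f\n",
                mean(v$mindiff), stats::sd(v$mindiff)))
  }
  if (any(!x$valid)) {
    tb <- table(x$reason[!x$valid])
    cat("  excluded:", paste(sprintf("%s (%d)", names(tb), tb), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Aggregate strides into trial-like segments
#'
#' Partitions the chronological valid strides into contiguous segments of
#' `target_len` strides (a final remainder is kept as an extra trial if it
#' holds at least half a trial). Trial metrics are the arithmetic means of
#' the member strides' Maxdiff and Mindiff.
#'
#' @param strides A `stride_table`.
#' @param target_len Strides per trial.
#' @return A data.frame with one row per trial: `trial`, `n_strides`,
#'   `maxdiff`, `mindiff`, `start`, `end`.
#' @export
split_trials <- function(strides, target_len = 17L) {
  if (target_len < 2L) stop("'target_len' must be at least 2", call. = FALSE)
  v <- strides[strides$valid, ]
  n <- nrow(v)
  out <- data.frame(trial = integer(), n_strides = integer(),
                    maxdiff = numeric(), mindiff = numeric(),
                    start = integer(), end = integer())
  if (n == 0L) return(out)
  n_full <- n %/% target_len
  rem <- n - n_full * target_len
  sizes <- rep(target_len, n_full)
  if (rem >= target_len / 2) sizes <- c(sizes, rem)
  if (length(sizes) == 0L) return(out)
  stop_at <- cumsum(sizes)
  start_at <- stop_at - sizes + 1L
  for (k in seq_along(sizes)) {
    blk <- v[start_at[k]:stop_at[k], ]
    out <- rbind(out, data.frame(
      trial = k, n_strides = nrow(blk), maxdiff = mean(blk$maxdiff),
      mindiff = mean(blk$mindiff), start = blk$start[1],
      end = blk$end[nrow(blk)]
    ))
  }
  out
}
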