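#' Vertical displacement signal (VDS) of a keypoint
#'
#' Per-frame perpendicular distance from a keypoint to the groundline of that
#' frame, positive above the line. Frames in which the keypoint is hidden
#' become `NA` gaps and are propagated, never silently imputed.
#'
#' @param traj A `trajectory_set`.
#' @param gl A [groundline] with one line per frame (dynamic) or constant
#'   parameters (fixed).
#' @param keypoint Keypoint name, e.g. `"withers"`.
#' @return An object of class `vds` holding the raw pixel series; convert to
#'   millimetres with [calibrate_vds()] and filter with [highpass_vds()].
#' @export
compute_vds <- function(traj, gl, keypoint) {
  stopifnot(inherits(traj, "trajectory_set"), inherits(gl, "groundline"))
  if (!keypoint %in% traj$keypoints)
    stop(sprintf("keypoint '%s' is not in the trajectory schema (%s)",
                 keypoint, paste(traj$keypoints, collapse = ", ")),
         call. = FALSE)
  if (gl$n != nrow(traj$x))
    stop("groundline and trajectory frame counts differ", call. = FALSE)
  d <- point_line_distance(traj$x[, keypoint], traj$y[, keypoint], gl)
  vis <- traj$visible[, keypoint]
  d[!vis] <- NA_real_
  structure(list(values = d, values_px = d, visible = vis, fps = traj$fps,
                 keypoint = keypoint, scale = NA_real_, f_est = NA_real_,
                 cutoff = NA_real_, filtered = FALSE,
                 warmup = rep(FALSE, length(d)), unit = "px"),
            class = "vds")
}

# signed perpendicular distance (positive above the line, i.e. smaller image y)
point_line_distance <- function(x, y, gl) {
  ln <- gl_line(gl)
  (ln$b * x - y + ln$c) / sqrt(1 + ln$b^2)
}

#' @export
print.vds <- function(x, ...) {
  cat(sprintf("VDS (%s): %d frames at %g fps, unit %s%s\n", x$keypoint,
              length(x$values), x$fps, x$unit,
              if (x$filtered) sprintf(", high-passed at %.3g Hz", x$cutoff) else ""))
  if (!is.na(x$scale))
    cat(sprintf("  calibration scale: %.4g mm/px\n", x$scale))
  v <- x$values[!is.na(x$values)]
  cat(sprintf("  range %.1f to %.1f, %d gap frames\n",
              min(v), max(v), sum(is.na(x$values))))
  invisible(x)
}

#' @export
plot.vds <- function(x, ...) {
  t <- (seq_along(x$values) - 1L) / x$fps
  graphics::plot(t, x$values, type = "l", xlab = "time (s)",
                 ylab = sprintf("VDS %s (%s)", x$keypoint, x$unit), ...)
  if (any(x$warmup)) {
    w <- range(t[x$warmup & t < max(t) / 2])
    graphics::rect(w[1], graphics::par("usr")[3], w[2],
                   graphics::par("usr")[4], col = grDevices::adjustcolor("grey", 0.3),
                   border = NA)
    w <- range(t[x$warmup & t > max(t) / 2])
    graphics::rect(w[1], graphics::par("usr")[3], w[2],
                   graphics::par("usr")[4], col = grDevices::adjustcolor("grey", 0.3),
                   border = NA)
  }
  invisible(x)
}

#' Calibrate a pixel VDS to millimetres via the withers height
#'
#' The pixel-to-millimetre scale is the known withers height divided by the
#' median perpendicular withers-to-groundline distance over visible frames
#' (the median is robust to the oscillation extremes). The scale is recorded
#' on the returned series, making calibrated VDS invariant to camera zoom.
#'
#' @param vds A `vds` in pixels from [compute_vds()].
#' @param traj The `trajectory_set` the VDS came from (provides the withers).
#' @param gl The [groundline] used for the VDS.
#' @param withers_height Withers height in cm.
#' @param min_coverage Minimum fraction of frames with a visible withers.
#' @return The `vds` converted to mm, with `scale` (mm/px) recorded.
#' @export
calibrate_vds <- function(vds, traj, gl, withers_height, min_coverage = 0.5) {
  stopifnot(inherits(vds, "vds"))
  check_number(withers_height, "withers_height", lower = 0, strict_lower = TRUE)
  wvis <- traj$visible[, "withers"]
  coverage <- mean(wvis)
  if (coverage < min_coverage)
    stop(sprintf("withers visible in only %.1f%% of frames (need >= %.0f%%); cannot calibrate",
                 100 * coverage, 100 * min_coverage), call. = FALSE)
  wd <- point_line_distance(traj$x[, "withers"], traj$y[, "withers"], gl)
  med <- stats::median(wd[wvis])
  if (!is.finite(med) || med <= 0)
    stop("withers-to-groundline distance is degenerate; cannot calibrate",
         call. = FALSE)
  scale <- withers_height * 10 / med
  vds$values <- vds$values_px * scale
  vds$scale <- scale
  vds$unit <- "mm"
  vds
}

#' Estimate the stride frequency from a limb-derived signal
#'
#' Periodogram peak search on a mean-removed, Hann-windowed copy of the
#' signal within the search band. At trot the trunk oscillates at twice the
#' stride frequency, so a candidate peak is validated by requiring
#' periodogram support at its second harmonic; among supported candidates the
#' most powerful wins. If no candidate has harmonic support (e.g. a pure
#' tone) the strongest band peak is returned. A signal with no peak above the
#' noise floor is an error, not a number.
#'
#' @param x Numeric signal (a hoof trajectory works well); `NA` gaps are
#'   bridged linearly.
#' @param fps Sampling rate, Hz.
#' @param band Search band in Hz.
#' @param min_peak Required ratio of the peak to the median periodogram power.
#' @return Estimated stride frequency in Hz.
#' @export
estimate_stride_frequency <- function(x, fps, band = c(0.5, 2.5),
                                      min_peak = 10) {
  x <- fill_gaps(as.numeric(x))
  n <- length(x)
  if (n < 5 * fps)
    stop("need at least 5 s of signal to estimate the stride frequency",
         call. = FALSE)
  x <- x - mean(x)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))  # Hann
  xw <- x * w
  nfft <- 2^ceiling(log2(8 * n))
  p <- Mod(stats::fft(c(xw, rep(0, nfft - n))))^2
  freq <- (seq_len(nfft) - 1L) * fps / nfft
  half <- freq <= fps / 2
  p <- p[half]; freq <- freq[half]
  noise <- stats::median(p[freq > 0.1])
  inband <- which(freq >= band[1] & freq <= band[2])
  if (length(inband) < 3L)
    stop("search band contains too few frequency bins", call. = FALSE)
  # local maxima in band above the noise floor
  pb <- p[inband]
  loc <- which(diff(sign(diff(pb))) == -2) + 1L
  loc <- loc[pb[loc] > min_peak * noise]
  if (length(loc) == 0L)
    stop("no periodogram peak above the noise floor in the search band",
         call. = FALSE)
  cand <- freq[inband][loc]
  pow <- pb[loc]
  ord <- order(pow, decreasing = TRUE)
  cand <- cand[ord]; pow <- pow[ord]
  supported <- vapply(cand, function(f0) {
    sup <- p[freq >= 1.9 * f0 & freq <= 2.1 * f0]
    length(sup) > 0 && max(sup) > 5 * noise
  }, logical(1))
  if (any(supported)) cand[which(supported)[1]] else cand[1]
}

#' Zero-phase Butterworth high-pass filtering of a VDS
#'
#' Applies a 3rd-order Butterworth high-pass with cutoff 5% below the
#' estimated trot (stride) frequency, forward and backward so the net phase
#' shift is zero and stride extrema keep their timing. The amplitude
#' response is applied twice (gain at the cutoff is 1/2). `NA` gaps are
#' bridged by linear interpolation before filtering and re-masked after; the
#' series is reflect-padded so edge transients stay negligible, and the
#' first and last `warmup_factor / cutoff` seconds are flagged as warm-up
#' (stride extraction skips them).
#'
#' Alongside the high-passed series, a low-passed copy (`peaks`, cutoff
#' `peak_lp_factor * f_est`) is stored for extremum reading: the trot signal
#' is band-limited to the first two stride harmonics, so suppressing
#' detector noise above ~3f sharpens the per-stride extrema, while the mild
#' attenuation of the second harmonic cancels exactly in the max-max and
#' min-min differences that Maxdiff/Mindiff take.
#'
#' @param vds A `vds` (typically calibrated).
#' @param f_est Estimated stride frequency, Hz.
#' @param cutoff_factor Cutoff as a fraction of `f_est`.
#' @param order Filter order.
#' @param warmup_factor Warm-up span per edge, in units of 1/cutoff seconds.
#' @param peak_lp_factor Cutoff of the extremum-reading low-pass, as a
#'   multiple of `f_est`; `0` disables the peak trace.
#' @return The filtered `vds` with `f_est`, `cutoff`, `warmup` and `peaks`
#'   recorded.
#' @export
highpass_vds <- function(vds, f_est, cutoff_factor = 0.95, order = 3,
                         warmup_factor = 1, peak_lp_factor = 3) {
  stopifnot(inherits(vds, "vds"))
  check_number(f_est, "f_est", lower = 0, strict_lower = TRUE)
  cutoff <- cutoff_factor * f_est
  if (cutoff >= vds$fps / 2)
    stop(sprintf("cutoff %.3g Hz is at or above the Nyquist frequency %.3g Hz",
                 cutoff, vds$fps / 2), call. = FALSE)
  imputed <- fill_gaps_harmonic(vds$values, vds$fps, f_est)
  filtered <- butter_highpass(imputed, vds$fps, cutoff, order)
  filtered[is.na(vds$values)] <- NA_real_
  vds$values <- filtered
  vds$f_est <- f_est
  vds$cutoff <- cutoff
  vds$filtered <- TRUE
  n <- length(filtered)
  wu <- min(n, ceiling(warmup_factor / cutoff * vds$fps))
  vds$warmup <- seq_len(n) <= wu | seq_len(n) > n - wu
  lp_cut <- peak_lp_factor * f_est
  if (peak_lp_factor > 0 && lp_cut < vds$fps / 2) {
    pk <- butter_lowpass(vds$values, vds$fps, lp_cut, order)
    pk[is.na(vds$values)] <- NA_real_
    vds$peaks <- pk
  }
  vds
}

# forward-backward Butterworth low-pass with odd reflective padding
butter_lowpass <- function(x, fps, cutoff, order = 3) {
  x <- fill_gaps_spline(x)
  n <- length(x)
  bf <- signal::butter(order, cutoff / (fps / 2), type = "low")
  np <- min(n - 1L, round(3 / cutoff * fps))
  left <- 2 * x[1] - x[(np + 1L):2]
  right <- 2 * x[n] - x[(n - 1L):(n - np)]
  y <- signal::filtfilt(bf, c(left, x, right))
  y[(np + 1L):(np + n)]
}

# Bridge NA gaps with a natural cubic spline: VDS gaps sit in a smooth,
# band-limited oscillation whose curvature makes linear interpolation err
# by millimetres, which the IIR filter would ring into neighbouring
# strides.
fill_gaps_spline <- function(x) {
  if (!anyNA(x)) return(x)
  idx <- which(!is.na(x))
  if (length(idx) < 4L) return(fill_gaps(x))
  out <- stats::spline(idx, x[idx], xout = seq_along(x), method = "natural")$y
  # no extrapolation beyond the first/last observed sample
  out[seq_along(x) < idx[1]] <- x[idx[1]]
  out[seq_along(x) > idx[length(idx)]] <- x[idx[length(idx)]]
  out
}

# Impute NA gaps by local harmonic regression at the known stride
# frequency: the trot VDS is a short Fourier series in f, so a trig fit on
# the surrounding two stride periods reconstructs a gap almost exactly,
# where polynomial interpolation would leave a millimetre-scale error that
# the zero-phase filter rings into neighbouring strides.
fill_gaps_harmonic <- function(x, fps, f, n_harm = 3L) {
  if (!anyNA(x)) return(x)
  ok <- which(!is.na(x))
  if (length(ok) < 4L * n_harm) return(fill_gaps_spline(x))
  t <- (seq_along(x) - 1) / fps
  design <- function(tt) {
    X <- cbind(1, tt)
    for (k in seq_len(n_harm))
      X <- cbind(X, cos(2 * pi * k * f * tt), sin(2 * pi * k * f * tt))
    X
  }
  out <- x
  for (run in split(which(is.na(x)), cumsum(c(1, diff(which(is.na(x)))) != 1))) {
    lo <- max(1, min(run) - ceiling(2 * fps / f))
    hi <- min(length(x), max(run) + ceiling(2 * fps / f))
    near <- intersect(lo:hi, ok)
    if (length(near) < 3L * n_harm + 2L) next
    co <- tryCatch(stats::lm.fit(design(t[near]), x[near])$coefficients,
                   error = function(e) NULL)
    if (is.null(co) || anyNA(co)) next
    out[run] <- design(t[run]) %*% co
  }
  fill_gaps_spline(out)
}

# forward-backward Butterworth high-pass with odd reflective padding; the
# mean is removed first (a no-op through a high-pass) so constant input
# maps to exactly zero
butter_highpass <- function(x, fps, cutoff, order = 3) {
  x <- fill_gaps_spline(x)
  x <- x - mean(x)
  n <- length(x)
  bf <- signal::butter(order, cutoff / (fps / 2), type = "high")
  np <- min(n - 1L, round(3 / cutoff * fps))
  left <- 2 * x[1] - x[(np + 1L):2]
  right <- 2 * x[n] - x[(n - 1L):(n - np)]
  y <- signal::filtfilt(bf, c(left, x, right))
  y[(np + 1L):(np + n)]
}
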