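# Paired-difference agreement statistics (Bland-Altman battery).

#' Match strides across two synchronized recordings
#'
#' After shifting the second recording's frame indices by `sync_offset`,
#' strides are paired greedily by maximal temporal overlap (ties go to the
#' earlier stride); each stride is used at most once and pairs overlapping
#' less than half of the shorter stride are dropped. Only valid strides are
#' considered.
#'
#' @param a,b `stride_table`s from the same session.
#' @param sync_offset Frames to add to `b`'s clock to align it with `a`'s.
#' @return A data.frame with one row per matched pair: indices into the
#'   original tables, the overlap fraction, and the paired `maxdiff` /
#'   `mindiff` values of both recordings.
#' @export
match_strides <- function(a, b, sync_offset = 0L) {
  va <- which(a$valid)
  vb <- which(b$valid)
  empty <- data.frame(a_idx = integer(), b_idx = integer(),
                      overlap = numeric(),
                      maxdiff_a = numeric(), maxdiff_b = numeric(),
                      mindiff_a = numeric(), mindiff_b = numeric())
  if (length(va) == 0L || length(vb) == 0L) return(empty)
  bs <- b$start[vb] + sync_offset
  be <- b$end[vb] + sync_offset
  cand <- list()
  for (i in seq_along(va)) {
    ia <- va[i]
    ov <- pmin(a$end[ia], be) - pmax(a$start[ia], bs)
    shorter <- pmin(a$end[ia] - a$start[ia], be - bs)
    frac <- ov / shorter
    j <- which(frac >= 0.5)
    if (length(j))
      cand[[length(cand) + 1L]] <- data.frame(i = i, j = j, frac = frac[j])
  }
  if (length(cand) == 0L) return(empty)
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand$frac, cand$i, cand$j), ]
  used_a <- logical(length(va))
  used_b <- logical(length(vb))
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    if (!used_a[cand$i[r]] && !used_b[cand$j[r]]) {
      keep[r] <- TRUE
      used_a[cand$i[r]] <- TRUE
      used_b[cand$j[r]] <- TRUE
    }
  }
  cand <- cand[keep, ]
  cand <- cand[order(cand$i), ]
  ia <- va[cand$i]; ib <- vb[cand$j]
  data.frame(a_idx = ia, b_idx = ib, overlap = cand$frac,
             maxdiff_a = a$maxdiff[ia], maxdiff_b = b$maxdiff[ib],
             mindiff_a = a$mindiff[ia], mindiff_b = b$mindiff[ib])
}

#' Agreement statistics for a set of paired differences
#'
#' Computes the descriptive battery for a vector of signed differences
#' (condition A minus condition B): mean signed difference, sample SD,
#' 95% limits of agreement (mean +/- 1.96 SD), mean absolute difference
#' (MAE), and a normal-approximation confidence interval for the MAE
#' (`mae +/- z * sd(|d|) / sqrt(n)`, z = 2.576 at 99%, 1.96 at 95%).
#'
#' @param diffs Numeric vector of signed differences (length >= 2, finite).
#' @param ci_level Confidence level for the MAE interval (0.99 or 0.95).
#' @param labels Optional length-2 character vector naming the conditions.
#' @return An object of class `agreement_stats`.
#' @export
agreement <- function(diffs, ci_level = 0.99, labels = NULL) {
  diffs <- as.numeric(diffs)
  if (length(diffs) < 2L)
    stop("need at least 2 paired differences", call. = FALSE)
  if (any(!is.finite(diffs)))
    stop("paired differences must all be finite", call. = FALSE)
  n <- length(diffs)
  m <- mean(diffs)
  s <- stats::sd(diffs)
  mae <- mean(abs(diffs))
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  half <- z * stats::sd(abs(diffs)) / sqrt(n)
  structure(list(
    n = n, mean_signed = m, sd = s,
    loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
    mae = mae, mae_ci_low = mae - half, mae_ci_high = mae + half,
    ci_level = ci_level, labels = labels
  ), class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, digits = 3, ...) {
  lab <- if (!is.null(x$labels)) sprintf(" (%s - %s)", x$labels[1], x$labels[2]) else ""
  cat(sprintf("Agreement over n = %d paired differences%s\n", x$n, lab))
  cat(sprintf("  mean signed %s, SD %s, 95%% LoA (%s, %s)\n",
              signif(x$mean_signed, digits), signif(x$sd, digits),
              signif(x$loa_low, digits), signif(x$loa_high, digits)))
  cat(sprintf("  MAE %s, %d%% CI (%s, %s)\n",
              signif(x$mae, digits), round(100 * x$ci_level),
              signif(x$mae_ci_low, digits), signif(x$mae_ci_high, digits)))
  invisible(x)
}

as_row.agreement_stats <- function(x) {
  data.frame(n = x$n, mean_signed = x$mean_signed, sd = x$sd,
             loa_low = x$loa_low, loa_high = x$loa_high, mae = x$mae,
             mae_ci_low = x$mae_ci_low, mae_ci_high = x$mae_ci_high)
}

#' Bland-Altman table and statistics
#'
#' For each pair the mean `(a + b) / 2` and the difference `a - b`; returns
#' the table together with [agreement()] on the differences. Pairs whose
#' difference falls outside `plot_range` are reported separately (they would
#' fall outside the plot).
#'
#' @param a_vals,b_vals Equal-length numeric vectors (n >= 2).
#' @param ci_level Confidence level for the MAE interval.
#' @param plot_range Optional length-2 range for the difference axis.
#' @return An object of class `bland_altman`: `table` (means, diffs),
#'   `stats` ([agreement()]), and `outliers`.
#' @export
bland_altman <- function(a_vals, b_vals, ci_level = 0.99, plot_range = NULL) {
  if (length(a_vals) != length(b_vals))
    stop(sprintf("length mismatch: a has %d values, b has %d",
                 length(a_vals), length(b_vals)), call. = FALSE)
  means <- (a_vals + b_vals) / 2
  diffs <- a_vals - b_vals
  out <- integer(0)
  if (!is.null(plot_range))
    out <- which(diffs < plot_range[1] | diffs > plot_range[2])
  structure(list(
    table = data.frame(mean = means, diff = diffs),
    stats = agreement(diffs, ci_level = ci_level),
    outliers = out, plot_range = plot_range
  ), class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat("Bland-Altman analysis\n")
  print(x$stats)
  if (length(x$outliers))
    cat(sprintf("  %d pair(s) outside the plot range\n", length(x$outliers)))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, xlab = "pair mean", ylab = "pair difference",
                              ...) {
  graphics::plot(x$table$mean, x$table$diff, pch = 16,
                 col = grDevices::adjustcolor("black", 0.4),
                 xlab = xlab, ylab = ylab, ...)
  graphics::abline(h = x$stats$mean_signed, col = "blue")
  graphics::abline(h = c(x$stats$loa_low, x$stats$loa_high),
                   col = "red", lty = 2)
  invisible(x)
}
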