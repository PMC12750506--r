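# Internal helpers shared across modules.

# Evaluate expr with a private RNG state; the caller's .Random.seed is
# untouched, so simulator determinism never leaks into user code.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  eval.parent(substitute(expr))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  bad_lo <- if (strict_lower) x <= lower else x < lower
  bad_hi <- if (strict_upper) x >= upper else x > upper
  if (bad_lo || bad_hi)
    stop(sprintf("'%s' = %g is outside the allowed range (%s%g, %g%s)",
                 name, x,
                 if (strict_lower) "" else "[", lower,
                 upper, if (strict_upper) "" else "]"),
         call. = FALSE)
  invisible(x)
}

# Centered moving average that tolerates NA at the edges.
moving_average <- function(x, k) {
  if (k <= 1L) return(x)
  n <- length(x)
  half <- (k - 1L) %/% 2L
  cs <- cumsum(c(0, ifelse(is.na(x), 0, x)))
  cn <- cumsum(c(0, !is.na(x)))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  s <- cs[hi + 1L] - cs[lo]
  m <- cn[hi + 1L] - cn[lo]
  out <- s / m
  out[m == 0] <- NA_real_
  out
}

# Centered rolling maximum (window k, odd); NA-tolerant.
rolling_max <- function(x, k) {
  n <- length(x)
  half <- (k - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    w <- x[max(1L, i - half):min(n, i + half)]
    if (all(is.na(w))) NA_real_ else max(w, na.rm = TRUE)
  }, numeric(1))
}

# Linear interpolation across NA gaps, extending flat at the edges.
fill_gaps <- function(x) {
  if (!anyNA(x)) return(x)
  idx <- which(!is.na(x))
  if (length(idx) == 0L) stop("signal has no finite samples", call. = FALSE)
  if (length(idx) == 1L) return(rep(x[idx], length(x)))
  stats::approx(idx, x[idx], xout = seq_along(x), rule = 2)$y
}

# Runs of TRUE, as a matrix with columns start, end (inclusive indices).
true_runs <- function(flag) {
  flag[is.na(flag)] <- FALSE
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
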