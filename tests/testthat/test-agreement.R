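test_that("agreement statistics match closed-form arithmetic", {
  st <- agreement(c(1, 2, 3, 4, 5), ci_level = 0.99)
  expect_equal(st$n, 5)
  expect_equal(st$mean_signed, 3)
  expect_equal(st$sd, sqrt(2.5), tolerance = 1e-12)
  expect_equal(st$loa_low, 3 - 1.96 * sqrt(2.5), tolerance = 1e-12)
  expect_equal(st$loa_high, 3 + 1.96 * sqrt(2.5), tolerance = 1e-12)
  expect_equal(st$mae, 3)
  alt <- agreement(c(1, -1, 1, -1))
  expect_equal(alt$mean_signed, 0)
  expect_equal(alt$mae, 1)
  zero <- agreement(c(0, 0, 0, 0))
  expect_equal(zero$mean_signed, 0)
  expect_equal(zero$sd, 0)
  expect_equal(zero$mae, 0)
  expect_equal(zero$loa_low, 0)
  expect_error(agreement(1), "at least 2")
  expect_error(agreement(c(1, NA, 3)), "finite")
})

test_that("agreement and Bland-Altman equal brute-force recomputation", {
  set.seed(17)
  for (rep in 1:200) {
    n <- sample(2:60, 1)
    d <- switch(1 + rep %% 3,
                stats::rnorm(n, sd = stats::runif(1, 0.1, 10)),
                stats::rt(n, df = 3),
                stats::runif(n, -5, 5))
    for (lvl in c(0.95, 0.99)) {
      st <- agreement(d, ci_level = lvl)
      m <- sum(d) / n
      sdd <- sqrt(sum((d - m)^2) / (n - 1))
      mae <- sum(abs(d)) / n
      z <- stats::qnorm(1 - (1 - lvl) / 2)
      half <- z * sqrt(sum((abs(d) - mae)^2) / (n - 1)) / sqrt(n)
      expect_equal(st$mean_signed, m, tolerance = 1e-12)
      expect_equal(st$sd, sdd, tolerance = 1e-12)
      expect_equal(st$loa_low, m - 1.96 * sdd, tolerance = 1e-12)
      expect_equal(st$loa_high, m + 1.96 * sdd, tolerance = 1e-12)
      expect_equal(st$mae, mae, tolerance = 1e-12)
      expect_equal(st$mae_ci_low, mae - half, tolerance = 1e-12)
      expect_equal(st$mae_ci_high, mae + half, tolerance = 1e-12)
    }
    a <- stats::rnorm(n)
    ba <- bland_altman(a, a - d)
    expect_equal(ba$table$mean, (a + (a - d)) / 2, tolerance = 1e-12)
    expect_equal(ba$table$diff, d, tolerance = 1e-12)
    expect_equal(ba$stats$mae, sum(abs(d)) / n, tolerance = 1e-12)
  }
})

test_that("95% limits of agreement cover about 95% of normal differences", {
  set.seed(23)
  d <- stats::rnorm(1e4, mean = 0.3, sd = 1.7)
  st <- agreement(d)
  cover <- mean(d >= st$loa_low & d <= st$loa_high)
  expect_gt(cover, 0.94)
  expect_lt(cover, 0.96)
})

test_that("Bland-Altman handles identity, pure bias and outlier reporting", {
  a <- c(10, 11, 12)
  pair <- bland_altman(c(10, 10), c(12, 12))$table[1, ]
  expect_equal(pair$mean, 11)   # mean of a = 10 and b = 12
  expect_equal(pair$diff, -2)   # diff defined a - b
  id <- bland_altman(a, a)
  expect_true(all(id$table$diff == 0))
  expect_equal(id$stats$loa_low, 0)
  expect_equal(id$stats$loa_high, 0)
  bias <- bland_altman(a + 1, a)
  expect_equal(bias$stats$mean_signed, 1)
  expect_equal(bias$stats$sd, 0)
  expect_equal(c(bias$stats$loa_low, bias$stats$loa_high), c(1, 1))
  out <- bland_altman(c(1, 2, 50), c(1.1, 2.2, 3), plot_range = c(-5, 5))
  expect_equal(out$outliers, 3L)
  expect_error(bland_altman(1:3, 1:4), "mismatch")
})

test_that("stride matching pairs by overlap, once each, identity-safe", {
  mk <- function(starts, dur = 24) {
    n <- length(starts)
    data.frame(stride = seq_len(n), start = starts, end = starts + dur,
               keypoint = "withers", dur_frames = dur,
               left_max = 0, right_max = 0, left_min = 0, right_min = 0,
               maxdiff = seq_len(n), mindiff = -seq_len(n),
               valid = TRUE, reason = "")
  }
  a <- mk(seq(1, 24 * 10, by = 24))
  m <- match_strides(a, a)
  expect_equal(nrow(m), 10)
  expect_equal(m$a_idx, m$b_idx)
  expect_true(all(m$overlap == 1))
  # shifting b by one full stride period loses at most a boundary stride
  b <- mk(seq(1, 24 * 10, by = 24) + 24)
  m2 <- match_strides(a, b, sync_offset = -24)
  expect_gte(nrow(m2), 9)
  expect_true(all(abs((a$start[m2$a_idx]) - (b$start[m2$b_idx] - 24)) == 0))
  # disjoint recordings pair nothing
  c0 <- mk(seq(1, 24 * 5, by = 24) + 2000)
  expect_equal(nrow(match_strides(a, c0)), 0)
  # a half-stride offset still matches by majority overlap
  d <- mk(seq(1, 24 * 10, by = 24) + 10)
  m3 <- match_strides(a, d)
  expect_gte(nrow(m3), 9)
  expect_true(all(m3$overlap >= 0.5))
})
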