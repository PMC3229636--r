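test_that("window counting matches hand enumeration", {
  g <- genome_spec("1", 20)
  a <- data.frame(chrom = "1", pos = 1:10)
  b <- a[0, ]
  wc <- count_reads_in_windows(a, b, g, window_length = 10, advance = 5)
  expect_equal(wc$start, c(0, 5, 10))
  expect_equal(wc$x, c(10, 5, 0))
  expect_equal(wc$y, c(0, 0, 0))
})

test_that("empty placements give an all-zero track and partial windows drop", {
  g <- genome_spec("1", 25)
  none <- data.frame(chrom = character(), pos = numeric())
  wc <- count_reads_in_windows(none, none, g, window_length = 10, advance = 5)
  # [0,10) [5,15) [10,20) [15,25); a window starting at 20 would overrun
  expect_equal(nrow(wc), 4)
  expect_true(all(wc$x == 0 & wc$y == 0))
})

test_that("non-overlapping tiling counts each read exactly once", {
  g <- genome_spec("1", 1000)
  set.seed(4)
  a <- data.frame(chrom = "1", pos = sample(1000, 400, replace = TRUE))
  wc <- count_reads_in_windows(a, a[0, ], g, window_length = 100,
                               advance = 100)
  expect_equal(sum(wc$x), nrow(a))
})

test_that("reads beyond chromosome bounds are skipped with a warning", {
  g <- genome_spec("1", 100)
  a <- data.frame(chrom = "1", pos = c(5, 50, 150))
  expect_warning(
    wc <- count_reads_in_windows(a, a[0, ], g, window_length = 50,
                                 advance = 50),
    "skipped")
  expect_equal(sum(wc$x), 2)
  expect_equal(attr(wc, "n_skipped"), 1L)
})

test_that("equal counts with equal totals give log2 0 and p 1", {
  wc <- make_track(x = rep(20, 50), y = rep(20, 50))
  st <- window_ratio_test(wc)
  expect_equal(st$log2_ratio, rep(0, 50))
  expect_equal(st$p_value, rep(1, 50), tolerance = 1e-12)
  expect_false(any(st$significant))
})

test_that("zero-count windows follow the sentinel contract", {
  wc <- make_track(x = c(0, 30, 0), y = c(0, 0, 30))
  st <- window_ratio_test(wc, total_a = 30, total_b = 30)
  expect_true(is.na(st$log2_ratio[1]) && is.na(st$p_value[1]))
  expect_false(st$significant[1])
  expect_identical(st$log2_ratio[2], Inf)
  expect_identical(st$log2_ratio[3], -Inf)
  expect_true(all(st$p_value[2:3] >= 0 & st$p_value[2:3] <= 1))
})

test_that("ratio-test tail probability agrees with Monte-Carlo", {
  # moderate-tail case, where the normal approximation of the transformed
  # ratio should track the simulated distribution of the same statistic
  mu <- 80
  x0 <- 105; y0 <- 75
  wc <- make_track(x = x0, y = y0)
  p_gh <- window_ratio_test(wc, total_a = mu, total_b = mu)$p_value
  t_obs <- abs((mu * (x0 / y0) - mu) / sqrt(mu * (x0 / y0)^2 + mu))
  set.seed(17)
  xs <- rpois(4e5, mu); ys <- rpois(4e5, mu)
  ok <- ys > 0
  t_mc <- (mu * (xs[ok] / ys[ok]) - mu) /
    sqrt(mu * (xs[ok] / ys[ok])^2 + mu)
  p_mc <- mean(abs(t_mc) >= t_obs)
  # the transform is a normal approximation: its tail probability tracks
  # the simulated distribution of the same statistic to within a few
  # percent at moderate tails (its small bias is detectable with enough
  # draws, so the comparison is relative, not within pure MC error)
  expect_lt(abs(p_gh - p_mc) / p_mc, 0.1)
  # deeper tail: agreement within a factor of two is all the normal
  # approximation guarantees, and ordering is preserved
  x1 <- 100; y1 <- 50
  p_gh2 <- window_ratio_test(make_track(x1, y1), total_a = mu,
                             total_b = mu)$p_value
  t_obs2 <- abs((mu * (x1 / y1) - mu) / sqrt(mu * (x1 / y1)^2 + mu))
  p_mc2 <- mean(abs(t_mc) >= t_obs2)
  # at ~1e-4 the MC estimate itself is too noisy for a tight band; require
  # the right order of magnitude and preserved ordering
  expect_lt(abs(log10(p_gh2 / max(p_mc2, 1 / length(t_mc)))), 1)
  expect_lt(p_gh2, p_gh)
})

test_that("null windows are calibrated at the 0.001 threshold", {
  set.seed(23)
  n <- 2e4
  wc <- make_track(x = rpois(n, 40), y = rpois(n, 40))
  st <- window_ratio_test(wc)
  expect_lte(mean(st$p_value <= 0.001, na.rm = TRUE), 0.002)
})

test_that("automatic window sizing is monotone and scales with multiplier", {
  cfg1 <- caller_config(window_multiplier = 1)
  cfg2 <- caller_config(window_multiplier = 2)
  w1 <- auto_window_length(2.5e9, 2e7, 2e7, cfg1)
  w2 <- auto_window_length(2.5e9, 2e7, 2e7, cfg2)
  expect_equal(w2, 2L * w1)
  w_big <- auto_window_length(2.5e9, 4e7, 4e7, cfg2)
  expect_lt(w_big, w2)
  expect_error(auto_window_length(100, 1, 1, cfg2), "feasible")
})

test_that("minimal window sits exactly at the detection boundary", {
  # independent recomputation of the detectability criterion at the
  # returned minimal length and one bp less
  cfg <- caller_config(window_multiplier = 1)
  G <- 1e9; ta <- 1.5e7; tb <- 1.4e7
  w <- auto_window_length(G, ta, tb, cfg)
  crit <- qnorm(1 - cfg$p_threshold / 2)
  t_at <- function(wl, lr) {
    mu_x <- ta * wl / G; mu_y <- tb * wl / G
    z <- 2^lr * ta / tb
    abs((mu_y * z - mu_x) / sqrt(mu_y * z^2 + mu_x))
  }
  both <- function(wl) min(t_at(wl, cfg$log2_threshold),
                           t_at(wl, -cfg$log2_threshold))
  expect_gte(both(w), crit)
  expect_lt(both(w - 1), crit)
})
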