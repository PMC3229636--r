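test_that("delta-Ct arithmetic and censoring policy", {
  expect_equal(delta_ct(c(20, 20, 20, 20), c(20, 20, 20, 20))$dct, 0)
  expect_equal(delta_ct(c(21, 21, 21, 21), c(20, 20, 20, 20))$dct, 1)
  expect_warning(d <- delta_ct(c(21, NA, 21, 21), c(20, 20, 20, 20)),
                 "censored")
  expect_equal(d$dct, 1)
  expect_equal(d$n_used, 3L)
  all_na <- delta_ct(c(NA, NA, NA, NA), c(20, 20, 20, 20))
  expect_identical(all_na$dct, Inf)
})

test_that("copy number follows the 2^(-ddCt) closed form", {
  expect_equal(copy_number(1, 1)$copy_number, 2)
  expect_equal(copy_number(0, 1)$copy_number, 4)   # ddct = -1
  expect_equal(copy_number(2, 1)$copy_number, 1)   # ddct = +1
  expect_equal(copy_number(1, 1, calibrator_cn = 3)$copy_number, 3)
  expect_error(copy_number(1, Inf), "calibration impossible")
})

test_that("zero-noise simulation round-trips exactly, censored gives 0", {
  plan <- qpcr_plan(c(cal = 2, s1 = 1, s2 = 2, s3 = 3, s4 = 4, s5 = 0),
                    ct_noise_sd = 0)
  ct <- simulate_qpcr(plan, seed = 81)
  calls <- call_copy_numbers(ct, "cal")
  expect_equal(calls$copy_number,
               c(2, 1, 2, 3, 4, 0), tolerance = 1e-12)
  expect_equal(calls$rounded_cn, c(2L, 1L, 2L, 3L, 4L, 0L))
  expect_equal(calls$ddct[2], 1)
  expect_equal(calls$ddct[5], -1)
})

test_that("copy number is invariant to a constant Ct shift", {
  plan <- qpcr_plan(c(cal = 2, a = 4, b = 1), ct_noise_sd = 0.05)
  ct <- simulate_qpcr(plan, seed = 82)
  shifted <- ct
  num <- grepl("_ct_rep", names(ct))
  shifted[, num] <- shifted[, num] + 3.7
  c1 <- call_copy_numbers(ct, "cal")
  c2 <- call_copy_numbers(shifted, "cal")
  expect_equal(c1$copy_number, c2$copy_number, tolerance = 1e-10)
})

test_that("noisy quadruplicates recover the planted grid reliably", {
  set.seed(83)
  truth <- rep(1:4, length.out = 18)
  names(truth) <- sprintf("s%02d", 1:18)
  hits <- 0
  plan <- qpcr_plan(c(cal = 2, truth), ct_noise_sd = 0.1, replicates = 4)
  ct <- simulate_qpcr(plan, seed = 84)
  calls <- call_copy_numbers(ct, "cal")
  got <- calls$rounded_cn[match(names(truth), calls$sample)]
  expect_gte(mean(got == truth), 0.95)
})

test_that("mode calibration rescales the modal level to two copies", {
  calls <- data.frame(sample = c("h1", "h2", "h3", "h4"),
                      delta_ct = 0, ddct = 0,
                      copy_number = c(1, 1, 1, 2),
                      rounded_cn = c(1L, 1L, 1L, 2L),
                      cn_min = c(1, 1, 1, 2), cn_max = c(1, 1, 1, 2),
                      stringsAsFactors = FALSE)
  class(calls) <- c("copy_number_calls", "data.frame")
  out <- mode_calibrate(calls)
  expect_equal(out$copy_number, c(2, 2, 2, 4))
  # all equal: everything becomes two copies
  calls2 <- calls; calls2$copy_number <- 3; calls2$rounded_cn <- 3L
  expect_equal(mode_calibrate(calls2)$copy_number, rep(2, 4))
  # tie between modes is an error naming them
  calls3 <- calls
  calls3$rounded_cn <- c(1L, 1L, 2L, 2L)
  expect_error(mode_calibrate(calls3), "1 and 2")
  expect_error(mode_calibrate(calls[1:2, ]), "at least 3")
})

test_that("qPCR plan validation", {
  expect_error(qpcr_plan(c(2, 2)), "named")
  expect_error(qpcr_plan(c(a = -1)), "non-negative")
  expect_error(qpcr_plan(c(a = 2), replicates = 0), "replicate")
  plan <- qpcr_plan(c(a = 2))
  expect_error(simulate_qpcr(plan, efficiency = 0.5), "efficiency")
})

test_that("Ct tables round-trip through TSV", {
  plan <- qpcr_plan(c(cal = 2, s1 = 4), ct_noise_sd = 0.1)
  ct <- simulate_qpcr(plan, seed = 85)
  f <- tempfile(fileext = ".tsv")
  write_ct_table(ct, f)
  back <- read_ct_table(f)
  expect_equal(back, ct, tolerance = 1e-12)
  unlink(f)
})
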