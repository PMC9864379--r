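test_that("dual-delay back-extrapolation follows the log-linear model", {
  # one halving per delay doubling
  be <- back_extrapolate_intensity(100, 50, 5.5, 11)
  expect_equal(be$i0, 200)
  # no decay: return i1 with a warning
  expect_warning(be2 <- back_extrapolate_intensity(80, 80, 5.5, 11),
                 "non-decaying")
  expect_equal(be2$i0, 80)
  expect_equal(be2$t2_apparent_ms, Inf)
  # independently computed log-linear extrapolation
  be3 <- back_extrapolate_intensity(90, 60, 5.5, 11)
  expect_equal(be3$i0, 135)
  expect_equal(be3$t2_apparent_ms, 5.5 / log(1.5), tolerance = 1e-12)

  expect_error(back_extrapolate_intensity(-1, 5, 5.5, 11), "positive")
  expect_error(back_extrapolate_intensity(10, 5, 11, 5.5), "t2 > t1")

  # scale invariance: scaling both volumes by k scales i0 by k
  for (k in c(0.01, 3, 1e4)) {
    expect_equal(back_extrapolate_intensity(90 * k, 60 * k, 5.5, 11)$i0,
                 k * 135, tolerance = 1e-12)
  }
})

test_that("volume correction compensates dilution multiplicatively", {
  expect_equal(volume_correct(10, 350, 350), 10)
  expect_equal(volume_correct(1, 990, 350), 990 / 350, tolerance = 1e-12)
  expect_equal(volume_correct(1, 990, 350), 2.829, tolerance = 1e-3)
  # factor composition
  expect_equal(volume_correct(volume_correct(7, 500, 350), 990, 500),
               volume_correct(7, 990, 350), tolerance = 1e-12)
  expect_error(volume_correct(1, -5, 350), "> 0")
})

test_that("correct_series recovers the generating sigmoid", {
  # noiseless: corrected I/I0 equals the (normalised) generator sigmoid
  tab <- simulate_titration(noise_sd = 0, seed = 1)
  tr <- attr(tab, "truth")
  ser <- one_corrected_series(tab, "C7")
  expect_equal(ser$i_rel, tr$i_rel_true / tr$i_rel_true[1], tolerance = 1e-10)
  expect_identical(ser$i_rel[1], 1)

  # constant folded fraction (m = 0) with a 3x T2 shrink: i_rel stays 1
  flat <- simulate_titration(m = 0, noise_sd = 0, seed = 2, peak_ids = "X",
                             t2_profile = function(vv) 39 - 26 * vv / 88)
  fc <- correct_series(flat)
  expect_equal(fc$i_rel, rep(1, nrow(fc)), tolerance = 1e-10)

  # corrected intensities are invariant to the T2 trajectory
  t_a <- simulate_titration(noise_sd = 0, seed = 3, peak_ids = "P",
                            t2_profile = 25)
  t_b <- simulate_titration(noise_sd = 0, seed = 3, peak_ids = "P",
                            t2_profile = function(vv) 40 - 30 * vv / 100)
  expect_equal(correct_series(t_a)$i_rel, correct_series(t_b)$i_rel,
               tolerance = 1e-10)
})

test_that("correction round trip stays within the injected noise level", {
  # reference-point noise propagates to all points, so the per-seed RMS
  # fluctuates around sqrt(2) x noise SD; the median over seeds must stay
  # below the 1.5x bound
  sd0 <- 0.02
  rms <- vapply(1:20, function(s) {
    tab <- simulate_titration(noise_sd = sd0, seed = 100 + s, peak_ids = "P")
    tr <- attr(tab, "truth")
    ser <- one_corrected_series(tab)
    sqrt(mean((ser$i_rel - tr$i_rel_true / tr$i_rel_true[1])^2))
  }, numeric(1))
  expect_lt(stats::median(rms), 1.5 * sd0)
  expect_true(all(rms < 3 * sd0))
})

test_that("censored and malformed points are handled explicitly", {
  tab <- simulate_titration(noise_sd = 0, seed = 4, peak_ids = "P")
  df <- as.data.frame(tab)
  # vanished peak at the highest DMSO point: flag, keep, exclude value
  df$volume_raw[df$dmso_vv_percent == 88] <- c(-1e-6, 0)
  corr <- correct_series(as_titration_table(df))
  expect_true(corr$censored[corr$dmso_vv_percent == 88])
  expect_true(is.na(corr$i_rel[corr$dmso_vv_percent == 88]))
  expect_false(any(corr$censored[corr$dmso_vv_percent < 88]))

  # a point missing one delay is an error naming the point
  df2 <- as.data.frame(tab)[-2, ]
  expect_error(correct_series(as_titration_table(df2)), "exactly 2 required")
})
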