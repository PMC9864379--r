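test_that("v/v%% to molar conversion matches the closed form", {
  expect_equal(vv_to_molar(0), 0)
  # ~70 v/v% is "nearly 10 M"
  expect_equal(vv_to_molar(70, 1.10, 78.13), 9.855, tolerance = 1e-4)
  expect_equal(vv_to_molar(100, 1.10, 78.13), 1100 / 78.13, tolerance = 1e-12)
  expect_equal(vv_to_molar(100, 1.10, 78.13), 14.08, tolerance = 1e-3)
  expect_error(vv_to_molar(101), "within")
  expect_error(vv_to_molar(-1), "within")
  # inverse
  expect_equal(molar_to_vv(vv_to_molar(37.5)), 37.5, tolerance = 1e-12)
})

test_that("folded fraction and intensity model obey the two-state algebra", {
  # midpoint: m*conc = dG0 gives exactly one half
  expect_equal(folded_fraction(23, 2.3, 10, 310), 0.5)
  # closed form exp(-7.761) at zero denaturant
  expect_equal(folded_fraction(20, 2.3, 0, 310),
               1 / (1 + exp(-20 / (8.314e-3 * 310))), tolerance = 1e-12)
  expect_equal(folded_fraction(20, 2.3, 0, 310), 0.99957, tolerance = 1e-5)
  # m = 0: no concentration dependence
  expect_equal(folded_fraction(10, 0, c(0, 5, 14), 310),
               rep(folded_fraction(10, 0, 0, 310), 3))

  expect_equal(intensity_model(10, a = 0.8, m = 2.3, d50 = 10, 310), 0.4)
  # I(conc)/a == f_F(conc) everywhere (algebraic identity of the two forms)
  conc <- seq(0, 14, by = 0.25)
  expect_equal(intensity_model(conc, 1.2, 2.3, 10, 310) / 1.2,
               folded_fraction(2.3 * 10, 2.3, conc, 310), tolerance = 1e-15)
  # f_F monotone decreasing in conc for m > 0
  expect_true(all(diff(folded_fraction(23, 2.3, conc, 310)) < 0))

  expect_equal(dG_at_conc(23, 2.3, 0), 23)
  expect_equal(dG_at_conc(23, 2.3, 10), 0)
  expect_equal(dG_at_conc(23, 2.3, 5), 11.5)
})

test_that("two-state fit recovers noiseless parameters and matches the grid oracle", {
  tab <- simulate_titration(a = 1, m = 2.3, d50_M = 10, noise_sd = 0,
                            seed = 1, peak_ids = "P")
  tr <- attr(tab, "truth")
  ser <- one_corrected_series(tab)
  fit <- fit_two_state(ser, temperature_K = 310)
  expect_true(fit$converged)
  expect_equal(fit$m, 2.3, tolerance = 1e-6)
  expect_equal(fit$d50, 10, tolerance = 1e-6)
  expect_equal(fit$dG0, 23, tolerance = 1e-6)
  # normalisation to the reference point rescales the plateau to 1/f(c_ref)
  expect_equal(fit$a, tr$a_norm, tolerance = 1e-6)
  # dG0 is the exact product, never refit
  expect_identical(fit$dG0, fit$m * fit$d50)
  # d50 reported on both axes
  expect_equal(fit$d50_vv, molar_to_vv(fit$d50), tolerance = 1e-12)

  # independent zooming grid search agrees to 4 significant digits
  conc <- vv_to_molar(ser$dmso_vv_percent)
  or <- oracle_two_state_grid(conc, ser$i_rel, 310)
  expect_equal(fit$m, unname(or["m"]), tolerance = 5e-5)
  expect_equal(fit$d50, unname(or["d50"]), tolerance = 5e-5)
  expect_equal(fit$a, unname(or["a"]), tolerance = 5e-5)
})

test_that("degenerate series are flagged or rejected", {
  flat <- data.frame(peak_id = "F", dmso_vv_percent = seq(0, 80, 10),
                     i_rel = rep(1, 9), censored = FALSE)
  fit <- fit_two_state(flat, 310)
  expect_false(fit$converged)
  expect_true(is.na(fit$dG0))

  few <- data.frame(peak_id = "S", dmso_vv_percent = c(0, 20, 40),
                    i_rel = c(1, 0.8, 0.2), censored = FALSE)
  expect_error(fit_two_state(few, 310), "at least 5")
})

test_that("fits are invariant to titration direction", {
  tab <- simulate_titration(noise_sd = 0.02, seed = 11, peak_ids = "P")
  ser <- one_corrected_series(tab)
  up <- fit_two_state(ser, 310)
  dn <- fit_two_state(ser[rev(seq_len(nrow(ser))), ], 310)
  expect_equal(up$m, dn$m, tolerance = 1e-8)
  expect_equal(up$d50, dn$d50, tolerance = 1e-8)
  expect_equal(up$dG0, dn$dG0, tolerance = 1e-8)
})

test_that("parameter recovery holds over 100 seeded noisy titrations", {
  res <- vapply(1:100, function(s) {
    tab <- simulate_titration(a = 1, m = 2.3, d50_M = 10, noise_sd = 0.02,
                              seed = 1000 + s, peak_ids = "P")
    f <- fit_two_state(one_corrected_series(tab), 310)
    c(err = abs(f$dG0 - 23) / 23,
      cover = as.numeric(abs(f$dG0 - 23) <= f$dG0_se),
      conv = as.numeric(f$converged))
  }, numeric(3))
  expect_true(all(res["conv", ] == 1))
  expect_lt(stats::median(res["err", ]), 0.05)
  cov <- mean(res["cover", ])
  expect_gte(cov, 0.55)
  expect_lte(cov, 0.80)
})

test_that("pooling averages converged fits only", {
  mk <- function(peak, dG0, conv = TRUE)
    structure(list(peak_id = peak, dG0 = dG0, converged = conv),
              class = "unfolding_fit")
  p <- pool_peaks(list(mk("A", 20), mk("B", 20), mk("C", 20)))
  expect_equal(p$mean_dG0, 20)
  expect_equal(p$sd_dG0, 0)

  p2 <- pool_peaks(list(mk("A", 17), mk("B", 33)))
  expect_equal(p2$mean_dG0, 25)
  expect_equal(p2$sd_dG0, sqrt(128), tolerance = 1e-12)
  expect_equal(p2$sd_dG0, 11.31, tolerance = 1e-3)

  # six per-peak values in the 17-33 kJ/mol window averaging 23
  vals <- c(17, 19, 22, 24, 26, 30)
  p6 <- pool_peaks(lapply(seq_along(vals),
                          function(i) mk(paste0("P", i), vals[i])))
  expect_equal(p6$mean_dG0, 23)
  expect_equal(p6$n_peaks, 6)

  # non-converged fits are excluded; nothing converged is an error
  p7 <- pool_peaks(list(mk("A", 20), mk("B", 99, conv = FALSE)))
  expect_equal(p7$n_peaks, 1)
  expect_error(pool_peaks(list(mk("A", 1, conv = FALSE))), "no converged")
})
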