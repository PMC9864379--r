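test_that("Lipari-Szabo spectral density has the right limits and values", {
  # rigid limit: J(0) = 0.4 * tau_c
  expect_equal(lipari_szabo_J(0, 1, 7.7e-9), 3.08e-9, tolerance = 1e-12)
  # closed form at the 15N frequency of a 700 MHz magnet
  wN <- 2 * pi * 70.966e6
  expect_equal(lipari_szabo_J(wN, 1, 7.7e-9),
               0.4 * 7.7e-9 / (1 + (wN * 7.7e-9)^2), tolerance = 1e-15)
  expect_equal(lipari_szabo_J(wN, 1, 7.7e-9), 2.41e-10, tolerance = 1e-3)
  expect_error(lipari_szabo_J(0, 1.2, 7.7e-9), "S2")
  expect_error(lipari_szabo_J(0, 0.5, -1), "tau_c")

  # internal motion adds a faster component; J0 ordering holds
  grid <- expand.grid(S2 = c(0.3, 0.7, 0.95), tc = c(2, 7.7, 15) * 1e-9)
  for (i in seq_len(nrow(grid))) {
    const <- nmr_constants(70.966)
    js <- vapply(c(0, const$omega_N, 0.87 * const$omega_H),
                 lipari_szabo_J, numeric(1),
                 S2 = grid$S2[i], tau_c = grid$tc[i])
    expect_true(all(diff(js) < 0))  # J0 > JwN > JwH
  }
})

test_that("forward rates behave physically", {
  # extreme narrowing: R2/R1 -> 1
  r <- forward_rates(1, 1e-4, field_15N_MHz = 70.966)
  expect_equal(r$R2 / r$R1, 1, tolerance = 0.02)
  # Rex adds to R2 only, exactly
  base <- forward_rates(0.87, 7.7, field_15N_MHz = 70.966)
  rex <- forward_rates(0.87, 7.7, field_15N_MHz = 70.966, Rex = 5)
  expect_identical(rex$R2, base$R2 + 5)
  expect_identical(rex$R1, base$R1)
  expect_identical(rex$NOE, base$NOE)
  # slow tumbling at 310 K in 50% DMSO: NOE positive but below 1
  expect_gt(base$NOE, 0.65)
  expect_lt(base$NOE, 1)
})

test_that("reduced mapping inverts the forward model within 2%", {
  for (field in c(50.684, 70.966)) {
    const <- nmr_constants(field)
    for (tc in c(2, 5, 7.7, 10, 15)) {
      for (S2 in c(0.5, 0.7, 0.87, 1)) {
        r <- forward_rates(S2, tc, field_15N_MHz = field, const = const)
        jm <- reduced_jmap(r$R1, r$R2, r$NOE, field, const = const)
        J0 <- lipari_szabo_J(0, S2, tc * 1e-9)
        JN <- lipari_szabo_J(const$omega_N, S2, tc * 1e-9)
        expect_equal(jm$J0, J0, tolerance = 0.02)
        expect_equal(jm$JwN, JN, tolerance = 0.02)
        expect_false(jm$unphysical)
      }
    }
  }
  # NOE = 1 means no cross-relaxation: J(0.87 wH) = 0
  expect_equal(reduced_jmap(1.5, 10, 1, 70.966)$JwH, 0)
})

test_that("rigid synthetic residues fall on the tau_c-only locus", {
  # points mapped from rigid residues must lie on the curve traced by the
  # rigid forward model as tau_c varies (no internal motion)
  ds <- simulate_relaxation(noise_sd = 0, s2_mean = 1, s2_sd = 0, seed = 5)
  jm <- jmap_dataset(ds)
  curve_J0 <- function(tc) lipari_szabo_J(0, 1, tc)
  curve_JN <- function(tc) lipari_szabo_J(nmr_constants(70.966)$omega_N, 1, tc)
  # invert each residue's J0 for tau_c, then check JwN lands on the curve
  for (i in seq_len(nrow(jm))) {
    tc_i <- jm$J0[i] / 0.4
    expect_equal(jm$JwN[i], curve_JN(tc_i), tolerance = 0.02)
  }
  expect_equal(jm$J0, rep(curve_J0(7.7e-9), nrow(jm)), tolerance = 0.01)
})

test_that("tau_c estimation from R2/R1 round-trips the generator", {
  ds <- simulate_relaxation(noise_sd = 0, tau_c_ns = 7.7, seed = 1)
  est <- estimate_tauc_r2r1(ds)
  expect_equal(est$tau_c_ns, 7.7, tolerance = 0.005)
  # slower tumbling regime at the lower field
  ds12 <- simulate_relaxation(noise_sd = 0, tau_c_ns = 12,
                              field_15N_MHz = 50.684, seed = 2)
  expect_equal(estimate_tauc_r2r1(ds12)$tau_c_ns, 12, tolerance = 0.005)
  # extreme narrowing: ratio ~ 1 falls below the solver grid and is flagged
  fast <- simulate_relaxation(noise_sd = 0, tau_c_ns = 0.01, s2_mean = 1,
                              s2_sd = 0, seed = 3)
  expect_error(estimate_tauc_r2r1(fast), "filtered")
})

test_that("model-free fit inverts the forward model", {
  # noiseless: all parameters recovered to < 0.1%
  ds <- simulate_relaxation(noise_sd = 0, seed = 3)
  tr <- attr(ds, "truth")
  mf <- fit_model_free(ds, mc_reps = 0)
  expect_equal(mf$tau_c_ns, tr$tau_c_ns, tolerance = 1e-3)
  expect_equal(mf$per_residue$S2, tr$S2, tolerance = 1e-3)

  # rigid noiseless: S2 = 1 within 1e-3
  rigid <- simulate_relaxation(noise_sd = 0, s2_mean = 1, s2_sd = 0, seed = 4)
  mfr <- fit_model_free(rigid, mc_reps = 0)
  expect_equal(mfr$per_residue$S2, rep(1, 53), tolerance = 1e-3)

  # S2 invariant to uniform error scaling on noiseless data
  scaled <- as.data.frame(ds)
  scaled$R1_err <- scaled$R1_err * 7
  scaled$R2_err <- scaled$R2_err * 7
  scaled$NOE_err <- scaled$NOE_err * 7
  mfs <- fit_model_free(as_relaxation_dataset(scaled, 70.966), mc_reps = 0)
  expect_equal(mfs$per_residue$S2, mf$per_residue$S2, tolerance = 1e-6)
})

test_that("model-free recovery with noise and Monte-Carlo errors", {
  ds <- simulate_relaxation(noise_sd = 0.02, seed = 7)
  tr <- attr(ds, "truth")
  mf <- fit_model_free(ds, mc_reps = 50, seed = 11)
  expect_equal(mf$tau_c_ns, 7.7, tolerance = 0.03)
  expect_lt(sqrt(mean((mf$per_residue$S2 - tr$S2)^2)), 0.02)
  expect_equal(mean(mf$per_residue$S2), 0.87, tolerance = 0.02)
  # MC errors are on the scale of the propagated noise
  expect_true(all(is.finite(mf$per_residue$S2_se)))
  expect_gt(stats::median(mf$per_residue$S2_se), 0.002)
  expect_lt(stats::median(mf$per_residue$S2_se), 0.05)
  expect_true(is.finite(mf$tau_c_se_ns) && mf$tau_c_se_ns > 0)
})

test_that("R1*R2 screening flags injected exchange and nothing else", {
  base <- simulate_relaxation(noise_sd = 0, s2_sd = 0, seed = 9)
  scr0 <- exchange_screen_r1r2(base)
  expect_equal(sum(scr0$flagged), 0L)

  rex <- simulate_relaxation(noise_sd = 0, s2_sd = 0, rex = c("25" = 5),
                             seed = 9)
  scr <- exchange_screen_r1r2(rex)
  expect_identical(rex$residue[scr$flagged], 25L)
  # the product statistic carries the injected contribution
  expect_gt(scr$r1r2[rex$residue == 25], attr(scr, "threshold"))
})

test_that("R1*R2 spread under noise matches Monte-Carlo propagation", {
  # uniform rigid protein: the sample SD of R1*R2 should agree with the
  # noise-propagated SD (delta method: product of two 2% -> ~2.8% of level)
  sds <- vapply(1:20, function(s) {
    ds <- simulate_relaxation(noise_sd = 0.02, s2_sd = 0, seed = 400 + s)
    stats::sd(ds$R1 * ds$R2)
  }, numeric(1))
  ds0 <- simulate_relaxation(noise_sd = 0, s2_sd = 0, seed = 1)
  level <- mean(ds0$R1 * ds0$R2)
  expected <- level * sqrt(2) * 0.02
  expect_equal(mean(sds), expected, tolerance = 0.15)
})
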