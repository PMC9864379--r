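## Seeded synthetic-data generators.  Each generator embeds its ground
## truth in the "truth" attribute of the returned object so that tests
## and recovery studies never rely on external data.

#' Simulate a raw dual-delay HSQC peak-volume titration
#'
#' Per titration point the true relative intensity follows the two-state
#' sigmoid ([intensity_model()]).  Raw volumes at the two spin-echo delays
#' are produced by monoexponential T2 decay with a T2 that shortens across
#' the titration (viscosity proxy), scaled by the dilution of a fixed
#' solute amount as the solution volume grows, and perturbed by
#' multiplicative noise.  Noise is applied per titration point (shared by
#' the two delays, as both spectra see the same sample) with an optional
#' independent per-delay component.
#'
#' Defaults emulate the published titration conditions: 12 DMSO points
#' between 0 and 88 v/v% at 310 K, midpoint near 10 M (~71 v/v%),
#' m = 2.3 kJ/mol/M, solution volume growing from 350 to 990 uL, delays
#' 5.5/11 ms, T2 shrinking threefold (40 to 13 ms) across the titration,
#' and 2% multiplicative Gaussian noise.
#'
#' @param a plateau amplitude.
#' @param m m-value in kJ/mol/M.
#' @param d50_M unfolding midpoint in mol/L.
#' @param temperature_K temperature in K.
#' @param dmso_vv DMSO grid in v/v %.
#' @param peak_ids character vector of peak labels (one series per peak,
#'   independent noise).
#' @param t1_ms,t2_ms the two transverse delays in ms.
#' @param t2_profile T2 in ms per titration point: a function of vv, or a
#'   vector matching `dmso_vv`, or a single value.
#' @param volume_profile solution volume in uL per titration point
#'   (vector or single value).
#' @param noise_sd multiplicative noise SD (fraction), shared per point.
#' @param delay_noise_sd additional independent per-delay multiplicative
#'   noise SD (fraction).
#' @param noise_type `"gaussian"` (1 + N(0, sd)) or `"lognormal"`.
#' @param pulse_scale per-point 1H pulse calibration factor (vector or
#'   single value); recorded in the table and divided out on correction.
#' @param amplitude base peak-volume scale in instrument units.
#' @param density,molar_mass DMSO bulk properties.
#' @param seed RNG seed; identical seed and spec give identical tables.
#' @return a `titration_table` with attribute `truth` (list of the
#'   generating parameters and the per-point true I/I0 per peak).
#' @export
simulate_titration <- function(a = 1, m = 2.3, d50_M = 10,
                               temperature_K = 310,
                               dmso_vv = seq(0, 88, by = 8),
                               peak_ids = c("C7", "K9", "C14", "K15",
                                            "G21", "T37"),
                               t1_ms = 5.5, t2_ms = 11,
                               t2_profile = function(vv) 40 - 27 * vv / 88,
                               volume_profile = NULL,
                               noise_sd = 0.02, delay_noise_sd = 0,
                               noise_type = c("gaussian", "lognormal"),
                               pulse_scale = 1,
                               amplitude = 1e5,
                               density = .DMSO_DENSITY,
                               molar_mass = .DMSO_MOLAR_MASS,
                               seed = NULL) {
  noise_type <- match.arg(noise_type)
  npt <- length(dmso_vv)
  t2v <- if (is.function(t2_profile)) t2_profile(dmso_vv) else
    rep_len(t2_profile, npt)
  if (any(t2v <= 0)) .stopf("t2_profile must be positive")
  vol <- if (is.null(volume_profile)) seq(350, 990, length.out = npt) else
    rep_len(volume_profile, npt)
  pulse <- rep_len(pulse_scale, npt)
  conc <- vv_to_molar(dmso_vv, density, molar_mass)
  i_true <- intensity_model(conc, a, m, d50_M, temperature_K)

  mult <- function(n, sd) {
    if (sd <= 0) return(rep(1, n))
    if (noise_type == "gaussian") 1 + stats::rnorm(n, 0, sd)
    else stats::rlnorm(n, -sd^2 / 2, sd)
  }

  .with_seed(seed, {
    rows <- lapply(peak_ids, function(pk) {
      eps_pt <- mult(npt, noise_sd)
      eps_d1 <- mult(npt, delay_noise_sd)
      eps_d2 <- mult(npt, delay_noise_sd)
      dilution <- vol[1] / vol
      v1 <- amplitude * i_true * exp(-t1_ms / t2v) * dilution * pulse *
        eps_pt * eps_d1
      v2 <- amplitude * i_true * exp(-t2_ms / t2v) * dilution * pulse *
        eps_pt * eps_d2
      data.frame(peak_id = pk,
                 dmso_vv_percent = rep(dmso_vv, each = 2),
                 delay_ms = rep(c(t1_ms, t2_ms), npt),
                 volume_raw = as.vector(rbind(v1, v2)),
                 solution_volume_uL = rep(vol, each = 2),
                 pulse_scale = rep(pulse, each = 2),
                 stringsAsFactors = FALSE)
    })
    out <- as_titration_table(do.call(rbind, rows))
    ## normalising to the reference point cancels the generating `a` and
    ## leaves an observable plateau of 1 / f(c_ref)
    a_norm <- 1 + exp(m * (min(conc) - d50_M) /
                        (.R_GAS * temperature_K))
    attr(out, "truth") <- list(a = a, a_norm = a_norm, m = m, d50_M = d50_M,
                               dG0 = m * d50_M,
                               temperature_K = temperature_K,
                               dmso_vv = dmso_vv, dmso_molar = conc,
                               i_rel_true = i_true, t2_ms = t2v,
                               solution_volume_uL = vol,
                               noise_sd = noise_sd, seed = seed)
    out
  })
}

#' Simulate a per-residue 15N relaxation dataset
#'
#' Residue order parameters are drawn from a clipped normal distribution
#' (defaults: mean 0.87, SD 0.06, the regime of a rigid disulfide-bonded
#' backbone at 310 K); rates come from [forward_rates()] at a single
#' global correlation time, with optional per-residue exchange (Rex)
#' contributions and fractional Gaussian noise.  Stated errors equal the
#' true noise level (or `noise_floor` for noiseless data).
#'
#' Default residue numbering runs 2..55 excluding the proline at 29,
#' giving the 53 amide NH probes of a 55-residue protein.
#'
#' @param n_residues number of residues (ignored when `residues` given).
#' @param residues integer vector of residue indices.
#' @param s2_mean,s2_sd mean and SD of the S2 distribution.
#' @param s2_floor,s2_ceiling clipping bounds for drawn S2.
#' @param tau_c_ns global correlation time in ns.
#' @param field_15N_MHz 15N frequency in MHz.
#' @param rex named numeric vector of Rex contributions (s^-1), names are
#'   residue indices; or `NULL`.
#' @param noise_sd fractional Gaussian noise on R1, R2 and NOE.
#' @param noise_floor relative error reported when `noise_sd = 0`.
#' @param seed RNG seed.
#' @return a `relaxation_dataset` with attribute `truth` (generating
#'   `S2`, `tau_c_ns`, `rex`, `seed`).
#' @export
simulate_relaxation <- function(n_residues = 53,
                                residues = NULL,
                                s2_mean = 0.87, s2_sd = 0.06,
                                s2_floor = 0, s2_ceiling = 1,
                                tau_c_ns = 7.7,
                                field_15N_MHz = 70.966,
                                rex = NULL,
                                noise_sd = 0.02,
                                noise_floor = 0.02,
                                seed = NULL) {
  if (is.null(residues)) {
    residues <- setdiff(2:55, 29)[seq_len(min(n_residues, 53))]
    if (n_residues > 53) residues <- seq_len(n_residues) + 1L
  }
  n <- length(residues)
  const <- nmr_constants(field_15N_MHz)
  .with_seed(seed, {
    S2 <- pmin(pmax(stats::rnorm(n, s2_mean, s2_sd), s2_floor), s2_ceiling)
    rex_vec <- rep(0, n)
    if (!is.null(rex)) {
      pos <- match(as.integer(names(rex)), residues)
      if (anyNA(pos)) .stopf("rex names must be residue indices present in the dataset")
      rex_vec[pos] <- rex
    }
    R1 <- R2 <- NOE <- numeric(n)
    for (i in seq_len(n)) {
      r <- forward_rates(S2[i], tau_c_ns, NULL, Rex = rex_vec[i],
                         const = const)
      R1[i] <- r$R1; R2[i] <- r$R2; NOE[i] <- r$NOE
    }
    err_frac <- if (noise_sd > 0) noise_sd else noise_floor
    df <- data.frame(residue = residues,
                     R1 = R1 * (1 + stats::rnorm(n, 0, noise_sd)),
                     R1_err = abs(R1) * err_frac,
                     R2 = R2 * (1 + stats::rnorm(n, 0, noise_sd)),
                     R2_err = abs(R2) * err_frac,
                     NOE = NOE * (1 + stats::rnorm(n, 0, noise_sd)),
                     NOE_err = abs(NOE) * err_frac)
    out <- as_relaxation_dataset(df, field_15N_MHz)
    attr(out, "truth") <- list(S2 = S2, tau_c_ns = tau_c_ns,
                               rex = rex_vec, field_15N_MHz = field_15N_MHz,
                               noise_sd = noise_sd, seed = seed)
    out
  })
}

#' Simulate DSC thermograms across a DMSO series
#'
#' One thermogram per DMSO condition.  The melting point of condition `x`
#' follows the stability parabola `Tm(x) = p1*x^2 + p2*x + p3`
#' (optionally jittered by `tm_jitter_sd` to emulate run-to-run Tm
#' scatter).  The endotherm is the equilibrium two-state excess heat
#' capacity `Cp_ex(T) = dH^2/(R*Tm_K^2) * K/(1+K)^2` with
#' `K = exp(-dH/R * (1/T - 1/Tm))` (temperatures in kelvin), whose
#' maximum falls exactly at Tm; the van't Hoff enthalpy `dH_vH` only sets
#' the peak width and area.  A linear instrument baseline and optional
#' additive Gaussian noise are superimposed.
#'
#' @param p1,p2,p3 stability-parabola coefficients (degC per (v/v%)^2,
#'   degC per v/v%, degC).
#' @param dmso_vv DMSO conditions in v/v % (default: 0-55% in steps of 5,
#'   12 conditions).
#' @param temp_C temperature grid in degC (default 40-130 by 0.1).
#' @param dH_vH van't Hoff enthalpy in kJ/mol (shape parameter only).
#' @param baseline_intercept,baseline_slope linear baseline (instrument
#'   units, units/degC).
#' @param noise_sd additive Gaussian noise on Cp (instrument units).
#' @param tm_jitter_sd SD in degC of Gaussian jitter on the per-condition
#'   true Tm (emulates experimental Tm reproducibility).
#' @param gas_constant gas constant in kJ/mol/K.
#' @param seed RNG seed.
#' @return named list of `thermogram`s (names = DMSO v/v%), with
#'   attribute `truth` (data frame of `dmso_vv_percent`, `tm_C` actually
#'   generated, `tm_parabola_C` from the noiseless parabola).
#' @export
simulate_dsc <- function(p1 = -2.98e-3, p2 = -59.0e-3, p3 = 93.2,
                         dmso_vv = seq(0, 55, by = 5),
                         temp_C = seq(40, 130, by = 0.1),
                         dH_vH = 600,
                         baseline_intercept = 5, baseline_slope = 0.05,
                         noise_sd = 0, tm_jitter_sd = 0,
                         gas_constant = .R_GAS, seed = NULL) {
  tm_parab <- p1 * dmso_vv^2 + p2 * dmso_vv + p3
  .with_seed(seed, {
    tm_true <- tm_parab + if (tm_jitter_sd > 0)
      stats::rnorm(length(dmso_vv), 0, tm_jitter_sd) else 0
    if (any(tm_true <= min(temp_C) + 2 | tm_true >= max(temp_C) - 2))
      .stopf("melting point outside the scanned temperature window")
    out <- lapply(seq_along(dmso_vv), function(i) {
      TmK <- tm_true[i] + 273.15
      TK <- temp_C + 273.15
      K <- exp(-dH_vH / gas_constant * (1 / TK - 1 / TmK))
      cp <- dH_vH^2 / (gas_constant * TmK^2) * K / (1 + K)^2
      cp <- cp + baseline_intercept + baseline_slope * temp_C
      if (noise_sd > 0) cp <- cp + stats::rnorm(length(cp), 0, noise_sd)
      as_thermogram(data.frame(temperature_C = temp_C, cp = cp),
                    dmso_vv_percent = dmso_vv[i])
    })
    names(out) <- as.character(dmso_vv)
    attr(out, "truth") <- data.frame(dmso_vv_percent = dmso_vv,
                                     tm_C = tm_true,
                                     tm_parabola_C = tm_parab)
    attr(out, "params") <- list(p1 = p1, p2 = p2, p3 = p3, dH_vH = dH_vH,
                                seed = seed)
    out
  })
}
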