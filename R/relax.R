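## Backbone 15N relaxation: Lipari-Szabo spectral densities, forward
## R1/R2/NOE rates, reduced spectral density mapping, global-tauc /
## per-residue-S2 ("M2", isotropic tumbling) fitting, and R1*R2 exchange
## screening.
##
## Sign conventions: gamma(15N) < 0, so the "omegaH + omegaN" dipolar
## frequency is the *smaller* of the two proton-band frequencies
## (|omegaH| - |omegaN|) and "omegaH - omegaN" the larger.  Getting this
## right is what makes the 0.87*omegaH reduced-mapping convention close
## under round-tripping.

#' Physical constants for an amide 15N-1H spin pair
#'
#' The dipolar coupling constant `d = (mu0/4pi) * hbar * gammaH *
#' |gammaN| / r_NH^3` and the CSA constant `c^2 = (omegaN * dsigma)^2 / 3`
#' are recomputed from first principles for the requested field; nothing
#' is hard-coded downstream.
#'
#' @param field_15N_MHz 15N Larmor frequency in MHz (70.966 for a 700 MHz
#'   spectrometer, 50.684 for 500 MHz).
#' @param r_NH_A N-H bond length in Angstrom.
#' @param delta_sigma_ppm 15N chemical shift anisotropy in ppm.
#' @return list with gyromagnetic ratios (`gamma_H`, `gamma_N`, signed,
#'   rad s^-1 T^-1), angular frequencies `omega_N`, `omega_H` (magnitudes,
#'   rad/s), dipolar constant `d` (rad/s) and CSA constant squared `c2`.
#' @export
nmr_constants <- function(field_15N_MHz, r_NH_A = 1.02,
                          delta_sigma_ppm = -160) {
  gamma_H <- 2.6752218744e8   # rad s^-1 T^-1
  gamma_N <- -2.7126189e7     # rad s^-1 T^-1 (negative)
  mu0 <- 4 * pi * 1e-7
  hbar <- 1.054571817e-34
  omega_N <- 2 * pi * field_15N_MHz * 1e6
  omega_H <- omega_N * gamma_H / abs(gamma_N)
  r <- r_NH_A * 1e-10
  d <- (mu0 / (4 * pi)) * hbar * gamma_H * abs(gamma_N) / r^3
  c2 <- (omega_N * delta_sigma_ppm * 1e-6)^2 / 3
  list(gamma_H = gamma_H, gamma_N = gamma_N,
       omega_N = omega_N, omega_H = omega_H,
       d = d, d2 = d^2, c2 = c2,
       field_15N_MHz = field_15N_MHz, r_NH_A = r_NH_A,
       delta_sigma_ppm = delta_sigma_ppm)
}

#' Lipari-Szabo model-free spectral density
#'
#' `J(w) = (2/5) * (S2*tc/(1+(w tc)^2) + (1-S2)*t/(1+(w t)^2))` with
#' `1/t = 1/tc + 1/te`; the internal-motion term is omitted when `tau_e`
#' is `NULL` ("M2" model: one global correlation time, no effective
#' internal correlation time).
#'
#' @param omega angular frequency in rad/s (vectorised).
#' @param S2 generalised order parameter in `[0, 1]`.
#' @param tau_c global rotational correlation time in seconds.
#' @param tau_e effective internal correlation time in seconds, or `NULL`.
#' @return spectral density in s/rad.
#' @export
#' @examples
#' lipari_szabo_J(0, S2 = 1, tau_c = 7.7e-9)  # 0.4 * tau_c = 3.08e-9
lipari_szabo_J <- function(omega, S2, tau_c, tau_e = NULL) {
  if (S2 < 0 || S2 > 1) .stopf("S2 must lie in [0, 1] (got %s)", S2)
  if (tau_c <= 0) .stopf("tau_c must be > 0")
  J <- S2 * tau_c / (1 + (omega * tau_c)^2)
  if (!is.null(tau_e) && S2 < 1) {
    tau <- 1 / (1 / tau_c + 1 / tau_e)
    J <- J + (1 - S2) * tau / (1 + (omega * tau)^2)
  }
  0.4 * J
}

#' Forward 15N relaxation rates from model-free parameters
#'
#' Standard expressions for an amide 15N relaxed by the N-H dipolar
#' interaction and 15N CSA:
#' `R1 = (d2/4)*(J(wH-wN) + 3 J(wN) + 6 J(wH+wN)) + c2*J(wN)`,
#' `R2 = (d2/8)*(4 J(0) + J(wH-wN) + 3 J(wN) + 6 J(wH) + 6 J(wH+wN))
#'       + (c2/6)*(4 J(0) + 3 J(wN)) + Rex`,
#' `NOE = 1 + (d2/4)*(gammaH/gammaN)*(6 J(wH+wN) - J(wH-wN)) / R1`,
#' with signed `wN < 0`.
#'
#' @param S2 order parameter.
#' @param tau_c_ns global correlation time in ns.
#' @param tau_e_ns effective internal correlation time in ns or `NULL`.
#' @param field_15N_MHz 15N frequency in MHz.
#' @param Rex chemical-exchange contribution to R2 in s^-1.
#' @param const optionally a precomputed [nmr_constants()] list.
#' @return list with `R1`, `R2` (s^-1) and `NOE`.
#' @export
forward_rates <- function(S2, tau_c_ns, tau_e_ns = NULL,
                          field_15N_MHz = 70.966, Rex = 0,
                          const = nmr_constants(field_15N_MHz)) {
  tc <- tau_c_ns * 1e-9
  te <- if (is.null(tau_e_ns)) NULL else tau_e_ns * 1e-9
  wN <- const$omega_N
  wH <- const$omega_H
  J <- function(w) lipari_szabo_J(w, S2, tc, te)
  ## gammaN < 0: |wH - wN| = wH + |wN|, |wH + wN| = wH - |wN|
  J_HmN <- J(wH + wN)       # J(omegaH - omegaN)
  J_HpN <- J(wH - wN)       # J(omegaH + omegaN)
  J_N <- J(wN)
  J_H <- J(wH)
  J_0 <- J(0)
  d2 <- const$d2; c2 <- const$c2
  R1 <- (d2 / 4) * (J_HmN + 3 * J_N + 6 * J_HpN) + c2 * J_N
  R2 <- (d2 / 8) * (4 * J_0 + J_HmN + 3 * J_N + 6 * J_H + 6 * J_HpN) +
    (c2 / 6) * (4 * J_0 + 3 * J_N) + Rex
  sigma_NH <- (d2 / 4) * (6 * J_HpN - J_HmN)
  NOE <- 1 + (const$gamma_H / const$gamma_N) * sigma_NH / R1
  list(R1 = R1, R2 = R2, NOE = NOE)
}

#' Reduced spectral density mapping
#'
#' Algebraic inversion of (R1, R2, NOE) into J(0), J(omegaN) and
#' J(0.87*omegaH), using a single effective sampling frequency 0.87*omegaH
#' for all proton-band terms:
#' `sigmaNH = R1*(NOE-1)*gammaN/gammaH`;
#' `J(0.87wH) = 4 sigmaNH / (5 d2)`;
#' `J(wN) = (R1 - (7 d2/4) J(0.87wH)) / (3 d2/4 + c2)`;
#' `J(0) = (R2 - (d2/8)(3 J(wN) + 13 J(0.87wH)) - (c2/2) J(wN)) /
#'         (d2/2 + 2 c2/3)`.
#'
#' A negative mapped J(0) (possible with noisy data or strong exchange) is
#' returned but flagged `unphysical`.
#'
#' @param R1,R2 longitudinal/transverse rates in s^-1 (vectorised).
#' @param NOE hetNOE ratio (vectorised).
#' @param field_15N_MHz 15N frequency in MHz.
#' @param const optionally a precomputed [nmr_constants()] list.
#' @return data frame with columns `J0`, `JwN`, `JwH` (s/rad) and
#'   `unphysical`.
#' @export
reduced_jmap <- function(R1, R2, NOE, field_15N_MHz = 70.966,
                         const = nmr_constants(field_15N_MHz)) {
  if (any(R1 <= 0) || any(R2 <= 0)) .stopf("R1 and R2 must be > 0")
  d2 <- const$d2; c2 <- const$c2
  sigma_NH <- R1 * (NOE - 1) * (const$gamma_N / const$gamma_H)
  JwH <- 4 * sigma_NH / (5 * d2)
  JwN <- (R1 - (7 * d2 / 4) * JwH) / (3 * d2 / 4 + c2)
  J0 <- (R2 - (d2 / 8) * (3 * JwN + 13 * JwH) - (c2 / 2) * JwN) /
    (d2 / 2 + 2 * c2 / 3)
  data.frame(J0 = J0, JwN = JwN, JwH = JwH,
             unphysical = J0 < 0 | JwN < 0)
}

#' Map a whole relaxation dataset to reduced spectral densities
#'
#' @param dataset a `relaxation_dataset`.
#' @return data frame with `residue`, `J0`, `JwN`, `JwH`, `unphysical`.
#' @export
jmap_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "relaxation_dataset"))
  field <- attr(dataset, "field_15N_MHz")
  jm <- reduced_jmap(dataset$R1, dataset$R2, dataset$NOE, field)
  cbind(data.frame(residue = dataset$residue), jm)
}

## Rigid-limit R2/R1 ratio as a function of tau_c (seconds); monotone
## increasing, used to invert the observed ratio per residue.
.rigid_r2r1 <- function(tau_c_s, const) {
  r <- forward_rates(1, tau_c_s * 1e9, NULL, const = const)
  r$R2 / r$R1
}

#' Estimate the global rotational correlation time from R2/R1 ratios
#'
#' Per residue, the rigid-limit (S2-independent for the M2 model) R2/R1
#' ratio is inverted numerically for tau_c; the estimate is the 10%
#' trimmed mean over residues passing the mobility filter (NOE >= 0.65,
#' R2 within `r2_k` SD of the 10% trimmed mean) which excludes flexible
#' termini and exchange-broadened residues.
#'
#' @param dataset a `relaxation_dataset`.
#' @param noe_min minimum hetNOE for a residue to enter the estimate.
#' @param r2_k R2 outlier cut in SD units around the trimmed mean.
#' @param tau_range_ns search bracket for the per-residue inversion (ns).
#' @return list with `tau_c_ns` (trimmed-mean estimate), `tau_c_sd_ns`,
#'   `per_residue` data frame (`residue`, `tau_c_ns`, `used`, `flagged`),
#'   `n_used`.
#' @export
estimate_tauc_r2r1 <- function(dataset, noe_min = 0.65, r2_k = 1.5,
                               tau_range_ns = c(0.05, 50)) {
  stopifnot(inherits(dataset, "relaxation_dataset"))
  if (nrow(dataset) < 5L) .stopf("need at least 5 residues")
  const <- nmr_constants(attr(dataset, "field_15N_MHz"))
  lo <- .rigid_r2r1(tau_range_ns[1] * 1e-9, const)
  hi <- .rigid_r2r1(tau_range_ns[2] * 1e-9, const)

  tc <- vapply(dataset$R2 / dataset$R1, function(ratio) {
    if (!is.finite(ratio) || ratio <= lo || ratio >= hi) return(NA_real_)
    stats::uniroot(function(t) .rigid_r2r1(t * 1e-9, const) - ratio,
                   interval = tau_range_ns, tol = 1e-6)$root
  }, numeric(1))

  r2m <- mean(dataset$R2, trim = 0.1)
  r2sd <- stats::sd(dataset$R2)
  keep_r2 <- if (is.finite(r2sd) && r2sd > 0)
    abs(dataset$R2 - r2m) <= r2_k * r2sd else rep(TRUE, nrow(dataset))
  used <- dataset$NOE >= noe_min & keep_r2 & !is.na(tc)
  if (!any(used))
    .stopf("all residues filtered out; cannot estimate tau_c")
  est <- mean(tc[used], trim = 0.1)
  .log_msg("estimate_tauc_r2r1: tau_c = %.3f ns over %d residues", est,
           sum(used))
  list(tau_c_ns = est,
       tau_c_sd_ns = if (sum(used) > 1) stats::sd(tc[used]) else 0,
       per_residue = data.frame(residue = dataset$residue, tau_c_ns = tc,
                                used = used, flagged = is.na(tc)),
       n_used = sum(used))
}

## Least-squares S2 for one residue at fixed tau_c.  Errors of zero are
## replaced by a small fraction of the observable so that noiseless data
## remain well conditioned; S2 estimates are invariant to uniform error
## scaling.
.fit_s2_one <- function(R1, R2, NOE, errs, tau_c_ns, const) {
  errs <- pmax(errs, 1e-6 * abs(c(R1, R2, NOE)), 1e-12)
  chi2 <- function(S2) {
    r <- forward_rates(S2, tau_c_ns, NULL, const = const)
    sum(((c(r$R1, r$R2, r$NOE) - c(R1, R2, NOE)) / errs)^2)
  }
  op <- stats::optimize(chi2, interval = c(0, 1), tol = 1e-8)
  list(S2 = op$minimum, chi2 = op$objective)
}

.fit_all_s2 <- function(dataset, tau_c_ns, const) {
  n <- nrow(dataset)
  S2 <- numeric(n); chi2 <- numeric(n)
  for (i in seq_len(n)) {
    f <- .fit_s2_one(dataset$R1[i], dataset$R2[i], dataset$NOE[i],
                     c(dataset$R1_err[i], dataset$R2_err[i],
                       dataset$NOE_err[i]), tau_c_ns, const)
    S2[i] <- f$S2; chi2[i] <- f$chi2
  }
  list(S2 = S2, chi2 = chi2)
}

#' Model-free fit: one global correlation time, per-residue S2
#'
#' Three-stage fit of the isotropic ("spherical") model-free model with a
#' single global correlation time and one order parameter per residue
#' (no internal correlation time):
#' 1. initial tau_c from the R2/R1 ratio ([estimate_tauc_r2r1()]);
#' 2. per-residue S2 by weighted least squares on (R1, R2, NOE) at fixed
#'    tau_c;
#' 3. joint refinement of tau_c minimising the total chi-square, with the
#'    S2 re-fit at each candidate tau_c.
#'
#' Parameter errors come from Monte-Carlo resampling of the rates within
#' their stated errors (`mc_reps` replicates, seeded); each replicate
#' re-estimates tau_c from R2/R1 and refits all S2.
#'
#' @param dataset a `relaxation_dataset` (>= 5 residues).
#' @param mc_reps Monte-Carlo replicates for parameter errors; 0 skips
#'   error estimation.
#' @param seed RNG seed for the resampling.
#' @param refine_tauc set `FALSE` to keep the stage-1 tau_c.
#' @return a `model_free_result` list: `tau_c_ns`, `tau_c_se_ns`,
#'   `per_residue` data frame (`residue`, `S2`, `S2_se`, `chi2`),
#'   `total_chi2`, `n_residues`, `field_15N_MHz`.
#' @export
fit_model_free <- function(dataset, mc_reps = 200, seed = NULL,
                           refine_tauc = TRUE) {
  stopifnot(inherits(dataset, "relaxation_dataset"))
  if (nrow(dataset) < 5L) .stopf("need at least 5 residues")
  field <- attr(dataset, "field_15N_MHz")
  const <- nmr_constants(field)

  tc0 <- estimate_tauc_r2r1(dataset)$tau_c_ns
  tc <- tc0
  if (refine_tauc) {
    total_chi2 <- function(t) sum(.fit_all_s2(dataset, t, const)$chi2)
    op <- stats::optimize(total_chi2, interval = tc0 * c(0.7, 1.4),
                          tol = 1e-5)
    tc <- op$minimum
  }
  fit <- .fit_all_s2(dataset, tc, const)

  S2_se <- rep(NA_real_, nrow(dataset))
  tc_se <- NA_real_
  if (mc_reps > 0) {
    draws <- .with_seed(seed, {
      vapply(seq_len(mc_reps), function(rep) {
        pert <- dataset
        pert$R1 <- stats::rnorm(nrow(pert), dataset$R1, dataset$R1_err)
        pert$R2 <- stats::rnorm(nrow(pert), dataset$R2, dataset$R2_err)
        pert$NOE <- stats::rnorm(nrow(pert), dataset$NOE, dataset$NOE_err)
        pert$R1 <- pmax(pert$R1, 1e-3)
        pert$R2 <- pmax(pert$R2, 1e-3)
        tcr <- tryCatch(estimate_tauc_r2r1(pert)$tau_c_ns,
                        error = function(e) tc)
        c(tcr, .fit_all_s2(pert, tcr, const)$S2)
      }, numeric(1L + nrow(dataset)))
    })
    tc_se <- stats::sd(draws[1, ])
    S2_se <- apply(draws[-1, , drop = FALSE], 1, stats::sd)
  }
  .log_msg("fit_model_free: tau_c = %.3f ns (stage-1 %.3f), mean S2 = %.3f",
           tc, tc0, mean(fit$S2))
  structure(list(tau_c_ns = tc, tau_c_se_ns = tc_se,
                 per_residue = data.frame(residue = dataset$residue,
                                          S2 = fit$S2, S2_se = S2_se,
                                          chi2 = fit$chi2),
                 total_chi2 = sum(fit$chi2),
                 n_residues = nrow(dataset),
                 field_15N_MHz = field, model = "M2"),
            class = "model_free_result")
}

#' @export
print.model_free_result <- function(x, ...) {
  cat(sprintf("Model-free fit (M2, isotropic): %d residues at %.3f MHz\n",
              x$n_residues, x$field_15N_MHz))
  cat(sprintf("  tau_c = %.2f%s ns; mean S2 = %.3f (range %.3f-%.3f)\n",
              x$tau_c_ns,
              if (is.finite(x$tau_c_se_ns)) sprintf(" +- %.2f", x$tau_c_se_ns) else "",
              mean(x$per_residue$S2), min(x$per_residue$S2),
              max(x$per_residue$S2)))
  invisible(x)
}

#' Screen for chemical exchange with the R1*R2 product
#'
#' The R1*R2 product is nearly independent of the global tumbling time
#' and of S2 gradients, so residues with exchange broadening (Rex) stand
#' out as high outliers.  A residue is flagged when its product exceeds
#' the 10% trimmed mean by more than `k` sample standard deviations.
#'
#' @param dataset a `relaxation_dataset` (>= 5 residues).
#' @param k flag threshold in SD units.
#' @return data frame with `residue`, `r1r2`, `zscore`, `flagged`;
#'   attributes `center`, `sd` and `threshold` carry the statistics.
#' @export
exchange_screen_r1r2 <- function(dataset, k = 1.5) {
  stopifnot(inherits(dataset, "relaxation_dataset"))
  if (nrow(dataset) < 5L) .stopf("need at least 5 residues")
  prod <- dataset$R1 * dataset$R2
  center <- mean(prod, trim = 0.1)
  s <- stats::sd(prod)
  thr <- center + k * s
  z <- if (is.finite(s) && s > 0) (prod - center) / s else rep(0, length(prod))
  out <- data.frame(residue = dataset$residue, r1r2 = prod, zscore = z,
                    flagged = is.finite(s) & s > 0 & prod > thr)
  attr(out, "center") <- center
  attr(out, "sd") <- s
  attr(out, "threshold") <- thr
  out
}
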