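## Two-state chemical unfolding model and per-peak fitting.
##
## Model: DG(c) = DG0 - m*c, with midpoint c50 where DG = 0, so
## DG0 = m*c50.  The folded fraction is
##   fF(c) = 1 / (1 + exp((-DG0 + m*c) / (R*T)))
## and the observed relative intensity of a folded-state peak is
##   I/I0 = a / (1 + exp(m*(c - c50) / (R*T))) = a * fF(c).
## All energies in kJ/mol, m in kJ/mol/M, concentrations in mol/L.

#' Convert DMSO v/v percent to molar concentration
#'
#' `(vv/100) * density * 1000 / molar_mass`.  With the defaults (density
#' 1.10 g/mL, molar mass 78.13 g/mol), 70 v/v% is 9.86 M -- "nearly 10 M".
#'
#' @param vv volume percent in `[0, 100]`.
#' @param density DMSO density in g/mL.
#' @param molar_mass DMSO molar mass in g/mol.
#' @return concentration in mol/L.
#' @export
vv_to_molar <- function(vv, density = .DMSO_DENSITY,
                        molar_mass = .DMSO_MOLAR_MASS) {
  if (any(vv < 0 | vv > 100, na.rm = TRUE))
    .stopf("vv must be within [0, 100]")
  (vv / 100) * density * 1000 / molar_mass
}

#' Convert molar DMSO concentration to v/v percent
#' @param conc concentration in mol/L.
#' @inheritParams vv_to_molar
#' @return volume percent.
#' @export
molar_to_vv <- function(conc, density = .DMSO_DENSITY,
                        molar_mass = .DMSO_MOLAR_MASS) {
  100 * conc * molar_mass / (1000 * density)
}

#' Folded protein fraction under the two-state model
#'
#' @param dG0 standard unfolding free energy at zero denaturant (kJ/mol).
#' @param m denaturant m-value (kJ/mol/M).
#' @param conc denaturant concentration (mol/L).
#' @param temperature_K temperature (K).
#' @param gas_constant gas constant (kJ/mol/K).
#' @return folded fraction in (0, 1).
#' @export
folded_fraction <- function(dG0, m, conc, temperature_K = 310,
                            gas_constant = .R_GAS) {
  if (any(temperature_K <= 0)) .stopf("temperature_K must be > 0")
  1 / (1 + exp((-dG0 + m * conc) / (gas_constant * temperature_K)))
}

#' Two-state intensity model for a folded-state peak
#'
#' `a / (1 + exp(m * (conc - d50) / (R*T)))`; identical to
#' `a * folded_fraction(m * d50, m, conc, T)`.
#'
#' @param conc denaturant concentration (mol/L).
#' @param a plateau amplitude (dimensionless).
#' @param m m-value (kJ/mol/M).
#' @param d50 unfolding midpoint (mol/L).
#' @inheritParams folded_fraction
#' @return predicted I/I0.
#' @export
intensity_model <- function(conc, a, m, d50, temperature_K = 310,
                            gas_constant = .R_GAS) {
  if (any(temperature_K <= 0)) .stopf("temperature_K must be > 0")
  a / (1 + exp(m * (conc - d50) / (gas_constant * temperature_K)))
}

#' Unfolding free energy at a given denaturant concentration
#' @inheritParams folded_fraction
#' @return `dG0 - m * conc` in kJ/mol.
#' @export
dG_at_conc <- function(dG0, m, conc) dG0 - m * conc

#' Fit the two-state unfolding model to a corrected titration series
#'
#' Weighted nonlinear least squares of the intensity model in
#' `(a, m, d50)` on the non-censored points of one peak.  Initial guesses
#' are taken from the data: `a` from the maximum intensity, `d50` from the
#' concentration nearest `a/2`, and `m` from the central slope.  The
#' derived standard free energy `dG0 = m * d50` is reported with its
#' standard error propagated through the (m, d50) covariance; it is never
#' refit.  The amplitude is bounded to (0, 1.5] to exclude degenerate
#' fits.
#'
#' @param series one peak's rows of a `corrected_titration` (columns
#'   `dmso_vv_percent`, `i_rel`, `censored`; alternatively a data frame
#'   with a `dmso_molar` column).
#' @param temperature_K temperature of the titration (K).
#' @param weights optional per-point standard deviations of `i_rel`; unit
#'   weights by default.
#' @param density,molar_mass DMSO bulk properties for the v/v% to molar
#'   conversion of the concentration axis.
#' @param gas_constant gas constant (kJ/mol/K).
#' @return an `unfolding_fit` list: `peak_id`, estimates and standard
#'   errors of `a`, `m`, `d50` (molar and v/v%), `dG0`, `temperature_K`,
#'   `converged`, `n_points`, and the `vcov` of the fit.
#' @export
fit_two_state <- function(series, temperature_K = 310, weights = NULL,
                          density = .DMSO_DENSITY,
                          molar_mass = .DMSO_MOLAR_MASS,
                          gas_constant = .R_GAS) {
  peak <- if ("peak_id" %in% names(series)) as.character(series$peak_id[1]) else NA_character_
  if ("peak_id" %in% names(series) && length(unique(series$peak_id)) > 1L)
    .stopf("fit_two_state expects a single peak; got %d",
           length(unique(series$peak_id)))
  keep <- if ("censored" %in% names(series)) !series$censored else
    rep(TRUE, nrow(series))
  conc <- if ("dmso_molar" %in% names(series)) series$dmso_molar else
    vv_to_molar(series$dmso_vv_percent, density, molar_mass)
  conc <- conc[keep]
  y <- series$i_rel[keep]
  w <- if (is.null(weights)) rep(1, length(y)) else 1 / weights[keep]^2
  ok <- is.finite(conc) & is.finite(y)
  conc <- conc[ok]; y <- y[ok]; w <- w[ok]
  if (length(y) < 5L)
    .stopf("need at least 5 non-censored points to fit peak '%s' (got %d)",
           peak, length(y))

  failed <- function(reason) {
    .log_msg("fit_two_state[%s]: not converged (%s)", peak, reason)
    structure(list(peak_id = peak, converged = FALSE, reason = reason,
                   a = NA_real_, m = NA_real_, d50 = NA_real_,
                   dG0 = NA_real_, a_se = NA_real_, m_se = NA_real_,
                   d50_se = NA_real_, dG0_se = NA_real_,
                   d50_vv = NA_real_, temperature_K = temperature_K,
                   n_points = length(y), vcov = NULL),
              class = "unfolding_fit")
  }
  ## no transition in range: essentially flat data carry no information
  if (diff(range(y)) < 0.1 * max(abs(y)))
    return(failed("no transition in concentration range"))

  RT <- gas_constant * temperature_K
  a0 <- max(y)
  d50_0 <- conc[which.min(abs(y - a0 / 2))]
  ## slope at the transition centre; model slope there is -a*m/(4RT)
  mid <- order(abs(y - a0 / 2))[seq_len(min(4L, length(y)))]
  sl <- tryCatch(stats::coef(stats::lm(y[mid] ~ conc[mid]))[2],
                 error = function(e) NA_real_)
  m0 <- if (is.finite(sl) && sl < 0) -4 * RT * sl / a0 else 1
  m0 <- min(max(m0, 0.05), 50)
  if (d50_0 <= 0) d50_0 <- stats::median(conc)

  fit <- tryCatch(
    stats::nls(y ~ a / (1 + exp(m * (conc - d50) / RT)),
               start = list(a = a0, m = m0, d50 = d50_0),
               weights = w, algorithm = "port",
               lower = c(a = 1e-6, m = 1e-4, d50 = 1e-6),
               upper = c(a = 1.5, m = Inf, d50 = Inf),
               control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) e)
  if (inherits(fit, "error")) return(failed(conditionMessage(fit)))

  cf <- stats::coef(fit)
  V <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  se <- if (is.null(V)) rep(NA_real_, 3) else sqrt(pmax(diag(V), 0))
  names(se) <- names(cf)
  dG0 <- unname(cf["m"] * cf["d50"])
  dG0_se <- if (is.null(V)) NA_real_ else
    sqrt(max(cf["d50"]^2 * V["m", "m"] + cf["m"]^2 * V["d50", "d50"] +
               2 * cf["m"] * cf["d50"] * V["m", "d50"], 0))
  ## a transition outside the sampled range is not a measurement
  if (cf["d50"] > max(conc) * 1.5 || cf["d50"] < min(conc[conc > 0], Inf) / 2)
    return(failed("fitted midpoint outside sampled concentration range"))
  .log_msg("fit_two_state[%s]: a=%.4g+-%.2g m=%.4g+-%.2g d50=%.4g+-%.2g dG0=%.4g+-%.2g",
           peak, cf["a"], se["a"], cf["m"], se["m"], cf["d50"], se["d50"],
           dG0, dG0_se)
  structure(list(peak_id = peak, converged = TRUE, reason = NULL,
                 a = unname(cf["a"]), m = unname(cf["m"]),
                 d50 = unname(cf["d50"]), dG0 = dG0,
                 a_se = unname(se["a"]), m_se = unname(se["m"]),
                 d50_se = unname(se["d50"]), dG0_se = dG0_se,
                 d50_vv = molar_to_vv(unname(cf["d50"]), density, molar_mass),
                 temperature_K = temperature_K,
                 n_points = length(y), vcov = V),
            class = "unfolding_fit")
}

#' @export
print.unfolding_fit <- function(x, ...) {
  cat(sprintf("Two-state unfolding fit, peak %s (%d points, %s)\n",
              x$peak_id, x$n_points,
              if (x$converged) "converged" else paste0("NOT converged: ", x$reason)))
  if (x$converged) {
    cat(sprintf("  a    = %.4f +- %.4f\n", x$a, x$a_se))
    cat(sprintf("  m    = %.3f +- %.3f kJ/mol/M\n", x$m, x$m_se))
    cat(sprintf("  d50  = %.3f +- %.3f M (%.1f v/v%%)\n",
                x$d50, x$d50_se, x$d50_vv))
    cat(sprintf("  dG0  = %.2f +- %.2f kJ/mol at %.0f K\n",
                x$dG0, x$dG0_se, x$temperature_K))
  }
  invisible(x)
}

#' Fit every peak of a corrected titration
#'
#' @param corrected a `corrected_titration` from [correct_series()].
#' @inheritParams fit_two_state
#' @return named list of `unfolding_fit` objects, one per peak.
#' @export
fit_all_peaks <- function(corrected, temperature_K = 310, ...) {
  stopifnot(inherits(corrected, "corrected_titration"))
  lapply(split(as.data.frame(corrected), corrected$peak_id),
         fit_two_state, temperature_K = temperature_K, ...)
}

#' Pool per-peak unfolding free energies
#'
#' Unweighted mean and sample standard deviation of `dG0` over the
#' converged fits only.
#'
#' @param fits list of `unfolding_fit` objects.
#' @return a `pooled_unfolding` list: `mean_dG0`, `sd_dG0`, `n_peaks`,
#'   `dG0` (named vector of per-peak values), `fits`.
#' @export
pool_peaks <- function(fits) {
  if (inherits(fits, "unfolding_fit")) fits <- list(fits)
  conv <- Filter(function(f) isTRUE(f$converged), fits)
  if (!length(conv)) .stopf("no converged fits to pool")
  vals <- vapply(conv, `[[`, numeric(1), "dG0")
  names(vals) <- vapply(conv, `[[`, character(1), "peak_id")
  structure(list(mean_dG0 = mean(vals),
                 sd_dG0 = if (length(vals) > 1) stats::sd(vals) else 0,
                 n_peaks = length(vals), dG0 = vals, fits = conv),
            class = "pooled_unfolding")
}

#' @export
print.pooled_unfolding <- function(x, ...) {
  cat(sprintf("Pooled unfolding free energy over %d peak(s): %.1f +- %.1f kJ/mol\n",
              x$n_peaks, x$mean_dG0, x$sd_dG0))
  invisible(x)
}
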