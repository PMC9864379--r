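## DSC thermogram processing: reference/baseline subtraction, melting
## point extraction, and the parabolic Tm(x) stability fit.

#' Excess heat capacity from sample and reference thermograms
#'
#' Subtracts the reference trace (if supplied either as a separate
#' thermogram or as a `cp_reference` column) and removes a linear chord
#' baseline anchored on the means of a pre- and a post-transition window.
#'
#' @param sample a `thermogram`.
#' @param reference optional reference-buffer `thermogram` on the same
#'   temperature grid; if `NULL` and `sample` has a `cp_reference`
#'   column, that column is used.
#' @param baseline `"chord"` (default) or `"none"`.
#' @param pre_window,post_window temperature intervals (degC, length-2)
#'   used as baseline anchors; defaults are the first and last 5 degC of
#'   the scan.  A warning is issued when a window overlaps the apparent
#'   transition peak.
#' @return a `thermogram` whose `cp` is the excess heat capacity.
#' @export
excess_heat_capacity <- function(sample, reference = NULL,
                                 baseline = c("chord", "none"),
                                 pre_window = NULL, post_window = NULL) {
  stopifnot(inherits(sample, "thermogram"))
  baseline <- match.arg(baseline)
  tt <- sample$temperature_C
  cp <- sample$cp
  if (!is.null(reference)) {
    stopifnot(inherits(reference, "thermogram"))
    if (nrow(reference) != nrow(sample) ||
        any(abs(reference$temperature_C - tt) > 1e-9))
      .stopf("sample and reference temperature grids differ")
    cp <- cp - reference$cp
  } else if ("cp_reference" %in% names(sample)) {
    cp <- cp - sample$cp_reference
  }
  if (baseline == "chord") {
    rng <- range(tt)
    if (is.null(pre_window)) pre_window <- c(rng[1], rng[1] + 5)
    if (is.null(post_window)) post_window <- c(rng[2] - 5, rng[2])
    pre <- tt >= pre_window[1] & tt <= pre_window[2]
    post <- tt >= post_window[1] & tt <= post_window[2]
    if (!any(pre) || !any(post))
      .stopf("baseline window contains no samples")
    t_peak <- tt[which.max(cp)]
    if ((t_peak >= pre_window[1] && t_peak <= pre_window[2]) ||
        (t_peak >= post_window[1] && t_peak <= post_window[2]))
      .warnf("baseline window overlaps the transition peak at %.1f degC",
             t_peak)
    x1 <- mean(tt[pre]); y1 <- mean(cp[pre])
    x2 <- mean(tt[post]); y2 <- mean(cp[post])
    slope <- (y2 - y1) / (x2 - x1)
    cp <- cp - (y1 + slope * (tt - x1))
  }
  out <- data.frame(temperature_C = tt, cp = cp)
  as_thermogram(out, dmso_vv_percent = attr(sample, "dmso_vv_percent"),
                scan_rate = attr(sample, "scan_rate"))
}

#' Extract the melting temperature from an excess heat capacity trace
#'
#' Tm is the temperature of the maximum of the excess heat capacity,
#' refined by a local quadratic fit over +-`half_window` grid points
#' around the grid maximum.  The reported uncertainty combines the
#' curvature of the local fit with the grid spacing.  A flat trace or a
#' secondary peak exceeding `secondary_frac` of the main peak raises an
#' error (single dominant endotherm required).
#'
#' @param thermogram a `thermogram` holding excess Cp (see
#'   [excess_heat_capacity()]).
#' @param half_window grid points on each side of the maximum used for the
#'   quadratic refinement.
#' @param secondary_frac multi-modality threshold as a fraction of the
#'   main peak height.
#' @return a `melt_point` list: `dmso_vv_percent`, `tm_C`, `tm_err_C`.
#' @export
extract_tm <- function(thermogram, half_window = 5L, secondary_frac = 0.5) {
  stopifnot(inherits(thermogram, "thermogram"))
  tt <- thermogram$temperature_C
  cp <- thermogram$cp
  n <- length(cp)
  if (n < 2L * half_window + 1L) .stopf("thermogram too short")
  peak_h <- max(cp) - stats::median(cp)
  spread <- max(cp) - min(cp)
  if (!is.finite(peak_h) || spread <= 0 || peak_h < 0.05 * spread ||
      spread < 1e-12 * max(abs(cp), 1))
    .stopf("no dominant endotherm: trace is flat")
  imax <- which.max(cp)

  ## secondary-peak check: local maxima outside the main peak window
  loc <- which(diff(sign(diff(cp))) == -2) + 1L
  loc <- loc[abs(loc - imax) > 2L * half_window]
  base <- stats::median(cp)
  if (length(loc) && any(cp[loc] - base > secondary_frac * (cp[imax] - base)))
    .stopf("multi-modal trace: secondary peak at %.1f degC exceeds %.0f%% of main",
           tt[loc[which.max(cp[loc])]], 100 * secondary_frac)

  idx <- max(1L, imax - half_window):min(n, imax + half_window)
  tw <- tt[idx] - tt[imax]
  fit <- stats::lm(cp[idx] ~ tw + I(tw^2))
  cf <- stats::coef(fit)
  h <- stats::median(diff(tt[idx]))
  if (!is.finite(cf[3]) || cf[3] >= 0) {
    tm <- tt[imax]
    tm_err <- h / 2
  } else {
    vertex <- -cf[2] / (2 * cf[3])
    if (abs(vertex) > half_window * h) vertex <- 0  # refinement ran away
    tm <- tt[imax] + vertex
    ## delta-method error of the vertex plus a grid-resolution floor
    V <- stats::vcov(fit)
    g <- c(0, -1 / (2 * cf[3]), cf[2] / (2 * cf[3]^2))
    var_v <- drop(t(g) %*% V %*% g)
    tm_err <- sqrt(max(var_v, 0) + (h / 2)^2 / 3)
  }
  structure(list(dmso_vv_percent = attr(thermogram, "dmso_vv_percent"),
                 tm_C = unname(tm), tm_err_C = unname(tm_err)),
            class = "melt_point")
}

#' Fit the parabolic dependence of Tm on DMSO content
#'
#' Ordinary least squares of `Tm(x) = p1*x^2 + p2*x + p3` with `x` in
#' v/v %.  At least 4 points are required; exactly 3 yields the
#' interpolating parabola with a warning (no residual degrees of
#' freedom).
#'
#' @param points either a list of `melt_point`s or a data frame with
#'   columns `dmso_vv_percent` and `tm_C`.
#' @return a `parabola_fit` list: `p1`, `p2`, `p3`, standard errors,
#'   `r_squared`, `n`.
#' @export
fit_tm_parabola <- function(points) {
  if (is.list(points) && !is.data.frame(points) &&
      all(vapply(points, inherits, logical(1), "melt_point"))) {
    points <- data.frame(
      dmso_vv_percent = vapply(points, `[[`, numeric(1), "dmso_vv_percent"),
      tm_C = vapply(points, `[[`, numeric(1), "tm_C"))
  }
  x <- points$dmso_vv_percent
  y <- points$tm_C
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) .stopf("need at least 4 melt points (3 to interpolate)")
  if (length(x) == 3L)
    .warnf("only 3 points: interpolating parabola, no residual degrees of freedom")
  fit <- stats::lm(y ~ x + I(x^2))
  cf <- stats::coef(fit)
  ## a perfect (noiseless) fit triggers a spurious summary.lm warning
  se <- tryCatch(suppressWarnings(sqrt(diag(stats::vcov(fit)))),
                 error = function(e) rep(NA_real_, 3))
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(list(p1 = unname(cf[3]), p2 = unname(cf[2]), p3 = unname(cf[1]),
                 p1_se = unname(se[3]), p2_se = unname(se[2]),
                 p3_se = unname(se[1]),
                 r_squared = r2, n = length(x)),
            class = "parabola_fit")
}

#' Predict Tm at a given DMSO content
#'
#' @param fit a `parabola_fit`, or any list/data frame providing `p1`,
#'   `p2`, `p3` (e.g. published coefficients).
#' @param x DMSO content in v/v % (vectorised).
#' @return predicted Tm in degC.
#' @export
#' @examples
#' # published stability curve of a protein melting at 93.2 degC in buffer
#' predict_tm(list(p1 = -2.98e-3, p2 = -59.0e-3, p3 = 93.2), 50)
predict_tm <- function(fit, x) {
  stopifnot(all(c("p1", "p2", "p3") %in% names(fit)))
  fit$p1 * x^2 + fit$p2 * x + fit$p3
}

#' @export
print.parabola_fit <- function(x, ...) {
  cat(sprintf("Tm(x) = %.4g x^2 + %.4g x + %.4g  (n = %d, R^2 = %.3f)\n",
              x$p1, x$p2, x$p3, x$n, x$r_squared))
  invisible(x)
}

#' @export
print.melt_point <- function(x, ...) {
  cat(sprintf("Tm = %.2f +- %.2f degC (DMSO %s v/v%%)\n", x$tm_C, x$tm_err_C,
              ifelse(is.na(x$dmso_vv_percent), "?", x$dmso_vv_percent)))
  invisible(x)
}
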