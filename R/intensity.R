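## Dual-delay intensity corrections: T2 back-extrapolation, dilution and
## pulse-calibration scaling, normalisation to the reference condition.

#' Back-extrapolate a dual-delay peak volume to zero transverse time
#'
#' Two HSQC spectra are recorded per titration point, differing only in
#' the time the proton magnetisation spends in the transverse plane (t1,
#' and its double t2 by default).  Assuming monoexponential T2 decay, the
#' zero-time intensity is recovered by log-linear extrapolation:
#' `I0 = exp(log(i1) + t1 * (log(i1) - log(i2)) / (t2 - t1))`.  For
#' `t2 = 2 t1` this reduces to `i1^2 / i2`.  This removes the
#' viscosity-driven T2 bias from the titration.
#'
#' @param i1,i2 peak volumes at the short and long delay (same arbitrary
#'   units, both > 0).
#' @param t1,t2 delays in ms, `t2 > t1 > 0`.
#' @return list with `i0` (extrapolated volume) and `t2_apparent_ms`
#'   (apparent transverse relaxation time `(t2-t1)/log(i1/i2)`; `Inf` when
#'   the signal does not decay).
#' @export
#' @examples
#' back_extrapolate_intensity(100, 50, 5.5, 11)  # i0 = 200
back_extrapolate_intensity <- function(i1, i2, t1 = 5.5, t2 = 11) {
  if (any(c(i1, i2) <= 0) || anyNA(c(i1, i2)))
    .stopf("peak volumes must be positive (got i1=%s, i2=%s)", i1, i2)
  if (!(t2 > t1 && t1 > 0))
    .stopf("delays must satisfy t2 > t1 > 0 (got t1=%s, t2=%s)", t1, t2)
  if (i2 >= i1) {
    .warnf("non-decaying signal (i2 >= i1): returning i1 without extrapolation")
    return(list(i0 = i1, t2_apparent_ms = Inf))
  }
  slope <- (log(i1) - log(i2)) / (t2 - t1)
  list(i0 = exp(log(i1) + t1 * slope), t2_apparent_ms = 1 / slope)
}

#' Correct a peak volume for solution-volume change
#'
#' A fixed solute amount diluted from `reference_volume` to
#' `solution_volume` loses signal proportionally; multiplying by
#' `solution_volume / reference_volume` compensates.
#'
#' @param intensity peak volume.
#' @param solution_volume solution volume at the measurement (uL).
#' @param reference_volume solution volume at the reference condition (uL).
#' @return corrected volume.
#' @export
volume_correct <- function(intensity, solution_volume, reference_volume) {
  if (any(c(solution_volume, reference_volume) <= 0))
    .stopf("solution volumes must be > 0")
  intensity * (solution_volume / reference_volume)
}

#' Correct a dual-delay titration table to relative intensities I/I0
#'
#' For every titration point of every peak: back-extrapolate the two
#' delays to zero time, compensate the solution-volume change relative to
#' the reference condition, divide by the per-point `pulse_scale`
#' calibration factor, and normalise to the corrected intensity at the
#' reference condition (by default the lowest-DMSO point of each series,
#' where the protein is folded).  The relative intensity at the reference
#' point is exactly 1.
#'
#' Points with missing or nonpositive volumes (vanished peaks at high
#' DMSO) are kept in the output flagged `censored = TRUE` with `i_rel =
#' NA`; they are excluded from downstream fitting.
#'
#' @param x a `titration_table` (one or several peaks).
#' @param reference_dmso DMSO v/v% of the reference condition; `NULL`
#'   (default) uses the lowest DMSO point of each series.
#' @return a `corrected_titration` data frame with one row per titration
#'   point and columns `peak_id`, `dmso_vv_percent`, `i0_extrap`,
#'   `t2_apparent_ms`, `i_rel`, `censored`.
#' @export
correct_series <- function(x, reference_dmso = NULL) {
  stopifnot(inherits(x, "titration_table"))
  out <- lapply(titration_series(x), function(ser) {
    .correct_one_series(ser, reference_dmso)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("corrected_titration", "data.frame")
  res
}

.correct_one_series <- function(ser, reference_dmso = NULL) {
  pts <- split(ser, ser$dmso_vv_percent)
  dmso <- as.numeric(names(pts))
  o <- order(dmso)
  pts <- pts[o]; dmso <- dmso[o]

  one_point <- function(p) {
    if (nrow(p) != 2L)
      .stopf("peak '%s' at %.3g%% DMSO has %d delay row(s); exactly 2 required",
             p$peak_id[1], p$dmso_vv_percent[1], nrow(p))
    p <- p[order(p$delay_ms), ]
    v <- p$volume_raw
    if (anyNA(v) || any(v <= 0))
      return(list(i0 = NA_real_, t2 = NA_real_, censored = TRUE,
                  vol = p$solution_volume_uL[1], pulse = p$pulse_scale[1]))
    be <- withCallingHandlers(
      back_extrapolate_intensity(v[1], v[2], p$delay_ms[1], p$delay_ms[2]),
      warning = function(w) invokeRestart("muffleWarning"))
    list(i0 = be$i0, t2 = be$t2_apparent_ms, censored = FALSE,
         vol = p$solution_volume_uL[1], pulse = p$pulse_scale[1])
  }
  corr <- lapply(pts, one_point)

  ref_idx <- if (is.null(reference_dmso)) 1L else {
    w <- which(abs(dmso - reference_dmso) < 1e-9)
    if (!length(w)) .stopf("reference DMSO %.3g%% not present in series '%s'",
                           reference_dmso, ser$peak_id[1])
    w[1]
  }
  ref <- corr[[ref_idx]]
  if (ref$censored)
    .stopf("reference point of peak '%s' is censored; cannot normalise",
           ser$peak_id[1])

  vols <- vapply(corr, `[[`, numeric(1), "vol")
  i0 <- vapply(corr, `[[`, numeric(1), "i0")
  t2app <- vapply(corr, `[[`, numeric(1), "t2")
  cens <- vapply(corr, `[[`, logical(1), "censored")
  pulse <- vapply(corr, `[[`, numeric(1), "pulse")

  i_corr <- volume_correct(i0, vols, ref$vol) / pulse
  i_ref <- i_corr[ref_idx]
  data.frame(peak_id = ser$peak_id[1],
             dmso_vv_percent = dmso,
             solution_volume_uL = vols,
             i0_extrap = i0,
             t2_apparent_ms = t2app,
             i_rel = i_corr / i_ref,
             censored = cens,
             stringsAsFactors = FALSE)
}
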