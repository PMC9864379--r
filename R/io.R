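## Readers/writers for the three tabular CSV dialects.  All downstream
## stages consume the validated classed tables returned here; no stage
## re-parses files.

.TITRATION_COLS <- c("peak_id", "dmso_vv_percent", "delay_ms",
                     "volume_raw", "solution_volume_uL")
.RELAX_COLS <- c("residue", "R1", "R1_err", "R2", "R2_err", "NOE", "NOE_err")

.read_csv_checked <- function(path, required, numeric_cols) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    .stopf("missing required column(s) in %s: %s",
           basename(path), paste(missing, collapse = ", "))
  for (col in intersect(numeric_cols, names(df))) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(conv) & !is.na(v) & nzchar(trimws(v)))
      if (length(bad))
        .stopf("non-numeric value in column '%s' of %s at data row %d: '%s'",
               col, basename(path), bad[1], v[bad[1]])
      df[[col]] <- conv
    }
  }
  df
}

#' Read an HSQC peak-volume titration table
#'
#' Expected CSV columns: `peak_id`, `dmso_vv_percent`, `delay_ms`,
#' `volume_raw`, `solution_volume_uL`, optionally `pulse_scale`
#' (dimensionless 1H pulse-calibration factor, defaults to 1).  Each
#' titration point appears as two rows, one per spin-echo delay.
#'
#' @param path CSV file path.
#' @return a `titration_table`: a data frame sorted by peak then ascending
#'   DMSO then delay, with one row per (peak, DMSO point, delay).
#' @export
read_titration_table <- function(path) {
  df <- .read_csv_checked(path, .TITRATION_COLS,
                          setdiff(.TITRATION_COLS, "peak_id"))
  as_titration_table(df)
}

#' Validate a data frame as a titration table
#'
#' @param df data frame with the columns documented in
#'   [read_titration_table()].
#' @return a `titration_table`.
#' @export
as_titration_table <- function(df) {
  missing <- setdiff(.TITRATION_COLS, names(df))
  if (length(missing))
    .stopf("missing required column(s): %s", paste(missing, collapse = ", "))
  if (!"pulse_scale" %in% names(df)) df$pulse_scale <- 1
  key <- paste(df$peak_id, df$dmso_vv_percent, df$delay_ms, sep = "|")
  if (anyDuplicated(key))
    .stopf("duplicated (peak_id, dmso_vv_percent, delay_ms) rows: %s",
           paste(unique(key[duplicated(key)]), collapse = "; "))
  if (any(df$dmso_vv_percent < 0 | df$dmso_vv_percent > 100))
    .stopf("dmso_vv_percent outside [0, 100]")
  if (any(df$delay_ms <= 0)) .stopf("delay_ms must be > 0")
  if (any(df$solution_volume_uL <= 0)) .stopf("solution_volume_uL must be > 0")
  df <- df[order(df$peak_id, df$dmso_vv_percent, df$delay_ms), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("titration_table", "data.frame")
  df
}

#' Write a titration table to CSV
#' @param x a `titration_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_titration_table <- function(x, path) {
  utils::write.csv(as.data.frame(x)[, c(.TITRATION_COLS, "pulse_scale")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Split a titration table into per-peak series
#' @param x a `titration_table`.
#' @return named list of single-peak `titration_table`s.
#' @export
titration_series <- function(x) {
  stopifnot(inherits(x, "titration_table"))
  out <- split(as.data.frame(x), x$peak_id)
  lapply(out, function(df) {
    rownames(df) <- NULL
    class(df) <- c("titration_table", "data.frame")
    df
  })
}

#' Read a per-residue 15N relaxation table
#'
#' Expected CSV columns: `residue`, `R1`, `R1_err`, `R2`, `R2_err`, `NOE`,
#' `NOE_err` (rates in s^-1, hetNOE as a dimensionless ratio).  The 15N
#' Larmor frequency is not stored in the file and must be supplied.
#'
#' @param path CSV file path.
#' @param field_15N_MHz 15N frequency of the measurement in MHz.
#' @return a `relaxation_dataset` data frame with attribute
#'   `field_15N_MHz`.
#' @export
read_relaxation_table <- function(path, field_15N_MHz) {
  df <- .read_csv_checked(path, .RELAX_COLS, setdiff(.RELAX_COLS, "residue"))
  as_relaxation_dataset(df, field_15N_MHz)
}

#' Validate a data frame as a relaxation dataset
#' @inheritParams read_relaxation_table
#' @param df data frame with the columns of [read_relaxation_table()].
#' @return a `relaxation_dataset`.
#' @export
as_relaxation_dataset <- function(df, field_15N_MHz) {
  missing <- setdiff(.RELAX_COLS, names(df))
  if (length(missing))
    .stopf("missing required column(s): %s", paste(missing, collapse = ", "))
  if (!is.numeric(field_15N_MHz) || field_15N_MHz <= 0)
    .stopf("field_15N_MHz must be a positive number")
  bad <- df$R1 <= 0 | df$R2 <= 0
  if (any(bad))
    .stopf("nonpositive relaxation rate for residue(s): %s",
           paste(df$residue[bad], collapse = ", "))
  high <- df$NOE > 1.25
  if (any(high))
    .stopf("NOE > 1.25 (unphysical for 15N) for residue(s): %s",
           paste(df$residue[high], collapse = ", "))
  if (anyDuplicated(df$residue))
    .stopf("duplicated residue label(s): %s",
           paste(unique(df$residue[duplicated(df$residue)]), collapse = ", "))
  rownames(df) <- NULL
  attr(df, "field_15N_MHz") <- as.numeric(field_15N_MHz)
  class(df) <- c("relaxation_dataset", "data.frame")
  df
}

#' Write a relaxation dataset to CSV
#' @param x a `relaxation_dataset`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_relaxation_table <- function(x, path) {
  utils::write.csv(as.data.frame(x)[, .RELAX_COLS], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a DSC thermogram
#'
#' Two dialects are accepted: two columns (`temperature_C`, `cp`) or three
#' columns with an instrument reference trace (`temperature_C`, `cp`,
#' `cp_reference`).  The temperature grid must be strictly increasing;
#' uniform spacing is not required.
#'
#' @param path CSV file path.
#' @param dmso_vv_percent DMSO content (v/v %) of the condition, used as a
#'   label downstream.
#' @param scan_rate scan rate in degC/h (metadata only).
#' @return a `thermogram` data frame with attributes `dmso_vv_percent` and
#'   `scan_rate`.
#' @export
read_thermogram <- function(path, dmso_vv_percent = NA_real_,
                            scan_rate = 200) {
  df <- .read_csv_checked(path, c("temperature_C", "cp"),
                          c("temperature_C", "cp", "cp_reference"))
  as_thermogram(df, dmso_vv_percent = dmso_vv_percent, scan_rate = scan_rate)
}

#' Validate a data frame as a thermogram
#' @inheritParams read_thermogram
#' @param df data frame with columns `temperature_C`, `cp` and optionally
#'   `cp_reference`.
#' @return a `thermogram`.
#' @export
as_thermogram <- function(df, dmso_vv_percent = NA_real_, scan_rate = 200) {
  missing <- setdiff(c("temperature_C", "cp"), names(df))
  if (length(missing))
    .stopf("missing required column(s): %s", paste(missing, collapse = ", "))
  dt <- diff(df$temperature_C)
  if (any(dt <= 0))
    .stopf("temperature grid not strictly increasing at index %d (%.4f -> %.4f)",
           which(dt <= 0)[1] + 1L,
           df$temperature_C[which(dt <= 0)[1]],
           df$temperature_C[which(dt <= 0)[1] + 1L])
  rownames(df) <- NULL
  attr(df, "dmso_vv_percent") <- as.numeric(dmso_vv_percent)
  attr(df, "scan_rate") <- as.numeric(scan_rate)
  class(df) <- c("thermogram", "data.frame")
  df
}

#' Write a thermogram to CSV
#' @param x a `thermogram`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_thermogram <- function(x, path) {
  cols <- intersect(c("temperature_C", "cp", "cp_reference"), names(x))
  utils::write.csv(as.data.frame(x)[, cols], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
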