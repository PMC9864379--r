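## NOE distance-restraint bookkeeping: sequence-range classification and
## per-residue restraint density.

#' Read a NOE restraint list
#'
#' Two-column CSV of residue index pairs (`residue_i`, `residue_j`).
#'
#' @param path CSV file path.
#' @param n_residues protein length; indices must lie in `[1, n_residues]`.
#' @return a `restraint_list` data frame with attribute `n_residues`.
#' @export
read_restraint_list <- function(path, n_residues) {
  df <- .read_csv_checked(path, c("residue_i", "residue_j"),
                          c("residue_i", "residue_j"))
  as_restraint_list(df, n_residues)
}

#' Validate a data frame as a restraint list
#' @inheritParams read_restraint_list
#' @param df data frame with columns `residue_i`, `residue_j`.
#' @return a `restraint_list`.
#' @export
as_restraint_list <- function(df, n_residues) {
  stopifnot(n_residues > 0)
  missing <- setdiff(c("residue_i", "residue_j"), names(df))
  if (length(missing))
    .stopf("missing required column(s): %s", paste(missing, collapse = ", "))
  idx <- c(df$residue_i, df$residue_j)
  if (any(idx < 1 | idx > n_residues | idx != round(idx)))
    .stopf("residue index out of range [1, %d]", n_residues)
  attr(df, "n_residues") <- as.integer(n_residues)
  class(df) <- c("restraint_list", "data.frame")
  df
}

#' Classify NOE restraints by sequence range
#'
#' Standard NMR convention on the separation `|i - j|`: intra-residue 0,
#' sequential 1, medium-range 2-4, long-range >= 5.  Classification is
#' symmetric in (i, j) and the fractions sum to 1.
#'
#' @param restraints a `restraint_list` (or data frame with `residue_i`,
#'   `residue_j`).
#' @return data frame with one row per class: `class`, `count`,
#'   `fraction`.
#' @export
classify_ranges <- function(restraints) {
  if (!nrow(restraints)) .stopf("empty restraint list")
  sep <- abs(restraints$residue_i - restraints$residue_j)
  cls <- cut(sep, breaks = c(-0.5, 0.5, 1.5, 4.5, Inf),
             labels = c("intra", "sequential", "medium", "long"))
  counts <- as.integer(table(cls))
  data.frame(class = levels(cls), count = counts,
             fraction = counts / sum(counts))
}

#' NOE restraints per residue
#'
#' @param n_restraints total number of restraints.
#' @param n_residues protein length.
#' @return restraints per residue, rounded to 2 decimals (the convention
#'   used when quoting restraint densities).
#' @export
#' @examples
#' restraint_density(956, 55)  # 17.38
restraint_density <- function(n_restraints, n_residues) {
  if (n_residues <= 0) .stopf("n_residues must be > 0")
  round(n_restraints / n_residues, 2)
}
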