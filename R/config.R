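#' Run configuration
#'
#' Central container for the physical constants and experiment settings
#' shared by the pipeline stages.  All temperatures are stored in kelvin;
#' DSC input/output stays in degrees Celsius and is converted explicitly at
#' the boundary.
#'
#' @param temperature_K sample temperature in kelvin (titrations were run
#'   at 310 K).
#' @param gas_constant gas constant in kJ mol^-1 K^-1.
#' @param dmso_density DMSO density in g/mL used for v/v% to molar
#'   conversion.
#' @param dmso_molar_mass DMSO molar mass in g/mol.
#' @param field_15N_MHz 15N Larmor frequency of the spectrometer in MHz
#'   (70.966 for a 700 MHz instrument, 50.684 for 500 MHz).
#' @param rng_seed integer seed for all stochastic stages (Monte-Carlo
#'   errors, synthetic data).
#' @param paths named list of input/output paths (free-form, used by the
#'   command-line interface).
#' @param options named list of per-stage options (free-form).
#'
#' @return an object of class `dmso_config` (a validated named list).
#' @seealso [read_run_config()]
#' @export
run_config <- function(temperature_K = 310,
                       gas_constant = 8.314e-3,
                       dmso_density = 1.10,
                       dmso_molar_mass = 78.13,
                       field_15N_MHz = 70.966,
                       rng_seed = 1L,
                       paths = list(),
                       options = list()) {
  if (!is.numeric(temperature_K) || temperature_K <= 0)
    .stopf("temperature_K must be > 0 (kelvin), got %s", temperature_K)
  if (!is.numeric(dmso_density) || dmso_density <= 0)
    .stopf("dmso_density must be > 0 (g/mL)")
  if (!is.numeric(dmso_molar_mass) || dmso_molar_mass <= 0)
    .stopf("dmso_molar_mass must be > 0 (g/mol)")
  if (!is.numeric(gas_constant) || gas_constant <= 0)
    .stopf("gas_constant must be > 0 (kJ/mol/K)")
  if (!is.numeric(field_15N_MHz) || field_15N_MHz <= 0)
    .stopf("field_15N_MHz must be > 0 (MHz)")
  rng_seed <- as.integer(rng_seed)
  if (is.na(rng_seed)) .stopf("rng_seed must be an integer")
  structure(
    list(temperature_K = as.numeric(temperature_K),
         gas_constant = as.numeric(gas_constant),
         dmso_density = as.numeric(dmso_density),
         dmso_molar_mass = as.numeric(dmso_molar_mass),
         field_15N_MHz = as.numeric(field_15N_MHz),
         rng_seed = rng_seed,
         paths = paths,
         options = options),
    class = "dmso_config")
}

#' Read a run configuration from a JSON file
#'
#' Unknown top-level keys are a hard error so that typos in a config file
#' never fall back to defaults silently.
#'
#' @param path path to a JSON file whose keys match the arguments of
#'   [run_config()].
#' @return a `dmso_config` object.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) .stopf("config file not found: %s", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    .stopf("unknown config key(s): %s (known: %s)",
           paste(bad, collapse = ", "), paste(known, collapse = ", "))
  do.call(run_config, raw)
}

#' @export
print.dmso_config <- function(x, ...) {
  cat("dmsofold run configuration\n")
  cat(sprintf("  temperature      : %.1f K\n", x$temperature_K))
  cat(sprintf("  15N frequency    : %.3f MHz\n", x$field_15N_MHz))
  cat(sprintf("  DMSO density     : %.3f g/mL, M = %.2f g/mol\n",
              x$dmso_density, x$dmso_molar_mass))
  cat(sprintf("  RNG seed         : %d\n", x$rng_seed))
  invisible(x)
}
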