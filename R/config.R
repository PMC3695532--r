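# Structured configuration files and result serialization.
#
# Config schema (YAML, units in the key names to prevent MHz/kHz mistakes):
#
#   system:
#     preset: glycine_amine          # or explicit parameters:
#     cq_mhz: 1.18
#     eta_q: 0.54
#     dipole_khz: -0.716
#     euler_qd_deg: [0, 0, 0]
#     j_hz: 0
#     larmor_13c_mhz: 150
#     larmor_14n_mhz: 43.5
#     mas_khz: 25                    # required
#     rotor_angle_deg: 54.7356
#     offset_n_khz: 0
#     offset_c_khz: 0
#   experiment:
#     tau_n_ms: 2
#     nu1_n_khz: 35
#     offset_n_khz: 0
#     selection: SQ
#     delta_t1_periods: 1
#     t1_increments: 1
#     n_steps: 200
#   powder:
#     n_orientations: 1154
#   output_dir: results
#   verbose: false

.sys_keys <- c("preset", "cq_mhz", "eta_q", "dipole_khz", "euler_qd_deg",
               "j_hz", "larmor_13c_mhz", "larmor_14n_mhz", "mas_khz",
               "rotor_angle_deg", "offset_n_khz", "offset_c_khz")
.exp_keys <- c("tau_n_ms", "nu1_n_khz", "offset_n_khz", "selection",
               "delta_t1_periods", "t1_increments", "n_steps")

.check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad)) {
    abort(sprintf("unknown key(s) in `%s`: %s", where,
                  paste(bad, collapse = ", ")))
  }
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration (schema documented in the package source and
#' the methods vignette), applies defaults, rejects unknown keys, and
#' materialises the [spin_system()] and [hnc_experiment()] it describes.
#'
#' @param path Path to a YAML file.
#' @return A `run_config`: list with `system`, `experiment`, `powder_n`,
#'   `output_dir`, `verbose`, and the validated raw list in `raw`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  .check_keys(raw, c("system", "experiment", "powder", "output_dir",
                     "verbose"), "config")
  sys <- raw$system %||% abort("missing `system` block.")
  .check_keys(sys, .sys_keys, "system")
  if (is.null(sys$mas_khz)) abort("missing required field `system.mas_khz`.")
  if (!is.null(sys$preset)) {
    extra <- sys[setdiff(names(sys), "preset")]
    system <- do.call(preset_system, c(list(name = sys$preset), extra))
  } else {
    for (f in c("cq_mhz", "eta_q", "dipole_khz")) {
      if (is.null(sys[[f]])) abort(sprintf("missing required field `system.%s`.", f))
    }
    system <- do.call(spin_system, sys)
  }
  ex <- raw$experiment %||% list()
  .check_keys(ex, .exp_keys, "experiment")
  experiment <- do.call(hnc_experiment, ex)
  pw <- raw$powder %||% list()
  .check_keys(pw, "n_orientations", "powder")
  structure(
    list(system = system, experiment = experiment,
         powder_n = as.integer(pw$n_orientations %||% 1154L),
         output_dir = raw$output_dir %||% ".",
         verbose = isTRUE(raw$verbose), raw = raw),
    class = "run_config"
  )
}

#' Write a run configuration back to YAML
#'
#' Serialisation round-trips losslessly with [load_config()].
#'
#' @param config A `run_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(config$raw, path)
  invisible(path)
}

#' Write simulation results with provenance
#'
#' Serialises an `hnc_result` (JSON: efficiency and per-order amplitudes),
#' an `hnc_scan`/`hnc_grid` (CSV: one row per grid point) or an
#' `nmr_spectrum`/`nmr_spectrum2d` (CSV: axis and intensity) together with
#' the software version and, when available, an echo of the configuration.
#'
#' @param result A result object.
#' @param dir Output directory (created if missing).
#' @param stem File-name stem; default derived from the result class.
#' @param config Optional `run_config` echoed into the payload.
#' @return A tibble manifest with columns `file` and `type`.
#' @export
write_results <- function(result, dir, stem = NULL, config = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  version <- as.character(packageVersion("spinspy"))
  cfg_echo <- if (!is.null(config)) config$raw else NULL
  files <- character()
  types <- character()
  if (inherits(result, "hnc_result")) {
    stem <- stem %||% "efficiency"
    payload <- list(
      efficiency = result$efficiency,
      selected_amplitude = result$selected_amplitude,
      selection = result$selection,
      coherence_amplitudes = setNames(as.list(result$amplitudes$amplitude),
                                      as.character(result$amplitudes$order)),
      powder_n = result$powder_n,
      second_order = result$second_order,
      spinspy_version = version,
      config = cfg_echo
    )
    f <- file.path(dir, paste0(stem, ".json"))
    jsonlite::write_json(payload, f, auto_unbox = TRUE, digits = NA,
                         null = "null")
    files <- c(files, f); types <- c(types, "json")
  } else if (inherits(result, c("hnc_scan", "hnc_grid", "nmr_spectrum",
                                "nmr_spectrum2d"))) {
    stem <- stem %||% sub("^hnc_", "scan_", class(result)[1])
    f <- file.path(dir, paste0(stem, ".csv"))
    con <- file(f, "w")
    writeLines(sprintf("# spinspy %s", version), con)
    if (!is.null(attr(result, "scanned"))) {
      writeLines(sprintf("# scanned: %s; powder_n: %s", attr(result, "scanned"),
                         attr(result, "powder_n")), con)
    }
    df <- as.data.frame(result)
    write.csv(df, con, row.names = FALSE)
    close(con)
    files <- c(files, f); types <- c(types, "csv")
  } else {
    abort("unsupported result type.")
  }
  tibble(file = files, type = types)
}
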