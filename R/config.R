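# Run configuration: one nested object carrying every tunable of the
# pipeline, serializable to/from YAML without loss.

#' Pipeline run configuration
#'
#' Collects the instrument settings, generator rules, peak-fit thresholds,
#' indexing tolerances, EDP sign/correction tables and tilt reference into
#' one object with documented defaults.  The configuration round-trips
#' losslessly through [write_run_config()] / [read_run_config()].
#'
#' @param instrument SAXS [instrument_config()].
#' @param rules generator [phase_rules()].
#' @param peakfit list: `smoothness`, `asymmetry` (baseline),
#'   `min_prominence_sigmas`, `smooth_window`, `min_separation`
#'   (detection), `waxs_shape` (fit shape for WAXS peaks).
#' @param lamellar list: `rel_tolerance`, `max_order` (indexing),
#'   `coex_min_rel_dd` (minimum relative d difference for coexistence),
#'   `sharp_fwhm` (sharp/broad width threshold, inverse Angstrom).
#' @param edp list: `lorentz_exponent`, `n_z`, `factor_table`.
#' @param tilt a [tilt_reference()].
#' @param grid list: `compositions`, `temperatures` for simulation.
#' @param seed master RNG seed.
#' @param out_dir output directory for the command-line workflow.
#' @param log_level `"quiet"`, `"info"` or `"debug"`.
#' @export
run_config <- function(instrument = instrument_config("SAXS"),
                       rules = phase_rules(),
                       peakfit = list(),
                       lamellar = list(),
                       edp = list(),
                       tilt = tilt_reference(),
                       grid = list(),
                       seed = 1L, out_dir = ".",
                       log_level = "info") {
  pf_def <- list(smoothness = 1e7, asymmetry = 1e-3,
                 min_prominence_sigmas = 5, smooth_window = 11L,
                 min_separation = 8L, waxs_shape = "gaussian")
  lm_def <- list(rel_tolerance = 0.015, max_order = 6L,
                 coex_min_rel_dd = 0.05, sharp_fwhm = 0.0022)
  edp_def <- list(lorentz_exponent = 2, n_z = 513L,
                  factor_table = default_correction_table())
  grid_def <- list(compositions = c(0, 0.1, 0.25, 0.5, 1, 2.5),
                   temperatures = seq(16, 44, by = 4))
  cfg <- structure(list(
    instrument = instrument, rules = rules,
    peakfit = utils::modifyList(pf_def, peakfit),
    lamellar = utils::modifyList(lm_def, lamellar),
    edp = utils::modifyList(edp_def, edp),
    tilt = tilt,
    grid = utils::modifyList(grid_def, grid),
    seed = as.integer(seed), out_dir = out_dir,
    log_level = match.arg(log_level, c("quiet", "info", "debug"))),
    class = "run_config")
  validate_phase_rules(cfg$rules)
  cfg
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  cat(sprintf("  seed %d, out_dir '%s', log %s\n", x$seed, x$out_dir,
              x$log_level))
  cat(sprintf("  instrument: %s, q in [%.3g, %.3g], %d bins, seed %d\n",
              x$instrument$mode, x$instrument$q_min, x$instrument$q_max,
              x$instrument$n_bins, x$instrument$seed))
  cat(sprintf("  grid: %d compositions x %d temperatures\n",
              length(x$grid$compositions), length(x$grid$temperatures)))
  invisible(x)
}

#' Write / read a run configuration (YAML)
#'
#' @param config a [run_config()].
#' @param path file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  plain <- list(
    instrument = unclass(config$instrument),
    rules = unclass(config$rules),
    peakfit = config$peakfit,
    lamellar = c(config$lamellar),
    edp = list(lorentz_exponent = config$edp$lorentz_exponent,
               n_z = config$edp$n_z,
               factor_table = as.list(config$edp$factor_table)),
    tilt = unclass(config$tilt)[c("d_ref", "d_w_ref", "theta_ref")],
    grid = config$grid,
    seed = config$seed, out_dir = config$out_dir,
    log_level = config$log_level)
  yaml::write_yaml(plain, path, precision = 15)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  inst <- do.call(instrument_config, c(list(mode = raw$instrument$mode),
    raw$instrument[setdiff(names(raw$instrument), "mode")]))
  rules <- do.call(phase_rules, lapply(raw$rules, unlist))
  ft <- unlist(raw$edp$factor_table)
  run_config(
    instrument = inst, rules = rules,
    peakfit = raw$peakfit,
    lamellar = raw$lamellar,
    edp = list(lorentz_exponent = raw$edp$lorentz_exponent,
               n_z = raw$edp$n_z, factor_table = ft),
    tilt = do.call(tilt_reference, raw$tilt),
    grid = lapply(raw$grid, unlist),
    seed = raw$seed, out_dir = raw$out_dir,
    log_level = raw$log_level)
}
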