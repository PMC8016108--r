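#' @title Configuration files, fixtures and table output
#' @description
#' YAML run configurations with explicit unit suffixes, round-trip
#' serialization, named preset ("fixture") configs for the standard
#' simulations, and CSV/JSON writers used by the command-line interface.
#' @name cli_io
NULL

# YAML keys of a run config; every parameter carries its unit in the name.
config_param_keys <- c(
  "vibrissa_modulus_GPa", "vibrissa_radius_um", "follicle_length_mm",
  "k1_N_per_m", "k2_N_per_m", "k3_N_per_m", "k4_N_per_m",
  "k5_N_per_m", "k6_N_per_m",
  "spring_positions", "wall_rigidity_factor", "external_segment_frac",
  "deflection_angle_deg", "skin_modulus_MPa", "beta_mode"
)
config_other_keys <- c("rs_bound_um", "n_samples", "sweep")

params_to_config <- function(params) {
  list(
    vibrissa_modulus_GPa = pa_to_gpa(params$vibrissa_modulus),
    vibrissa_radius_um = m_to_um(params$vibrissa_radius),
    follicle_length_mm = m_to_mm(params$follicle_length),
    k1_N_per_m = params$k1, k2_N_per_m = params$k2, k3_N_per_m = params$k3,
    k4_N_per_m = params$k4, k5_N_per_m = params$k5, k6_N_per_m = params$k6,
    spring_positions = params$spring_positions,
    wall_rigidity_factor = params$wall_rigidity_factor,
    external_segment_frac = params$external_segment_frac,
    deflection_angle_deg = rad_to_deg(params$deflection_angle),
    skin_modulus_MPa = params$skin_modulus / 1e6,
    beta_mode = params$beta_mode
  )
}

config_to_params <- function(cfg) {
  d <- params_to_config(follicle_params())   # defaults, user units
  for (nm in intersect(names(cfg), config_param_keys)) {
    val <- cfg[[nm]]
    # YAML readers return plain-notation exponents ("2.5e5") as strings
    if (nm != "beta_mode") val <- as.numeric(unlist(val))
    if (anyNA(val)) stop("config: non-numeric value for key ", nm)
    d[[nm]] <- val
  }
  follicle_params(
    vibrissa_modulus_GPa = d$vibrissa_modulus_GPa,
    vibrissa_radius_um = d$vibrissa_radius_um,
    follicle_length_mm = d$follicle_length_mm,
    k1 = d$k1_N_per_m, k2 = d$k2_N_per_m, k3 = d$k3_N_per_m,
    k4 = d$k4_N_per_m, k5 = d$k5_N_per_m, k6 = d$k6_N_per_m,
    spring_positions = as.numeric(d$spring_positions),
    wall_rigidity_factor = d$wall_rigidity_factor,
    external_segment_frac = d$external_segment_frac,
    deflection_angle_deg = d$deflection_angle_deg,
    skin_modulus_MPa = d$skin_modulus_MPa,
    beta_mode = d$beta_mode
  )
}

#' Load a run configuration
#'
#' Reads a YAML config with unit-suffixed keys (see [save_config()] for the
#' schema). Missing keys take the default parameter values; an empty file
#' yields the full default configuration. Unknown keys raise a warning;
#' anatomical-constraint violations of the resulting parameter set are
#' reported as warnings but do not stop the load.
#'
#' @param path Path to a YAML file.
#' @return An object of class `run_config`: list with `params`
#'   (`follicle_params`), `rs_bound_um`, `n_samples`, and `sweep` (list of
#'   sweep settings or `NULL`).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  if (!is.list(cfg)) stop("config: top level must be a YAML mapping")
  unknown <- setdiff(names(cfg), c(config_param_keys, config_other_keys))
  if (length(unknown))
    warning("config: ignoring unknown keys: ",
            paste(unknown, collapse = ", "))
  params <- config_to_params(cfg)
  viol <- validate_anatomical_constraints(params)
  for (v in viol) warning("config: anatomical constraint: ", v)
  structure(
    list(params = params,
         rs_bound_um = if (is.null(cfg$rs_bound_um)) 4.8
                       else as.numeric(cfg$rs_bound_um),
         n_samples = if (is.null(cfg$n_samples)) 201L
                     else as.integer(cfg$n_samples),
         sweep = cfg$sweep),
    class = "run_config"
  )
}

#' Save a run configuration
#'
#' Writes the config back to YAML in user units with unit-suffixed keys;
#' `load_config(save_config(cfg, path))` reproduces the configuration.
#'
#' @param config A `run_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  out <- params_to_config(config$params)
  out$rs_bound_um <- config$rs_bound_um
  out$n_samples <- config$n_samples
  if (!is.null(config$sweep)) out$sweep <- config$sweep
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config> rs_bound = ", x$rs_bound_um, " um, n_samples = ",
      x$n_samples,
      if (!is.null(x$sweep)) paste0(", sweep: ", x$sweep$kind), "\n",
      sep = "")
  print(x$params)
  invisible(x)
}

#' Write the standard preset configurations
#'
#' Emits one YAML config per standard simulation: the default parameter set,
#' the k1-sensitivity grid, the (k2, k3) feasibility grid, the
#' external-support sweep, the blood-pressure sweep, and the
#' relaxed-bound (12 um) variant of the feasibility map.
#'
#' @param out_dir Writable directory (created if needed).
#' @return Character vector of the files written.
#' @export
generate_fixtures <- function(out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  base <- structure(list(params = follicle_params(), rs_bound_um = 4.8,
                         n_samples = 201L, sweep = NULL),
                    class = "run_config")
  presets <- list(
    paper_default = base,
    fig5_grid = within_config(base, sweep = list(
      kind = "k1_sensitivity", k1_min_N_per_m = 1e2, k1_max_N_per_m = 1e6,
      n_k1 = 9, k2_values_N_per_m = log_space(1e3, 1e6, 4),
      k3_values_N_per_m = log_space(1e4, 1e6, 4))),
    fig6_grid = within_config(base, sweep = list(
      kind = "k2k3_feasibility", k_min_N_per_m = 1e3, k_max_N_per_m = 1e6,
      n_per_axis = 13)),
    fig7_support = within_config(base, sweep = list(
      kind = "external_support", total_min_N_per_m = 1e4,
      total_max_N_per_m = 1e5, n_total = 9,
      ratio_min = 1 / 20, ratio_max = 20, n_ratio = 9)),
    fig8_pressure = within_config(base, sweep = list(
      kind = "blood_pressure", k3_min_N_per_m = 1e5, k3_max_N_per_m = 1e6,
      n_k3 = 9)),
    relaxed_12um = within_config(
      within_config(base, rs_bound_um = 12),
      sweep = list(kind = "k2k3_feasibility", k_min_N_per_m = 1e3,
                   k_max_N_per_m = 1e6, n_per_axis = 13))
  )
  files <- character(0)
  for (nm in names(presets)) {
    f <- file.path(out_dir, paste0(nm, ".yaml"))
    save_config(presets[[nm]], f)
    files <- c(files, f)
  }
  files
}

within_config <- function(config, ...) {
  upd <- list(...)
  for (nm in names(upd)) config[[nm]] <- upd[[nm]]
  config
}

#' Write deformation profiles as CSV
#'
#' Columns: `x_mm`, `u_um`, `f_um`, `r_um`, `V_N`.
#'
#' @param profiles A `deformation_profiles`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profiles_csv <- function(profiles, path) {
  stopifnot(inherits(profiles, "deformation_profiles"))
  df <- data.frame(x_mm = m_to_mm(profiles$x), u_um = m_to_um(profiles$u),
                   f_um = m_to_um(profiles$f), r_um = m_to_um(profiles$r),
                   V_N = profiles$V)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a sweep table as CSV plus a JSON metadata sidecar
#'
#' The CSV holds the tidy per-grid-point table; `<path>.meta.json` records
#' the sweep kind, grid definition, base parameters (user units) and package
#' version, so a run can be reproduced exactly.
#'
#' @param result A `sweep_result`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(result, path) {
  stopifnot(inherits(result, "sweep_result"))
  utils::write.csv(result$table, path, row.names = FALSE)
  meta <- list(kind = result$kind, grid = result$grid,
               base_params = params_to_config(result$base),
               version = result$version)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
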