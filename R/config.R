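#' Default run configuration
#'
#' All tunables of the pipeline in one list, with the conventional defaults:
#' cDL constant c = 0.04 um/keV, 3 mm isotropic grid, PTV interval
#' [0.95, 1.07] x prescription (the 95% level is the coverage criterion
#' level; at least 98% of the PTV must receive it), OAR percentile fraction
#' 0.30 (cDL30), AMS relaxation 1 with 200 iterations, and the 2 mm / 3.5%
#' robustness protocol.
#'
#' @return a nested list of class `run_config`
#' @export
default_config <- function() {
  structure(list(
    phantom = list(dims = c(20L, 20L, 20L), spacing = 3,
                   target_radius = 18, oar_radius = 6, seed = 42L),
    beam = list(peak_width_mm = 5, rise_width_mm = 14, entrance_ratio = 0.35,
                sigma0_mm = 4, sigma_k = 0.03, let_entrance = 2,
                let_distal = 10, density_scale = 1, sparsity_floor = 1e-4),
    plan = list(prescription_Gy = 74, gantry_deg = c(90, 270),
                spot_spacing_mm = 9, layer_spacing_mm = 9),
    cdl = list(c = 0.04, dose_floor_frac = 1e-6),
    constraints = list(lower_frac = 0.95, upper_frac = 1.07,
                       ptv_weight = 100, oar_weight = 1, fraction = 0.30),
    solver = list(algorithm = "ams", lambda = 1, iterations = 200L,
                  tol_frac = 1e-4, alpha = 0.99, eta = 0.99, n_perturb = 1L,
                  seed = 1L),
    robustness = list(shift_mm = 2, density_pct = 3.5)
  ), class = "run_config")
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Load a YAML run configuration
#'
#' Reads a YAML file, overlays it on [default_config()] and validates all
#' parameter domains at load time (c > 0, 0 < lambda <= 2, alpha and eta in
#' (0, 1), constraint fractions ordered, positive prescription, ...).
#'
#' @param path YAML file; missing/NULL returns the validated defaults
#' @return a validated `run_config`
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
    cfg <- merge_config(cfg, yaml::read_yaml(path))
  }
  validate_config(cfg)
}

#' Validate a run configuration
#' @param cfg a `run_config` list
#' @return the config, invisibly classed, or an error naming the bad field
#' @export
validate_config <- function(cfg) {
  with(cfg, {
    if (cdl$c <= 0) stop("cdl$c must be > 0")
    if (solver$lambda <= 0 || solver$lambda > 2)
      stop("solver$lambda must satisfy 0 < lambda <= 2")
    if (solver$alpha <= 0 || solver$alpha >= 1)
      stop("solver$alpha must lie in (0, 1)")
    if (solver$eta <= 0 || solver$eta >= 1)
      stop("solver$eta must lie in (0, 1)")
    if (solver$iterations < 1) stop("solver$iterations must be >= 1")
    if (!solver$algorithm %in% c("ams", "sup"))
      stop("solver$algorithm must be 'ams' or 'sup'")
    if (plan$prescription_Gy <= 0) stop("plan$prescription_Gy must be > 0")
    if (!(constraints$lower_frac > 0 && constraints$lower_frac <= 1 &&
          constraints$upper_frac >= 1))
      stop("need 0 < lower_frac <= 1 <= upper_frac")
    if (constraints$fraction <= 0 || constraints$fraction >= 1)
      stop("constraints$fraction must lie in (0, 1)")
    if (any(cfg$phantom$dims < 1) || cfg$phantom$spacing <= 0)
      stop("phantom dims/spacing invalid")
  })
  structure(cfg, class = "run_config")
}

#' Echo a configuration verbatim to a YAML file
#' @param cfg a `run_config`
#' @param path output YAML path
#' @return the path, invisibly
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
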