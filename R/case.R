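#' Build the full synthetic reoptimization case from a configuration
#'
#' One call that assembles everything the optimization phase consumes:
#' phantom grid and structures, beam model, spot plan, influence matrices,
#' the prescription-scaled uniform baseline fluence, its forward
#' calculation, and the combined constraint set (target dose intervals plus
#' OAR cDL30 upper bounds extracted from the baseline). This is the same
#' code path the command-line interface runs; tests and the acceptance
#' script call it directly.
#'
#' @param cfg a `run_config` (default [default_config()])
#' @return list with `grid`, `structures`, `params` (beam model), `spots`,
#'   `infl`, `x0` (baseline fluence), `baseline` (its [forward_plan()]),
#'   `cset` (the [constraint_set()]), `sys` (the [constraint_system()]) and
#'   `cfg`
#' @export
synthetic_case <- function(cfg = default_config()) {
  cfg <- validate_config(cfg)
  ph <- make_phantom(cfg$phantom$dims, cfg$phantom$spacing,
                     layout_sphere_oar(
                       center = cfg$phantom$dims * cfg$phantom$spacing / 2,
                       target_radius = cfg$phantom$target_radius,
                       oar_radius = cfg$phantom$oar_radius),
                     seed = cfg$phantom$seed)
  params <- do.call(beam_model, cfg$beam)
  spots <- plan_spots(ph$grid, ph$structures, params,
                      gantry_deg = cfg$plan$gantry_deg,
                      spot_spacing_mm = cfg$plan$spot_spacing_mm,
                      layer_spacing_mm = cfg$plan$layer_spacing_mm)
  infl <- simulate_influence(ph$grid, spots, params)
  rx <- cfg$plan$prescription_Gy
  x0 <- scale_to_prescription(infl, ph$structures$masks$PTV, rx)
  floorGy <- cfg$cdl$dose_floor_frac * rx
  baseline <- forward_plan(infl, x0, c = cfg$cdl$c, dose_floor = floorGy)
  cset <- build_constraints(baseline, ph$structures, rx,
                            lower_frac = cfg$constraints$lower_frac,
                            upper_frac = cfg$constraints$upper_frac,
                            ptv_weight = cfg$constraints$ptv_weight,
                            fraction = cfg$constraints$fraction)
  sys <- constraint_system(infl, cset, c = cfg$cdl$c)
  list(grid = ph$grid, structures = ph$structures, params = params,
       spots = spots, infl = infl, x0 = x0, baseline = baseline,
       cset = cset, sys = sys, cfg = cfg)
}

#' Reoptimize a synthetic case with AMS or its superiorization
#'
#' @param case output of [synthetic_case()]
#' @param algorithm "ams" (feasibility-seeking only) or "sup"
#'   (superiorization)
#' @return the solver result list ([feasibility_seek()] /[superiorize()])
#'   plus elements `forward` (the reoptimized [forward_plan()]) and
#'   `metrics` (its [plan_metrics()])
#' @export
reoptimize <- function(case, algorithm = case$cfg$solver$algorithm) {
  s <- case$cfg$solver
  rx <- case$cfg$plan$prescription_Gy
  ams <- ams_params(lambda = s$lambda, max_iterations = s$iterations,
                    tol = s$tol_frac * rx)
  res <- if (algorithm == "sup") {
    superiorize(case$x0, case$sys, ams,
                sup_params(alpha = s$alpha, eta = s$eta,
                           n_perturb = s$n_perturb))
  } else {
    feasibility_seek(case$x0, case$sys, ams)
  }
  res$forward <- forward_plan(case$infl, res$x, c = case$cfg$cdl$c,
                              dose_floor = case$cfg$cdl$dose_floor_frac * rx)
  res$metrics <- plan_metrics(res$forward, case$structures, rx)
  res
}
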