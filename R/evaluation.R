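#' Per-structure plan metrics
#'
#' Computes, for every structure in the set, the coverage and LET-burden
#' statistics used to compare plans: V95 (% of the structure volume
#' receiving at least 95% of the prescription), dose min/mean/max (Gy), cDL
#' min/mean/max (Gy) and cDL30 (the cDL value received by 30% of the
#' structure volume, via the step-convention volume-histogram percentile).
#'
#' @param fw a [forward_plan()] result
#' @param structures a [structure_set()] on the same grid
#' @param prescription_Gy prescription dose (Gy)
#' @return a data frame of class `plan_metrics`, one row per structure
#' @export
plan_metrics <- function(fw, structures, prescription_Gy) {
  if (!identical(structures$grid$dims, fw$grid$dims))
    stop("structure set and forward result are on different grids")
  rows <- lapply(names(structures$masks), function(nm) {
    vox <- which(as.vector(structures$masks[[nm]]))
    d <- fw$dose[vox]; q <- fw$cdl[vox]
    data.frame(
      structure = nm, role = structures$roles[[nm]], n_voxels = length(vox),
      V95 = 100 * mean(d >= 0.95 * prescription_Gy),
      D_min = min(d), D_mean = mean(d), D_max = max(d),
      cDL_min = min(q), cDL_mean = mean(q), cDL_max = max(q),
      cDL30 = vh_percentile(cumulative_vh(q, structure = nm), 0.30))
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(out) <- c("plan_metrics", "data.frame")
  out
}

#' Difference report between two plans
#'
#' Per-structure absolute deltas (after - before) and relative deltas
#' ((after - before) / before) for every numeric metric. Relative deltas
#' where the before value is not strictly positive are reported as NA
#' (flagged, not computed). Absolute deltas are antisymmetric under swapping
#' the arguments.
#'
#' @param before,after [plan_metrics()] frames over the same structures
#' @return list with data frames `absolute` and `relative`
#' @export
compare_plans <- function(before, after) {
  if (!identical(before$structure, after$structure))
    stop("the two plans cover different structure sets")
  num <- vapply(before, is.numeric, logical(1)) & names(before) != "n_voxels"
  ab <- after[, num, drop = FALSE] - before[, num, drop = FALSE]
  rel <- ab / before[, num, drop = FALSE]
  rel[!(before[, num, drop = FALSE] > 0)] <- NA
  ab <- cbind(structure = before$structure, ab)
  rel <- cbind(structure = before$structure, rel)
  list(absolute = ab, relative = rel)
}

#' The canonical nine-scenario robustness protocol
#'
#' One nominal scenario, six single-axis geometric shifts of +/- `shift_mm`,
#' and two density rescalings of +/- `density_pct` percent: nine scenarios
#' in total, matching the clinical setup/range robustness protocol.
#'
#' @param shift_mm magnitude of the setup shifts (default 2 mm)
#' @param density_pct magnitude of the density perturbation in percent
#'   (default 3.5)
#' @return data frame with columns `label`, `dx`, `dy`, `dz` (mm) and
#'   `density` (scale factor)
#' @export
robustness_scenarios <- function(shift_mm = 2, density_pct = 3.5) {
  data.frame(
    label = c("nominal",
              "shift+x", "shift-x", "shift+y", "shift-y", "shift+z", "shift-z",
              paste0("density-", density_pct, "%"),
              paste0("density+", density_pct, "%")),
    dx = c(0, shift_mm, -shift_mm, 0, 0, 0, 0, 0, 0),
    dy = c(0, 0, 0, shift_mm, -shift_mm, 0, 0, 0, 0),
    dz = c(0, 0, 0, 0, 0, shift_mm, -shift_mm, 0, 0),
    density = c(rep(1, 7), 1 - density_pct / 100, 1 + density_pct / 100))
}

#' Re-evaluate a fixed plan under the robustness scenarios
#'
#' For each scenario the influence matrices are re-simulated (spot lateral
#' positions shifted for setup errors; depths rescaled for density errors),
#' the forward calculation repeated with the *fixed* fluence, and the plan
#' metrics recomputed. Returns all per-scenario metrics and the
#' per-structure min/max envelope across scenarios (the shaded robustness
#' band).
#'
#' @param x fixed fluence vector of the plan under evaluation
#' @param grid a [voxel_grid()]
#' @param structures a [structure_set()]
#' @param spots a [spot_list()]
#' @param params a [beam_model()] (its `density_scale` is multiplied by the
#'   scenario factor)
#' @param prescription_Gy prescription dose (Gy)
#' @param scenarios scenario table (default [robustness_scenarios()])
#' @param c cDL scaling constant
#' @param dose_floor Gy floor for LET_d reporting
#' @return list with `metrics` (named list of [plan_metrics()] frames, one
#'   per scenario) and `envelope` (data frame of per-structure, per-metric
#'   min and max across scenarios)
#' @export
robustness_suite <- function(x, grid, structures, spots, params,
                             prescription_Gy,
                             scenarios = robustness_scenarios(),
                             c = cdl_constant(), dose_floor = 0) {
  mets <- vector("list", nrow(scenarios))
  names(mets) <- scenarios$label
  for (r in seq_len(nrow(scenarios))) {
    p2 <- params
    p2$density_scale <- params$density_scale * scenarios$density[r]
    infl <- tryCatch(
      simulate_influence(grid, spots, p2,
                         shift_mm = c(scenarios$dx[r], scenarios$dy[r],
                                      scenarios$dz[r])),
      error = function(e) stop(sprintf("scenario '%s': %s",
                                       scenarios$label[r], conditionMessage(e)),
                               call. = FALSE))
    fw <- forward_plan(infl, x, c = c, dose_floor = dose_floor)
    mets[[r]] <- plan_metrics(fw, structures, prescription_Gy)
  }
  metric_cols <- setdiff(names(mets[[1]])[vapply(mets[[1]], is.numeric,
                                                 logical(1))], "n_voxels")
  env_rows <- lapply(seq_len(nrow(mets[[1]])), function(i) {
    vals <- vapply(mets, function(m) unlist(m[i, metric_cols]),
                   numeric(length(metric_cols)))
    data.frame(structure = mets[[1]]$structure[i],
               metric = metric_cols,
               min = apply(vals, 1, min), max = apply(vals, 1, max),
               nominal = unlist(mets[[1]][i, metric_cols]),
               row.names = NULL)
  })
  list(metrics = mets, envelope = do.call(rbind, env_rows))
}
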