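#' Per-voxel interval constraint set
#'
#' A data frame with one row per constrained voxel: `voxel` (1-based linear
#' index), `structure`, `space` ("dose" for target rows, "cdl" for OAR
#' rows), `lower`/`upper` interval bounds (Gy in either space), `weight`
#' (> 0) and `ref` — the reference value the superiorization objective
#' pulls toward (the prescription for target rows, the cDL30 bound for OAR
#' rows).
#'
#' @param df data frame with the columns above
#' @return the data frame with class `constraint_set`
#' @export
constraint_set <- function(df) {
  need <- c("voxel", "structure", "space", "lower", "upper", "weight", "ref")
  if (!all(need %in% names(df)))
    stop("constraint set needs columns: ", paste(need, collapse = ", "))
  if (any(!df$space %in% c("dose", "cdl")))
    stop("space must be 'dose' or 'cdl'")
  if (any(df$lower > df$upper)) stop("lower bound exceeds upper bound")
  if (any(df$weight <= 0)) stop("weights must be > 0")
  class(df) <- c("constraint_set", "data.frame")
  df
}

#' Dose-space interval constraints for the target
#'
#' Every target voxel receives a dose interval `[lower_frac, upper_frac] x
#' prescription` with reference value equal to the prescription. The
#' per-voxel lower bound at 95% of the prescription is a sufficient
#' condition for the clinical DVH criterion (at least 98% of the PTV
#' receiving 95% of the prescribed dose), which is itself checked post hoc
#' by [plan_metrics()].
#'
#' @param ptv_mask logical mask of the target over the grid
#' @param prescription_Gy prescription dose (Gy)
#' @param lower_frac,upper_frac interval as fractions of the prescription
#'   (defaults 0.95 and 1.07, the usual coverage/homogeneity window)
#' @param weight row weight (default 100: target coverage is the binding
#'   clinical goal, weighted well above OAR rows)
#' @param structure structure name recorded on the rows
#' @return a [constraint_set()]
#' @export
build_ptv_constraints <- function(ptv_mask, prescription_Gy,
                                  lower_frac = 0.95, upper_frac = 1.07,
                                  weight = 100, structure = "PTV") {
  if (prescription_Gy <= 0) stop("prescription must be > 0")
  if (!(lower_frac > 0 && lower_frac <= 1 && upper_frac >= 1))
    stop("need 0 < lower_frac <= 1 <= upper_frac")
  vox <- which(as.vector(ptv_mask))
  if (length(vox) == 0) stop("empty PTV mask")
  constraint_set(data.frame(
    voxel = vox, structure = structure, space = "dose",
    lower = lower_frac * prescription_Gy,
    upper = upper_frac * prescription_Gy,
    weight = weight, ref = prescription_Gy))
}

#' cDL-space upper constraints for OARs from a baseline forward calculation
#'
#' For each OAR the baseline plan's cDL volume histogram is computed and its
#' percentile at `fraction` (default 0.30, i.e. cDL30 — the cDL value
#' received by 30% of the structure volume) becomes a per-voxel upper bound
#' `[0, cDL30]` with reference value cDL30. By the step-percentile
#' definition at least 30% of the OAR's voxels sit at or above this bound at
#' the baseline fluence, so the bound actively pushes the high-LET tail
#' down. An OAR receiving no baseline dose anywhere is skipped with a
#' warning (nothing to reduce).
#'
#' @param baseline_forward a [forward_plan()] result for the baseline fluence
#' @param oar_masks named list of logical masks, one per OAR
#' @param fraction volume fraction defining the percentile bound (default 0.30)
#' @param weight_map named numeric of per-OAR weights (default 1 for all)
#' @param exclude_mask optional logical mask (e.g. the PTV) whose voxels are
#'   removed from every OAR's constraint rows — target-priority overlap
#'   resolution
#' @return a [constraint_set()] (possibly with zero rows)
#' @export
build_oar_cdl_constraints <- function(baseline_forward, oar_masks,
                                      fraction = 0.30, weight_map = NULL,
                                      exclude_mask = NULL) {
  if (length(oar_masks) == 0 || is.null(names(oar_masks)))
    stop("oar_masks must be a named list of masks")
  rows <- list()
  for (nm in names(oar_masks)) {
    mask <- as.vector(oar_masks[[nm]])
    if (!is.null(exclude_mask)) mask <- mask & !as.vector(exclude_mask)
    vox <- which(mask)
    if (length(vox) == 0) next
    if (all(baseline_forward$dose[vox] <= baseline_forward$dose_floor)) {
      warning(sprintf("OAR '%s' receives no baseline dose; cDL constraint skipped", nm))
      next
    }
    vh <- cumulative_vh(baseline_forward$cdl[vox], structure = nm)
    bound <- vh_percentile(vh, fraction)
    w <- if (!is.null(weight_map) && nm %in% names(weight_map))
      weight_map[[nm]] else 1
    rows[[nm]] <- data.frame(
      voxel = vox, structure = nm, space = "cdl",
      lower = 0, upper = bound, weight = w, ref = bound)
  }
  if (length(rows) == 0)
    return(constraint_set(data.frame(
      voxel = integer(), structure = character(), space = character(),
      lower = numeric(), upper = numeric(), weight = numeric(),
      ref = numeric())))
  constraint_set(do.call(rbind, c(rows, list(make.row.names = FALSE))))
}

#' Build the full constraint set for a reoptimization problem
#'
#' Convenience wrapper: dose-interval rows for the target plus cDL30 upper
#' rows for every declared OAR, with target-priority overlap resolution (a
#' voxel inside both the target and an OAR keeps only its target row).
#'
#' @param baseline_forward a [forward_plan()] result at the baseline fluence
#' @param structures a [structure_set()]
#' @param prescription_Gy prescription dose (Gy)
#' @param target name of the target structure (default "PTV")
#' @param lower_frac,upper_frac,ptv_weight passed to [build_ptv_constraints()]
#' @param fraction,weight_map passed to [build_oar_cdl_constraints()]
#' @return a [constraint_set()]
#' @export
build_constraints <- function(baseline_forward, structures, prescription_Gy,
                              target = "PTV", lower_frac = 0.95,
                              upper_frac = 1.07, ptv_weight = 100,
                              fraction = 0.30, weight_map = NULL) {
  tmask <- structures$masks[[target]]
  if (is.null(tmask)) stop(sprintf("target '%s' not in structure set", target))
  ptv <- build_ptv_constraints(tmask, prescription_Gy, lower_frac,
                               upper_frac, ptv_weight, structure = target)
  oar_names <- structures_with_role(structures, "oar")
  oar <- build_oar_cdl_constraints(baseline_forward,
                                   structures$masks[oar_names],
                                   fraction = fraction,
                                   weight_map = weight_map,
                                   exclude_mask = tmask)
  constraint_set(rbind(as.data.frame(ptv), as.data.frame(oar),
                       make.row.names = FALSE))
}
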