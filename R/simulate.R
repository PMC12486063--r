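#' Simulate sparse influence matrices with the analytic beam model
#'
#' For every spot j the dose column is (depth-dose at the voxel's
#' water-equivalent depth) x (lateral Gaussian in the beam's-eye plane),
#' and the LET_d-numerator column is (depth LET_d) x (dose entry), so the
#' numerator equals local LET times local dose exactly and
#' numerator/denominator additivity across beamlets holds by construction.
#' Entries below `params$sparsity_floor` times the column maximum are
#' dropped from sparse storage.
#'
#' The lateral profile is normalised so a slice integrates to the depth-dose
#' value times the voxel cross-section: entry = dd(z) * (du*dv / (2 pi
#' sigma(z)^2)) * Gaussian. `shift_mm` applies a rigid patient shift: the
#' deposited pattern is translated by the shift vector, realised as a
#' lateral spot displacement plus a depth offset for the along-beam
#' component (exact for axis-aligned fields).
#'
#' @param grid a [voxel_grid()]
#' @param spots a [spot_list()]
#' @param params a [beam_model()]
#' @param shift_mm rigid patient shift (mm, length 3), default none
#' @return an [influence_matrix()] with `dose` and `letd_numerator`
#'   components
#' @export
simulate_influence <- function(grid, spots, params, shift_mm = c(0, 0, 0)) {
  stopifnot(inherits(spots, "spot_list"), inherits(params, "beam_model"))
  shift_mm <- as.numeric(shift_mm)
  if (length(shift_mm) != 3) stop("shift_mm must have length 3")
  sdf <- spots$spots
  fdf <- spots$fields
  lo <- grid$origin - grid$spacing / 2
  hi <- grid$origin + (grid$dims - 0.5) * grid$spacing
  nv <- n_voxels(grid)
  ns <- nrow(sdf)

  ii <- vector("list", ns); dd_x <- vector("list", ns); nn_x <- vector("list", ns)
  for (j in seq_len(ns)) {
    frow <- fdf[fdf$field == sdf$field[j], ]
    geo <- field_geometry(frow$gantry_deg)
    iso <- c(frow$isocenter_x, frow$isocenter_y, frow$isocenter_z)
    u0 <- iso[geo$lat[1]] + sdf$x_mm[j] + shift_mm[geo$lat[1]]
    v0 <- iso[geo$lat[2]] + sdf$y_mm[j] + shift_mm[geo$lat[2]]
    if (u0 < lo[geo$lat[1]] || u0 > hi[geo$lat[1]] ||
        v0 < lo[geo$lat[2]] || v0 > hi[geo$lat[2]])
      stop(sprintf("spot %d lies outside the lateral grid extent", j))

    ax <- axis_coords(grid, geo$axis)
    depth <- if (geo$dir > 0) ax - lo[geo$axis] else hi[geo$axis] - ax
    depth <- depth - geo$dir * shift_mm[geo$axis]
    live <- depth >= 0
    dd <- numeric(length(depth))
    dd[live] <- depth_dose(depth[live], sdf$energy[j], params)
    lt <- numeric(length(depth))
    lt[live] <- depth_letd(depth[live], sdf$energy[j], params)

    du <- axis_coords(grid, geo$lat[1]) - u0
    dv <- axis_coords(grid, geo$lat[2]) - v0
    dudv <- grid$spacing[geo$lat[1]] * grid$spacing[geo$lat[2]]

    arr_d <- array(0, grid$dims)
    arr_n <- array(0, grid$dims)
    for (t in which(dd > 0)) {
      sig <- params$sigma0_mm + params$sigma_k * depth[t]
      wu <- exp(-du^2 / (2 * sig^2))
      wv <- exp(-dv^2 / (2 * sig^2))
      slice <- dd[t] * (dudv / (2 * pi * sig^2)) * outer(wu, wv)
      if (geo$axis == 1L) {
        arr_d[t, , ] <- slice
        arr_n[t, , ] <- lt[t] * slice
      } else if (geo$axis == 2L) {
        arr_d[, t, ] <- slice
        arr_n[, t, ] <- lt[t] * slice
      } else {
        arr_d[, , t] <- slice
        arr_n[, , t] <- lt[t] * slice
      }
    }
    floor_j <- params$sparsity_floor * max(arr_d)
    keep <- which(arr_d > floor_j & arr_d > 0)
    ii[[j]] <- keep
    dd_x[[j]] <- arr_d[keep]
    nn_x[[j]] <- arr_n[keep]
  }

  lens <- lengths(ii)
  if (sum(lens) == 0L) stop("no spot deposits dose in the grid")
  i_all <- unlist(ii)
  j_all <- rep(seq_len(ns), lens)
  D <- Matrix::sparseMatrix(i = i_all, j = j_all, x = unlist(dd_x),
                            dims = c(nv, ns))
  N <- Matrix::sparseMatrix(i = i_all, j = j_all, x = unlist(nn_x),
                            dims = c(nv, ns))
  influence_matrix(D, N, grid)
}

#' Scale a uniform fluence so the mean target dose equals the prescription
#'
#' The deterministic baseline used as the reoptimization starting point:
#' all spot weights equal, scaled so the mean dose over the target mask is
#' exactly the prescription.
#'
#' @param infl an [influence_matrix()]
#' @param mask logical mask of the target structure
#' @param prescription_Gy prescription dose (Gy)
#' @return fluence vector (primaries per spot)
#' @export
scale_to_prescription <- function(infl, mask, prescription_Gy) {
  if (prescription_Gy <= 0) stop("prescription must be > 0")
  x1 <- rep(1, ncol(infl$dose))
  d <- forward_dose(infl, x1)
  m <- mean(d[as.vector(mask)])
  if (m <= 0) stop("no dose reaches the target; cannot scale")
  x1 * prescription_Gy / m
}
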