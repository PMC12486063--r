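#' Two-component sparse influence matrix
#'
#' Columns are beamlets, rows are voxels (0-based x-fastest linear order,
#' stored 1-based inside R). The `dose` component maps unit fluence to dose
#' per voxel (Gy per primary); `letd_numerator` holds the additive numerator
#' of the dose-averaged LET, i.e. per-beamlet (local LET_d) x (local dose)
#' (Gy.keV/um per primary), so that the voxel LET_d under fluence `x` is the
#' ratio of the two matrix-vector products. An optional `letd_denominator`
#' component can carry a separately scored denominator; when absent the dose
#' component is used (the proton-dose ~ total-dose simplification that makes
#' the cDL forward model linear in the fluence).
#'
#' @param dose sparse dgCMatrix, n_voxels x n_beamlets, entries >= 0
#' @param letd_numerator sparse dgCMatrix, same shape, entries >= 0, sparsity
#'   pattern contained in that of `dose`
#' @param grid the [voxel_grid()] the rows refer to
#' @param letd_denominator optional sparse dgCMatrix, same shape
#' @return an object of class `influence_matrix`
#' @export
influence_matrix <- function(dose, letd_numerator, grid,
                             letd_denominator = NULL) {
  dose <- methods::as(methods::as(dose, "CsparseMatrix"), "generalMatrix")
  letd_numerator <- methods::as(methods::as(letd_numerator, "CsparseMatrix"),
                                "generalMatrix")
  if (!identical(dim(dose), dim(letd_numerator)))
    stop("dose and letd_numerator must have identical shape")
  if (nrow(dose) != n_voxels(grid))
    stop("row count must equal the number of grid voxels")
  if (any(dose@x < 0) || any(letd_numerator@x < 0))
    stop("influence entries must be >= 0")
  # pattern containment: every stored numerator entry must be a stored dose entry
  pn <- paste(letd_numerator@i, rep(seq_len(ncol(dose)),
                                    diff(letd_numerator@p)))
  pd <- paste(dose@i, rep(seq_len(ncol(dose)), diff(dose@p)))
  if (!all(pn %in% pd))
    stop("sparsity pattern of letd_numerator must be contained in dose")
  if (!is.null(letd_denominator)) {
    letd_denominator <- methods::as(methods::as(letd_denominator,
                                                "CsparseMatrix"),
                                    "generalMatrix")
    if (!identical(dim(dose), dim(letd_denominator)))
      stop("letd_denominator must match the dose component's shape")
    if (any(letd_denominator@x < 0)) stop("influence entries must be >= 0")
  }
  structure(list(dose = dose, letd_numerator = letd_numerator,
                 letd_denominator = letd_denominator, grid = grid),
            class = "influence_matrix")
}

#' @export
print.influence_matrix <- function(x, ...) {
  cat(sprintf(
    "<influence_matrix> %d voxels x %d beamlets, %d stored dose entries\n",
    nrow(x$dose), ncol(x$dose), length(x$dose@x)))
  invisible(x)
}

#' Number of beamlets in an influence matrix
#' @param infl an `influence_matrix`
#' @return integer
#' @export
n_beamlets <- function(infl) ncol(infl$dose)

check_fluence <- function(infl, x, nonneg = TRUE) {
  if (length(x) != ncol(infl$dose))
    stop(sprintf("fluence length %d does not match %d beamlets",
                 length(x), ncol(infl$dose)))
  if (nonneg && any(x < 0)) stop("fluence entries must be >= 0")
  invisible(x)
}

#' Forward dose: D(x) = Dij x
#'
#' Linear in the fluence vector.
#' @param infl an [influence_matrix()]
#' @param x fluence vector (length = number of beamlets)
#' @return numeric dose image (Gy), one value per voxel
#' @export
forward_dose <- function(infl, x) {
  check_fluence(infl, x, nonneg = FALSE)
  as.numeric(infl$dose %*% x)
}

#' Forward dose-averaged LET: ratio of numerator and denominator images
#'
#' `LETd_i = (N x)_i / (D x)_i` for voxels with dose above `dose_floor`, 0
#' elsewhere (declared convention: LET_d is reported as 0 where there is no
#' dose to average over). Uses the `letd_denominator` component when the
#' matrix carries one, otherwise the dose component.
#'
#' @inheritParams forward_dose
#' @param dose_floor Gy; voxels at or below this dose report LET_d = 0
#' @return numeric LET_d image (keV/um)
#' @export
forward_letd <- function(infl, x, dose_floor = 0) {
  check_fluence(infl, x)
  num <- as.numeric(infl$letd_numerator %*% x)
  den_m <- if (is.null(infl$letd_denominator)) infl$dose else infl$letd_denominator
  den <- as.numeric(den_m %*% x)
  out <- numeric(length(num))
  ok <- den > dose_floor
  out[ok] <- num[ok] / den[ok]
  out
}

#' Forward cDL image: c x dose x LET_d
#'
#' `cDL_i = c * D(x)_i * LETd(x)_i`, in Gy (c in um/keV cancels the LET
#' units). Under the denominator ~ dose simplification this equals
#' `c * (N x)_i` wherever dose exceeds the floor, i.e. the cDL forward model
#' is linear in the fluence — the identity the cDL interval constraints rely
#' on, and it holds to machine precision.
#'
#' @inheritParams forward_letd
#' @param c scaling constant in um/keV (default [cdl_constant()], 0.04)
#' @return numeric cDL image (Gy)
#' @export
forward_cdl <- function(infl, x, c = cdl_constant(), dose_floor = 0) {
  if (c <= 0) stop("the constant c must be > 0")
  d <- forward_dose(infl, x)
  l <- forward_letd(infl, x, dose_floor)
  c * d * l
}

#' The default cDL scaling constant (um/keV)
#'
#' The constant multiplying dose x LET_d so the product carries dose units.
#' @return 0.04
#' @export
cdl_constant <- function() 0.04

#' Full forward calculation for a fluence vector
#'
#' @inheritParams forward_cdl
#' @return an object of class `forward_result`: list with numeric images
#'   `dose` (Gy), `letd` (keV/um), `cdl` (Gy), plus `c`, `dose_floor` and the
#'   `grid`
#' @export
forward_plan <- function(infl, x, c = cdl_constant(), dose_floor = 0) {
  d <- forward_dose(infl, x)
  l <- forward_letd(infl, x, dose_floor)
  structure(list(dose = d, letd = l, cdl = c * d * l, c = c,
                 dose_floor = dose_floor, grid = infl$grid),
            class = "forward_result")
}

#' @export
print.forward_result <- function(x, ...) {
  cat(sprintf("<forward_result> %d voxels: max dose %.3g Gy, max LET_d %.3g keV/um\n",
              length(x$dose), max(x$dose), max(x$letd)))
  invisible(x)
}

#' Sparse cDL constraint row for one voxel
#'
#' Returns the row vector `a_i` with `<a_i, x> = cDL(x)_i` for every fluence
#' `x` (under the linear cDL model), i.e. `c` times row i of the
#' LET_d-numerator component. This is the row the projection solver uses for
#' cDL-space interval constraints.
#'
#' @param infl an [influence_matrix()]
#' @param voxel 1-based linear voxel index
#' @param c scaling constant (um/keV)
#' @return a 1 x n_beamlets sparse matrix
#' @export
cdl_row <- function(infl, voxel, c = cdl_constant()) {
  if (voxel < 1 || voxel > nrow(infl$dose)) stop("voxel index out of range")
  c * infl$letd_numerator[voxel, , drop = FALSE]
}
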