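#' Spot list: scanned pencil beams grouped into fields
#'
#' `spots` is a data frame with one row per deliverable pencil beam:
#' `field` (id), `x_mm`, `y_mm` (lateral position in the field's beam's-eye
#' view, relative to the field isocenter), `energy` (MeV) and `fluence`
#' (initial number of primaries, >= 0). `fields` has one row per field:
#' `field`, `gantry_deg`, `couch_deg`, `isocenter_x/y/z` (mm).
#'
#' The simulator restricts gantry angles to multiples of 90 degrees with
#' couch 0, i.e. axis-aligned beams in the phantom frame: gantry 0 enters
#' along +z, 90 along +x, 180 along -z, 270 along -x. The beam's-eye lateral
#' axes (x_mm, y_mm) map to phantom axes (x, y) for beams along z and to
#' (y, z) for beams along x.
#'
#' @param spots data frame of spots (see Details)
#' @param fields data frame of fields (see Details)
#' @return an object of class `spot_list`
#' @export
spot_list <- function(spots, fields) {
  need_s <- c("field", "x_mm", "y_mm", "energy", "fluence")
  need_f <- c("field", "gantry_deg", "couch_deg",
              "isocenter_x", "isocenter_y", "isocenter_z")
  if (!all(need_s %in% names(spots)))
    stop("spots must have columns: ", paste(need_s, collapse = ", "))
  if (!all(need_f %in% names(fields)))
    stop("fields must have columns: ", paste(need_f, collapse = ", "))
  if (any(spots$fluence < 0)) stop("spot fluences must be >= 0")
  if (!all(spots$field %in% fields$field))
    stop("every spot must belong to a declared field")
  if (anyDuplicated(fields$field)) stop("duplicate field ids")
  if (!all(fields$gantry_deg %% 90 == 0))
    stop("simulator supports axis-aligned fields only (gantry multiple of 90)")
  if (!all(fields$couch_deg == 0)) stop("simulator supports couch 0 only")
  structure(list(spots = as.data.frame(spots), fields = as.data.frame(fields)),
            class = "spot_list")
}

#' @export
print.spot_list <- function(x, ...) {
  cat(sprintf("<spot_list> %d spots in %d fields\n",
              nrow(x$spots), nrow(x$fields)))
  invisible(x)
}

#' Number of spots (beamlets)
#' @param spots a `spot_list`
#' @return integer
#' @export
n_spots <- function(spots) nrow(spots$spots)

# beam geometry for one axis-aligned field:
# axis: phantom axis index the beam travels along; dir: +1/-1;
# lat: the two phantom axes spanned by beam's-eye (x_mm, y_mm)
field_geometry <- function(gantry_deg) {
  g <- gantry_deg %% 360
  switch(as.character(g),
         "0"   = list(axis = 3L, dir = +1, lat = c(1L, 2L)),
         "90"  = list(axis = 1L, dir = +1, lat = c(2L, 3L)),
         "180" = list(axis = 3L, dir = -1, lat = c(1L, 2L)),
         "270" = list(axis = 1L, dir = -1, lat = c(2L, 3L)),
         stop("gantry angle must be a multiple of 90 degrees"))
}

#' Plan a spot grid covering a target structure
#'
#' Generates energy layers whose ranges span the target's depth extent and a
#' lateral spot grid covering its beam's-eye cross-section, for each
#' requested field. All initial fluences are 1 primary; the optimizer (or
#' [scale_to_prescription()]) sets the weights.
#'
#' @param grid a [voxel_grid()]
#' @param structures a [structure_set()]
#' @param params a [beam_model()]
#' @param target structure name to cover (default "PTV")
#' @param gantry_deg gantry angle per field (multiples of 90)
#' @param spot_spacing_mm lateral spot spacing (mm)
#' @param layer_spacing_mm spacing of Bragg-peak depths between energy layers
#' @return a [spot_list()]
#' @export
plan_spots <- function(grid, structures, params, target = "PTV",
                       gantry_deg = c(90, 270), spot_spacing_mm = 9,
                       layer_spacing_mm = 9) {
  mask <- structures$masks[[target]]
  if (is.null(mask) || !any(mask)) stop(sprintf("target '%s' not found or empty", target))
  idx <- which(mask)
  sub <- grid_subscript(grid, idx - 1L)
  coords <- cbind(axis_coords(grid, 1)[sub[, 1]],
                  axis_coords(grid, 2)[sub[, 2]],
                  axis_coords(grid, 3)[sub[, 3]])
  iso <- colMeans(coords)
  lo <- grid$origin - grid$spacing / 2
  hi <- grid$origin + (grid$dims - 0.5) * grid$spacing

  fields <- data.frame(field = seq_along(gantry_deg), gantry_deg = gantry_deg,
                       couch_deg = 0,
                       isocenter_x = iso[1], isocenter_y = iso[2],
                       isocenter_z = iso[3])
  spot_rows <- list()
  for (f in seq_along(gantry_deg)) {
    geo <- field_geometry(gantry_deg[f])
    depth <- if (geo$dir > 0) coords[, geo$axis] - lo[geo$axis]
             else hi[geo$axis] - coords[, geo$axis]
    layers <- seq(min(depth), max(depth), by = layer_spacing_mm)
    energies <- energy_for_range(layers * params$density_scale, params)
    u <- coords[, geo$lat[1]] - iso[geo$lat[1]]
    v <- coords[, geo$lat[2]] - iso[geo$lat[2]]
    ugrid <- seq(floor(min(u) / spot_spacing_mm),
                 ceiling(max(u) / spot_spacing_mm)) * spot_spacing_mm
    vgrid <- seq(floor(min(v) / spot_spacing_mm),
                 ceiling(max(v) / spot_spacing_mm)) * spot_spacing_mm
    pos <- expand.grid(u = ugrid, v = vgrid)
    # keep lateral positions with a target voxel within one spot spacing
    keep <- vapply(seq_len(nrow(pos)), function(r) {
      any(abs(u - pos$u[r]) <= spot_spacing_mm &
          abs(v - pos$v[r]) <= spot_spacing_mm)
    }, logical(1))
    pos <- pos[keep, , drop = FALSE]
    for (e in energies) {
      spot_rows[[length(spot_rows) + 1L]] <-
        data.frame(field = f, x_mm = pos$u, y_mm = pos$v,
                   energy = e, fluence = 1)
    }
  }
  spot_list(do.call(rbind, spot_rows), fields)
}
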