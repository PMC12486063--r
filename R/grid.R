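#' Voxel grid geometry
#'
#' A regular 3D voxel grid on which all images, structure masks and
#' influence-matrix rows live. `origin` is the physical position (mm) of the
#' centre of the first voxel. Voxels are enumerated x-fastest: the linear
#' index of voxel (i, j, k) (0-based) is `i + nx*(j + ny*k)`, which is also
#' the native storage order of an R `array` with `dim = dims`, so
#' `as.vector(arr)[lin + 1]` retrieves voxel `lin`. This ordering is declared
#' in the sparse influence file header and must be preserved by all writers
#' and readers.
#'
#' @param dims integer vector of length 3, voxel counts (nx, ny, nz), each >= 1
#' @param spacing numeric length 3, voxel size in mm (default 3 mm isotropic)
#' @param origin numeric length 3, mm position of the first voxel centre
#' @return an object of class `voxel_grid`
#' @examples
#' g <- voxel_grid(c(20, 20, 20))
#' n_voxels(g)
#' @export
voxel_grid <- function(dims, spacing = c(3, 3, 3), origin = c(0, 0, 0)) {
  dims <- as.integer(dims)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(dims) != 3L || any(is.na(dims)) || any(dims < 1L))
    stop("`dims` must be 3 positive integers")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive numbers (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite numbers (mm)")
  structure(list(dims = dims, spacing = spacing, origin = origin),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %d x %d x %d voxels, spacing %g x %g x %g mm\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Number of voxels in a grid
#' @param grid a `voxel_grid`
#' @return integer voxel count
#' @export
n_voxels <- function(grid) prod(grid$dims)

#' Physical coordinates of voxel centres along one axis
#' @param grid a `voxel_grid`
#' @param axis 1, 2 or 3
#' @return numeric vector of mm positions
#' @export
axis_coords <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$dims[axis]) - 1) * grid$spacing[axis]
}

#' Convert (i, j, k) voxel subscripts to the 0-based linear index
#'
#' Subscripts are 1-based (R convention); the returned linear index is
#' 0-based and x-fastest, matching the on-disk declaration.
#' @param grid a `voxel_grid`
#' @param ijk integer matrix (n x 3) or vector of length 3, 1-based
#' @return 0-based linear indices
#' @export
grid_index <- function(grid, ijk) {
  if (is.null(dim(ijk))) ijk <- matrix(ijk, ncol = 3)
  stopifnot(ncol(ijk) == 3)
  d <- grid$dims
  if (any(ijk < 1) || any(ijk[, 1] > d[1]) || any(ijk[, 2] > d[2]) ||
      any(ijk[, 3] > d[3]))
    stop("voxel subscripts out of range")
  (ijk[, 1] - 1L) + d[1] * ((ijk[, 2] - 1L) + d[2] * (ijk[, 3] - 1L))
}

#' Convert 0-based linear indices to (i, j, k) voxel subscripts (1-based)
#' @param grid a `voxel_grid`
#' @param lin 0-based linear indices
#' @return integer matrix (n x 3) of 1-based subscripts
#' @export
grid_subscript <- function(grid, lin) {
  d <- grid$dims
  if (any(lin < 0) || any(lin >= prod(d))) stop("linear index out of range")
  i <- lin %% d[1]
  j <- (lin %/% d[1]) %% d[2]
  k <- lin %/% (d[1] * d[2])
  cbind(i = i + 1L, j = j + 1L, k = k + 1L)
}

#' Structure set: named organ masks over a grid
#'
#' Holds boolean masks with a role tag per structure. Roles are `"target"`
#' (PTV/CTV), `"oar"` (organ at risk) or `"external"`. Masks may overlap;
#' overlap between a target and an OAR must carry an explicit priority (see
#' [make_phantom()]) and constraint building resolves it target-first.
#'
#' @param grid a `voxel_grid`
#' @param masks named list of logical arrays with `dim == grid$dims`
#' @param roles named character vector, one role per mask
#' @return an object of class `structure_set`
#' @export
structure_set <- function(grid, masks, roles) {
  if (length(masks) == 0) stop("at least one structure is required")
  if (is.null(names(masks)) || any(!nzchar(names(masks))))
    stop("all masks must be named")
  roles <- roles[names(masks)]
  if (any(is.na(roles)) || !all(roles %in% c("target", "oar", "external")))
    stop("every structure needs a role in {target, oar, external}")
  for (nm in names(masks)) {
    m <- masks[[nm]]
    if (!is.logical(m) || !identical(as.integer(dim(m)), grid$dims))
      stop(sprintf("mask '%s' is not a logical array matching the grid", nm))
  }
  tg <- names(masks)[roles == "target"]
  if (length(tg) > 0 && any(!vapply(masks[tg], any, logical(1))))
    stop("a declared target mask is empty")
  structure(list(grid = grid, masks = masks, roles = roles),
            class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  cat(sprintf("<structure_set> %d structures on %d voxels\n",
              length(x$masks), n_voxels(x$grid)))
  for (nm in names(x$masks))
    cat(sprintf("  %-16s %-8s %6d voxels\n", nm, x$roles[[nm]],
                sum(x$masks[[nm]])))
  invisible(x)
}

#' Names of structures with a given role
#' @param structures a `structure_set`
#' @param role one of "target", "oar", "external"
#' @return character vector
#' @export
structures_with_role <- function(structures, role) {
  names(structures$masks)[structures$roles == role]
}
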