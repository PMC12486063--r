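#' Build a synthetic phantom: grid plus structure masks
#'
#' Constructs a voxel grid and a set of parametric structures (spheres and
#' boxes) standing in for a patient CT and its contoured structure set, so
#' the whole reoptimization pipeline can run on data generated in code.
#'
#' `layout` is a list of structure specifications, each a list with fields
#' `name`, `role` ("target" | "oar" | "external"), `shape` ("sphere" |
#' "box"), `center` (mm, length 3, in grid physical coordinates),
#' `radius` (mm, spheres) or `halfwidth` (mm, length 3, boxes), optional
#' `priority` (integer; larger wins where a target and an OAR overlap) and
#' optional `jitter_mm` (uniform random displacement of the centre, drawn
#' with `seed`; default 0, i.e. fully deterministic).
#'
#' Overlap between a target and an OAR is an error unless both declare a
#' priority; the overlapping voxels are then removed from the lower-priority
#' structure, so the stored masks are disjoint across the target/OAR pair.
#'
#' @param dims integer length-3 voxel counts
#' @param spacing mm, length 3 or scalar (default 3 mm)
#' @param layout list of structure specifications (see Details)
#' @param seed integer seed controlling any randomised placement
#' @param origin mm position of the first voxel centre
#' @return list with elements `grid` (a [voxel_grid()]) and
#'   `structures` (a [structure_set()])
#' @examples
#' ph <- make_phantom(c(20, 20, 20), 3, layout_sphere_oar())
#' ph$structures
#' @export
make_phantom <- function(dims, spacing = 3, layout, seed = 1L, origin = NULL) {
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  if (is.null(origin)) origin <- spacing / 2
  grid <- voxel_grid(dims, spacing, origin)
  if (missing(layout) || length(layout) == 0)
    stop("`layout` must name a target and at least one OAR")

  roles <- vapply(layout, function(s) s$role, character(1))
  nms <- vapply(layout, function(s) s$name, character(1))
  if (!any(roles == "target")) stop("layout declares no target structure")
  if (!any(roles == "oar")) stop("layout declares no OAR structure")
  if (anyDuplicated(nms)) stop("duplicate structure names in layout")

  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(as.integer(seed))
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)

  xs <- axis_coords(grid, 1); ys <- axis_coords(grid, 2); zs <- axis_coords(grid, 3)
  gx <- array(rep(xs, times = grid$dims[2] * grid$dims[3]), dim = grid$dims)
  gy <- array(rep(rep(ys, each = grid$dims[1]), times = grid$dims[3]),
              dim = grid$dims)
  gz <- array(rep(zs, each = grid$dims[1] * grid$dims[2]), dim = grid$dims)
  lo <- grid$origin - grid$spacing / 2
  hi <- grid$origin + (grid$dims - 0.5) * grid$spacing

  masks <- list()
  for (s in layout) {
    jit <- if (is.null(s$jitter_mm)) 0 else s$jitter_mm
    center <- as.numeric(s$center) + stats::runif(3, -jit, jit)
    if (identical(s$shape, "sphere")) {
      r <- as.numeric(s$radius)
      if (r <= 0) stop(sprintf("structure '%s': radius must be > 0", s$name))
      if (any(center - r < lo) || any(center + r > hi))
        stop(sprintf("structure '%s' extends beyond the grid", s$name))
      m <- (gx - center[1])^2 + (gy - center[2])^2 + (gz - center[3])^2 <= r^2
    } else if (identical(s$shape, "box")) {
      hw <- as.numeric(s$halfwidth)
      if (length(hw) == 1) hw <- rep(hw, 3)
      if (any(hw <= 0)) stop(sprintf("structure '%s': halfwidth must be > 0", s$name))
      if (any(center - hw < lo) || any(center + hw > hi))
        stop(sprintf("structure '%s' extends beyond the grid", s$name))
      m <- abs(gx - center[1]) <= hw[1] & abs(gy - center[2]) <= hw[2] &
        abs(gz - center[3]) <= hw[3]
    } else {
      stop(sprintf("structure '%s': unknown shape '%s'", s$name, s$shape))
    }
    masks[[s$name]] <- m
  }

  # target/OAR overlaps need an explicit priority; higher priority keeps voxels
  prio <- vapply(layout, function(s)
    if (is.null(s$priority)) NA_integer_ else as.integer(s$priority), integer(1))
  names(prio) <- nms
  tgt <- nms[roles == "target"]; oar <- nms[roles == "oar"]
  for (a in tgt) for (b in oar) {
    ov <- masks[[a]] & masks[[b]]
    if (any(ov)) {
      if (is.na(prio[a]) || is.na(prio[b]))
        stop(sprintf(
          "structures '%s' and '%s' overlap without declared priorities", a, b))
      loser <- if (prio[a] >= prio[b]) b else a
      masks[[loser]][ov] <- FALSE
    }
  }

  names(roles) <- nms
  list(grid = grid, structures = structure_set(grid, masks, roles))
}

#' Default phantom layout: central spherical PTV abutting one OAR
#'
#' A brainstem-like geometry: a spherical target in the middle of the grid
#' with a smaller spherical OAR touching its surface along +y. Sizes default
#' to a 18 mm radius target on a 60 mm cube (20 voxels at 3 mm).
#'
#' @param center mm centre of the target (default c(30, 30, 30))
#' @param target_radius mm (default 18)
#' @param oar_radius mm (default 6)
#' @return a layout list for [make_phantom()]
#' @export
layout_sphere_oar <- function(center = c(30, 30, 30), target_radius = 18,
                              oar_radius = 6) {
  list(
    list(name = "PTV", role = "target", shape = "sphere", center = center,
         radius = target_radius, priority = 2L),
    list(name = "OAR", role = "oar", shape = "sphere",
         center = center + c(0, target_radius + oar_radius, 0),
         radius = oar_radius, priority = 1L)
  )
}
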