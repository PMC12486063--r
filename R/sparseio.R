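#' Write an influence matrix in the package's sparse text format
#'
#' A self-describing plain-text container for per-beamlet sparse columns.
#' The header declares the format version, matrix shape, grid geometry,
#' component names/units and the voxel ordering (0-based linear index,
#' x-fastest); each beamlet block lists its nonzero voxel indices with one
#' value per component. Values are printed with 17 significant digits so a
#' write/read round trip is bit-exact for doubles.
#'
#' Format sketch:
#' \preformatted{
#' letseek-sparse 1
#' n_voxels 8000
#' n_beamlets 200
#' dims 20 20 20
#' spacing 3 3 3
#' origin 1.5 1.5 1.5
#' ordering 0-based x-fastest
#' components dose letd_numerator
#' units Gy Gy.keV/um
#' beamlet 1 153
#' <153 lines: voxel_index dose_value numerator_value>
#' ...
#' }
#'
#' @param infl an [influence_matrix()]
#' @param path output file path
#' @return the path, invisibly
#' @export
write_sparse_influence <- function(infl, path) {
  g <- infl$grid
  comps <- list(dose = infl$dose, letd_numerator = infl$letd_numerator)
  units <- c("Gy", "Gy.keV/um")
  if (!is.null(infl$letd_denominator)) {
    comps$letd_denominator <- infl$letd_denominator
    units <- c(units, "Gy")
  }
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(c(
    "letseek-sparse 1",
    sprintf("n_voxels %d", nrow(infl$dose)),
    sprintf("n_beamlets %d", ncol(infl$dose)),
    sprintf("dims %d %d %d", g$dims[1], g$dims[2], g$dims[3]),
    sprintf("spacing %.17g %.17g %.17g", g$spacing[1], g$spacing[2], g$spacing[3]),
    sprintf("origin %.17g %.17g %.17g", g$origin[1], g$origin[2], g$origin[3]),
    "ordering 0-based x-fastest",
    paste("components", paste(names(comps), collapse = " ")),
    paste("units", paste(units, collapse = " "))), con)
  p <- infl$dose@p
  for (j in seq_len(ncol(infl$dose))) {
    rng <- if (p[j + 1] > p[j]) (p[j] + 1):p[j + 1] else integer()
    idx0 <- infl$dose@i[rng] # already 0-based
    writeLines(sprintf("beamlet %d %d", j, length(rng)), con)
    if (length(rng)) {
      vals <- vapply(comps, function(m) as.numeric(m[idx0 + 1L, j]),
                     numeric(length(rng)))
      if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1)
      writeLines(paste(idx0,
                       apply(vals, 1, function(v)
                         paste(sprintf("%.17g", v), collapse = " "))), con)
    }
  }
  invisible(path)
}

#' Read an influence matrix from the sparse text format
#'
#' @param path file written by [write_sparse_influence()]
#' @param require_components component names that must be present (e.g.
#'   `"letd_numerator"` when cDL rows will be needed); an informative error
#'   is raised if one is missing
#' @return an [influence_matrix()]
#' @export
read_sparse_influence <- function(path,
                                  require_components = c("dose",
                                                         "letd_numerator")) {
  if (!file.exists(path)) stop(sprintf("sparse influence file not found: %s", path))
  lines <- readLines(path)
  if (length(lines) < 9 || !startsWith(lines[1], "letseek-sparse"))
    stop("not a letseek sparse influence file")
  ver <- strsplit(lines[1], " ")[[1]][2]
  if (!identical(ver, "1"))
    stop(sprintf("unsupported sparse format version '%s'", ver))
  kv <- function(key) {
    ln <- lines[startsWith(lines, paste0(key, " "))][1]
    if (is.na(ln)) stop(sprintf("sparse header missing '%s'", key))
    strsplit(sub(paste0("^", key, " "), "", ln), " ")[[1]]
  }
  nv <- as.integer(kv("n_voxels"))
  nb <- as.integer(kv("n_beamlets"))
  dims <- as.integer(kv("dims"))
  spacing <- as.numeric(kv("spacing"))
  origin <- as.numeric(kv("origin"))
  comps <- kv("components")
  miss <- setdiff(require_components, comps)
  if (length(miss))
    stop(sprintf("sparse file lacks required component(s): %s",
                 paste(miss, collapse = ", ")))
  ord <- paste(kv("ordering"), collapse = " ")
  if (!identical(ord, "0-based x-fastest"))
    stop(sprintf("unsupported voxel ordering declaration '%s'", ord))

  cur <- which(startsWith(lines, "beamlet "))
  if (length(cur) != nb) stop("sparse file truncated: beamlet count mismatch")
  i_list <- vector("list", nb)
  v_list <- lapply(comps, function(x) vector("list", nb))
  names(v_list) <- comps
  for (b in seq_len(nb)) {
    hd <- strsplit(lines[cur[b]], " ")[[1]]
    j <- as.integer(hd[2]); cnt <- as.integer(hd[3])
    if (j != b) stop("sparse file corrupt: beamlet blocks out of order")
    if (cur[b] + cnt > length(lines))
      stop("sparse file truncated inside a beamlet block")
    if (cnt > 0) {
      block <- lines[(cur[b] + 1):(cur[b] + cnt)]
      m <- matrix(as.numeric(unlist(strsplit(block, " "))),
                  ncol = 1 + length(comps), byrow = TRUE)
      if (any(is.na(m))) stop("sparse file corrupt: non-numeric entry")
      i_list[[b]] <- as.integer(m[, 1]) + 1L
      for (ci in seq_along(comps))
        v_list[[comps[ci]]][[b]] <- m[, 1 + ci]
    }
  }
  lens <- lengths(i_list)
  i_all <- unlist(i_list)
  j_all <- rep(seq_len(nb), lens)
  mk <- function(nm) Matrix::sparseMatrix(i = i_all, j = j_all,
                                          x = unlist(v_list[[nm]]),
                                          dims = c(nv, nb))
  grid <- voxel_grid(dims, spacing, origin)
  influence_matrix(mk("dose"), mk("letd_numerator"), grid,
                   letd_denominator = if ("letd_denominator" %in% comps)
                     mk("letd_denominator") else NULL)
}

#' Write a spot list as CSV (+ fields sidecar)
#'
#' Spots go to `path` with header `field,x_mm,y_mm,energy_MeV,fluence`; the
#' per-field geometry goes to a `*_fields.csv` sidecar.
#' @param spots a [spot_list()]
#' @param path CSV path for the spots table
#' @return the path, invisibly
#' @export
write_spots_csv <- function(spots, path) {
  df <- spots$spots
  names(df)[names(df) == "energy"] <- "energy_MeV"
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  fpath <- paste0(tools::file_path_sans_ext(path), "_fields.csv")
  utils::write.csv(spots$fields, fpath, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a spot list written by [write_spots_csv()]
#' @param path CSV path of the spots table
#' @return a [spot_list()]
#' @export
read_spots_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("spot CSV not found: %s", path))
  df <- utils::read.csv(path)
  names(df)[names(df) == "energy_MeV"] <- "energy"
  fpath <- paste0(tools::file_path_sans_ext(path), "_fields.csv")
  if (!file.exists(fpath)) stop(sprintf("fields sidecar not found: %s", fpath))
  spot_list(df, utils::read.csv(fpath))
}
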