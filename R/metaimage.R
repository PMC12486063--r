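#' Write a 3D scalar image in MetaImage format
#'
#' Writes a MetaIO header plus little-endian raw voxel data: `.mha` stores
#' the data locally after the header, `.mhd` writes a sibling `.raw` file.
#' Values are stored as MET_DOUBLE so a write/read round trip reproduces
#' dims, spacing, origin and every voxel value exactly. Voxel order is the
#' grid's x-fastest linear order, which is MetaIO's native layout.
#'
#' @param values numeric vector or array of voxel values (length = grid voxels)
#' @param grid the [voxel_grid()] describing geometry
#' @param path output path ending in `.mha` or `.mhd`
#' @return the path, invisibly
#' @export
write_metaimage <- function(values, grid, path) {
  values <- as.numeric(values)
  if (length(values) != n_voxels(grid))
    stop("value count does not match the grid")
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("mha", "mhd")) stop("path must end in .mha or .mhd")
  local <- ext == "mha"
  datafile <- if (local) "LOCAL" else
    paste0(tools::file_path_sans_ext(basename(path)), ".raw")
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    sprintf("DimSize = %d %d %d", grid$dims[1], grid$dims[2], grid$dims[3]),
    sprintf("ElementSpacing = %.17g %.17g %.17g",
            grid$spacing[1], grid$spacing[2], grid$spacing[3]),
    sprintf("Offset = %.17g %.17g %.17g",
            grid$origin[1], grid$origin[2], grid$origin[3]),
    "ElementNumberOfChannels = 1",
    "ElementType = MET_DOUBLE",
    sprintf("ElementDataFile = %s", datafile))
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeLines(hdr, con)
  if (local) {
    writeBin(values, con, size = 8, endian = "little")
  } else {
    rawcon <- file(file.path(dirname(path), datafile), "wb")
    on.exit(close(rawcon), add = TRUE)
    writeBin(values, rawcon, size = 8, endian = "little")
  }
  invisible(path)
}

#' Read a 3D scalar MetaImage (.mhd/.mha)
#'
#' Supports uncompressed single-channel 3D images with element types
#' MET_DOUBLE, MET_FLOAT, MET_SHORT, MET_USHORT, MET_UCHAR or MET_INT.
#'
#' @param path path to a `.mha` or `.mhd` file
#' @return list with `grid` (a [voxel_grid()]) and `values` (numeric array
#'   with `dim = grid$dims`)
#' @export
read_metaimage <- function(path) {
  if (!file.exists(path)) stop(sprintf("MetaImage file not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0) stop("MetaImage header ended before ElementDataFile")
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) next
    key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  if (!identical(hdr$NDims, "3"))
    stop("only 3D MetaImages are supported (NDims = 3)")
  if (!is.null(hdr$ElementNumberOfChannels) &&
      hdr$ElementNumberOfChannels != "1")
    stop("vector-valued MetaImages are not supported")
  if (identical(hdr$CompressedData, "True"))
    stop("compressed MetaImages are not supported")
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  spacing <- if (!is.null(hdr$ElementSpacing))
    as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1]]) else c(1, 1, 1)
  origin <- if (!is.null(hdr$Offset))
    as.numeric(strsplit(hdr$Offset, "\\s+")[[1]]) else c(0, 0, 0)
  type <- hdr$ElementType
  spec <- switch(type,
                 MET_DOUBLE = list(what = numeric(), size = 8, signed = TRUE),
                 MET_FLOAT = list(what = numeric(), size = 4, signed = TRUE),
                 MET_SHORT = list(what = integer(), size = 2, signed = TRUE),
                 MET_USHORT = list(what = integer(), size = 2, signed = FALSE),
                 MET_UCHAR = list(what = integer(), size = 1, signed = FALSE),
                 MET_INT = list(what = integer(), size = 4, signed = TRUE),
                 stop(sprintf("unsupported ElementType '%s'", type)))
  n <- prod(dims)
  msb <- identical(hdr$BinaryDataByteOrderMSB, "True") ||
    identical(hdr$ByteOrderMSB, "True")
  endian <- if (msb) "big" else "little"
  if (identical(hdr$ElementDataFile, "LOCAL")) {
    vals <- readBin(con, spec$what, n = n, size = spec$size,
                    signed = spec$signed, endian = endian)
  } else {
    rawpath <- file.path(dirname(path), hdr$ElementDataFile)
    if (!file.exists(rawpath))
      stop(sprintf("MetaImage data file not found: %s", rawpath))
    rcon <- file(rawpath, "rb")
    on.exit(close(rcon), add = TRUE)
    vals <- readBin(rcon, spec$what, n = n, size = spec$size,
                    signed = spec$signed, endian = endian)
  }
  if (length(vals) != n) stop("MetaImage data truncated")
  grid <- voxel_grid(dims, spacing, origin)
  list(grid = grid, values = array(as.numeric(vals), dim = dims))
}
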