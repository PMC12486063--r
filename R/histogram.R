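#' Cumulative volume histogram of a structure
#'
#' The standard DVH/LVH/cDLVH object: `V(v)` is the fraction of the
#' structure's voxels with value >= v, a non-increasing step curve with
#' V(min) = 1. The raw voxel values are retained so percentile extraction is
#' exact (no binning error).
#'
#' @param values numeric vector of per-voxel values inside the structure
#' @param bins optional numeric vector of value-axis points at which to
#'   tabulate the curve; defaults to the sorted unique values
#' @param structure optional structure name for labelling
#' @return an object of class `volume_histogram` with fields `value`
#'   (axis), `volume` (V at each axis point), `values` (sorted raw values)
#'   and `structure`
#' @examples
#' vh <- cumulative_vh(1:10)
#' vh_percentile(vh, 0.30)  # 8: the value received by >= 30% of the volume
#' @export
cumulative_vh <- function(values, bins = NULL, structure = NULL) {
  values <- as.numeric(values)
  if (length(values) == 0) stop("empty structure: no values to histogram")
  if (any(!is.finite(values))) stop("non-finite values in structure")
  sv <- sort(values)
  axis <- if (is.null(bins)) unique(sv) else sort(as.numeric(bins))
  # V(v) = fraction of values >= v; findInterval counts values < v via left-open
  n <- length(sv)
  below <- findInterval(axis, sv, left.open = TRUE)
  vol <- 1 - below / n
  structure(list(value = axis, volume = vol, values = sv,
                 structure = structure),
            class = "volume_histogram")
}

#' @export
print.volume_histogram <- function(x, ...) {
  cat(sprintf("<volume_histogram>%s %d voxels, values in [%g, %g]\n",
              if (is.null(x$structure)) "" else paste0(" ", x$structure),
              length(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Volume-histogram percentile (step convention)
#'
#' Returns the largest value v with V(v) >= `volume_fraction`, evaluated on
#' the raw voxel values with no interpolation, so results are integer-exact
#' on integer inputs. With n voxels this is the k-th largest value where
#' k = ceiling(fraction * n). The cDL30 organ-at-risk bound is
#' `vh_percentile(vh, 0.30)`.
#'
#' @param vh a [cumulative_vh()] object
#' @param volume_fraction fraction of the structure volume, in (0, 1)
#' @return the percentile value on the histogram's value axis
#' @export
vh_percentile <- function(vh, volume_fraction) {
  if (!is.finite(volume_fraction) || volume_fraction <= 0 ||
      volume_fraction >= 1)
    stop("volume_fraction must lie strictly between 0 and 1")
  n <- length(vh$values)
  k <- ceiling(volume_fraction * n - 1e-9)
  k <- max(1L, min(n, k))
  vh$values[n - k + 1L]
}
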