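#' Build a categorical surface-type history from topography, sea level and
#' ice extent
#'
#' Classifies every grid cell at every epoch as ocean, land or land ice.
#' The rules, applied per cell:
#' \enumerate{
#'   \item Inland lake cells keep their present-day class (the class they
#'     have at a sea-level offset of 0 m with no ice), so falling sea level
#'     never drains a preserved lake and rising sea level never floods it.
#'   \item Otherwise, cells with elevation at or below the epoch's sea
#'     level become ocean.
#'   \item Remaining cells under the ice extent become land ice; ice
#'     flagged over ocean cells is dropped with a warning (ice sheets
#'     convert land, never ocean produced by the sea-level rule).
#'   \item Everything else is land.
#' }
#'
#' @param topography numeric matrix (nlon, nlat) of cell elevations in m
#'   relative to present-day sea level.
#' @param seaLevel numeric vector of sea-level offsets in m (one per
#'   epoch; negative = lower than today).
#' @param iceExtent logical matrix (nlon, nlat) or array
#'   (nlon, nlat, nepoch) marking ice-covered cells.
#' @param lakes logical matrix (nlon, nlat) of preserved inland lake
#'   cells; default none.
#' @param geometry the [GridGeometry-class] of all grids.
#' @param epochs numeric epochs in ka BP, one per sea level; default
#'   `seq_along(seaLevel) - 1`.
#' @return a [SurfaceTypeGrid-class] with one slice per epoch.
#' @export
buildSurfaceMask <- function(topography, seaLevel, iceExtent,
                             lakes = NULL, geometry, epochs = NULL) {
  dg <- c(length(geometry@lon), length(geometry@lat))
  if (!all(dim(topography) == dg))
    stop("topography geometry mismatch: expected ",
         paste(dg, collapse = " x "))
  nep <- length(seaLevel)
  if (is.null(epochs)) epochs <- seq_len(nep) - 1
  if (length(epochs) != nep)
    stop("epochs must match length(seaLevel)")
  if (is.matrix(iceExtent))
    iceExtent <- array(iceExtent, c(dg, nep))
  if (!all(dim(iceExtent) == c(dg, nep)))
    stop("iceExtent geometry mismatch: expected ",
         paste(c(dg, nep), collapse = " x "))
  if (is.null(lakes)) lakes <- matrix(FALSE, dg[1L], dg[2L])
  if (!all(dim(lakes) == dg))
    stop("lakes geometry mismatch: expected ", paste(dg, collapse = " x "))

  presentClass <- ifelse(topography <= 0, SURFACE_LEVELS[["ocean"]],
                         SURFACE_LEVELS[["land"]])
  codes <- array(NA_integer_, c(dg, nep))
  droppedIce <- 0L
  for (t in seq_len(nep)) {
    cls <- ifelse(topography <= seaLevel[t], SURFACE_LEVELS[["ocean"]],
                  SURFACE_LEVELS[["land"]])
    ice <- iceExtent[, , t] & cls == SURFACE_LEVELS[["land"]]
    droppedIce <- droppedIce +
      sum(iceExtent[, , t] & cls == SURFACE_LEVELS[["ocean"]] & !lakes)
    cls[ice] <- SURFACE_LEVELS[["land_ice"]]
    cls[lakes] <- presentClass[lakes]
    codes[, , t] <- cls
  }
  if (droppedIce > 0L)
    warning(sprintf("%d ice cell-epochs over ocean dropped", droppedIce))
  new("SurfaceTypeGrid", geometry = geometry, epochs = as.numeric(epochs),
      codes = codes)
}

#' Subset a surface-type history by epoch
#'
#' @param mask a [SurfaceTypeGrid-class].
#' @param epochs epochs (ka BP) to keep, in the requested order.
#' @return a [SurfaceTypeGrid-class] restricted to `epochs`.
#' @export
subsetMask <- function(mask, epochs) {
  idx <- match(epochs, mask@epochs)
  if (anyNA(idx))
    stop("epochs missing from surface mask: ",
         paste(epochs[is.na(idx)], collapse = ", "))
  new("SurfaceTypeGrid", geometry = mask@geometry,
      epochs = as.numeric(epochs),
      codes = mask@codes[, , idx, drop = FALSE])
}
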