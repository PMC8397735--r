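#' Epochs of an object
#' @param x an object with a time axis in ka BP.
#' @return numeric epochs in ka BP.
#' @export
setGeneric("epochs", function(x) standardGeneric("epochs"))

#' Grid geometry of an object
#' @param x a gridded object.
#' @return a [GridGeometry-class].
#' @export
setGeneric("geometry", function(x) standardGeneric("geometry"))

#' Number of grid cells
#' @param x a gridded object.
#' @return integer cell count (nlon * nlat).
#' @export
setGeneric("nPixels", function(x) standardGeneric("nPixels"))

#' Values of a gridded object
#' @param x a [ClimateField-class] or similar.
#' @return the underlying numeric array.
#' @export
setGeneric("fieldValues", function(x) standardGeneric("fieldValues"))

#' Forcing predictor block
#'
#' The forcing columns of a [ForcingTable-class] as an n x 4 matrix in the
#' canonical order (obliquity, precession_i, precession_ii, co2).
#' @param x a [ForcingTable-class].
#' @return numeric matrix with one row per epoch.
#' @export
setGeneric("forcingMatrix", function(x) standardGeneric("forcingMatrix"))

#' @rdname epochs
#' @export
setMethod("epochs", "ForcingTable", function(x) x@epochs)
#' @rdname epochs
#' @export
setMethod("epochs", "ClimateField", function(x) x@epochs)
#' @rdname epochs
#' @export
setMethod("epochs", "SnapshotSet", function(x) x@epochs)
#' @rdname epochs
#' @export
setMethod("epochs", "SurfaceTypeGrid", function(x) x@epochs)
#' @rdname epochs
#' @export
setMethod("epochs", "BioclimSet", function(x) x@epochs)

#' @rdname geometry
#' @export
setMethod("geometry", "GridGeometry", function(x) x)
#' @rdname geometry
#' @export
setMethod("geometry", "ClimateField", function(x) x@geometry)
#' @rdname geometry
#' @export
setMethod("geometry", "SnapshotSet", function(x) x@geometry)
#' @rdname geometry
#' @export
setMethod("geometry", "SurfaceTypeGrid", function(x) x@geometry)
#' @rdname geometry
#' @export
setMethod("geometry", "EmulatorModel", function(x) x@geometry)
#' @rdname geometry
#' @export
setMethod("geometry", "BioclimSet", function(x) x@geometry)
#' @rdname geometry
#' @export
setMethod("geometry", "ReferenceClimatology", function(x) x@geometry)
#' @rdname geometry
#' @export
setMethod("geometry", "SyntheticWorld", function(x) x@geometry)

#' @rdname nPixels
#' @export
setMethod("nPixels", "GridGeometry",
          function(x) length(x@lon) * length(x@lat))
#' @rdname nPixels
#' @export
setMethod("nPixels", "ClimateField", function(x) nPixels(x@geometry))
#' @rdname nPixels
#' @export
setMethod("nPixels", "EmulatorModel", function(x) nPixels(x@geometry))

#' @rdname fieldValues
#' @export
setMethod("fieldValues", "ClimateField", function(x) x@values)

#' @rdname forcingMatrix
#' @export
setMethod("forcingMatrix", "ForcingTable", function(x) {
  m <- cbind(obliquity = x@obliquity, precession_i = x@precessionI,
             precession_ii = x@precessionII, co2 = x@co2)
  rownames(m) <- format(x@epochs)
  m
})

#' Indices of training epochs
#' @param x a [SelectionResult-class].
#' @return integer indices.
#' @export
setGeneric("trainIndices", function(x) standardGeneric("trainIndices"))
#' @rdname trainIndices
#' @export
setMethod("trainIndices", "SelectionResult", function(x) x@trainIndices)

#' Indices of test epochs
#' @param x a [SelectionResult-class].
#' @return integer indices.
#' @export
setGeneric("testIndices", function(x) standardGeneric("testIndices"))
#' @rdname testIndices
#' @export
setMethod("testIndices", "SelectionResult", function(x) x@testIndices)

#' Bioclim layer accessor
#' @param x a [BioclimSet-class].
#' @param layer layer name, e.g. "bio12".
#' @return numeric array (nlon, nlat, ntime).
#' @export
setGeneric("bioclimLayer", function(x, layer) standardGeneric("bioclimLayer"))
#' @rdname bioclimLayer
#' @export
setMethod("bioclimLayer", "BioclimSet", function(x, layer) {
  if (!layer %in% names(x@layers))
    stop("no such bioclim layer: ", layer)
  x@layers[[layer]]
})

setMethod("show", "GridGeometry", function(object) {
  cat(sprintf("GridGeometry: %d x %d cells, lon [%g, %g], lat [%g, %g]\n",
              length(object@lon), length(object@lat),
              min(object@lon), max(object@lon),
              min(object@lat), max(object@lat)))
})

setMethod("show", "ForcingTable", function(object) {
  n <- length(object@epochs)
  cat(sprintf("ForcingTable: %d epochs, %g-%g ka BP\n", n,
              max(object@epochs), min(object@epochs)))
  cat(sprintf("  co2 [%.1f, %.1f] ppm; obliquity [%.2f, %.2f] deg\n",
              min(object@co2), max(object@co2),
              min(object@obliquity), max(object@obliquity)))
})

setMethod("show", "SurfaceTypeGrid", function(object) {
  tab <- table(factor(object@codes, levels = SURFACE_LEVELS,
                      labels = names(SURFACE_LEVELS)))
  cat(sprintf("SurfaceTypeGrid: %d x %d cells, %d epochs\n",
              length(object@geometry@lon), length(object@geometry@lat),
              length(object@epochs)))
  cat("  cell-epoch counts:",
      paste(names(tab), as.integer(tab), sep = "=", collapse = ", "), "\n")
})

setMethod("show", "ClimateField", function(object) {
  cat(sprintf("ClimateField '%s' [%s]: %d x %d cells, %d epochs\n",
              object@variable, object@units,
              length(object@geometry@lon), length(object@geometry@lat),
              length(object@epochs)))
  v <- object@values[is.finite(object@values)]
  if (length(v))
    cat(sprintf("  range [%g, %g], %d NA\n", min(v), max(v),
                sum(!is.finite(object@values))))
})

setMethod("show", "SnapshotSet", function(object) {
  cat(sprintf("SnapshotSet: %s; %d months, %d epochs, %d x %d cells\n",
              paste(names(object@fields), collapse = ", "),
              length(object@months), length(object@epochs),
              length(object@geometry@lon), length(object@geometry@lat)))
})

setMethod("show", "PixelModel", function(object) {
  if (!object@ok) {
    cat(sprintf("PixelModel (unfit: %s)\n", object@reason))
    return(invisible(NULL))
  }
  cat(sprintf("PixelModel (%s): mean %.4g, R2 %.3f, RMSE %.4g\n",
              object@transform, object@meanTerm, object@r2, object@rmse))
  print(round(c(object@beta, object@betaSurface), 5))
})

setMethod("show", "EmulatorModel", function(object) {
  nm <- length(object@months)
  cat(sprintf("EmulatorModel: %d x %d grid, %d months, variables %s\n",
              length(object@geometry@lon), length(object@geometry@lat),
              nm, paste(object@variables, collapse = ", ")))
  for (v in object@variables) {
    ok <- object@fits[[v]]$ok
    cat(sprintf("  %s (%s): %d/%d pixel-months fit\n", v,
                object@fits[[v]]$transform, sum(ok), length(ok)))
  }
})

setMethod("show", "SelectionResult", function(object) {
  cat(sprintf(
    "SelectionResult: %d train / %d test epochs; %d candidates in %d draws\n",
    length(object@trainIndices), length(object@testIndices),
    object@candidateCount, object@nIterations))
})

setMethod("show", "BioclimSet", function(object) {
  cat(sprintf("BioclimSet: %d layers + tmin, %d epochs, %d x %d cells\n",
              length(object@layers), length(object@epochs),
              length(object@geometry@lon), length(object@geometry@lat)))
  cat("  layers:", paste(names(object@layers), collapse = ", "), "\n")
})

setMethod("show", "ProxyRecord", function(object) {
  cat(sprintf("ProxyRecord '%s' (%s) at (%.1fE, %.1fN): %d samples, %g-%g ka\n",
              object@name, object@type, object@lon, object@lat,
              length(object@age), min(object@age), max(object@age)))
})

setMethod("show", "SyntheticWorld", function(object) {
  cat(sprintf(
    "SyntheticWorld: %d x %d grid, %d snapshot epochs, %d extended epochs\n",
    length(object@geometry@lon), length(object@geometry@lat),
    length(object@forcings@epochs), length(object@forcingsExtended@epochs)))
  cat("  variables:", paste(object@variables, collapse = ", "),
      "| months:", length(object@months), "| seed:", object@seed, "\n")
})

setMethod("show", "ReferenceClimatology", function(object) {
  cat(sprintf(
    "ReferenceClimatology at %g ka: %d x %d cells, %d valid, months %d\n",
    object@epoch, length(object@geometry@lon), length(object@geometry@lat),
    sum(object@valid), length(object@months)))
})
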