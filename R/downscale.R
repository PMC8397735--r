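#' The standard 0.5 degree output geometry
#'
#' @param resolution grid spacing in degrees, default 0.5 (720 x 360).
#' @return a [GridGeometry-class] with centers at
#'   -179.75..179.75 E, -89.75..89.75 N for the default resolution.
#' @export
fineGeometry <- function(resolution = 0.5) {
  gridGeometry(seq(-180 + resolution / 2, 180 - resolution / 2,
                   by = resolution),
               seq(-90 + resolution / 2, 90 - resolution / 2,
                   by = resolution))
}

#' Refine a coarse geometry by an integer factor
#'
#' Subdivides the coarse domain into `factor` times as many cells per axis.
#' The latitude domain is the coarse cell edges clipped to +/-90.
#'
#' @param geom a coarse [GridGeometry-class].
#' @param factor integer refinement factor, >= 1.
#' @return a fine [GridGeometry-class].
#' @export
refineGeometry <- function(geom, factor = 2L) {
  stopifnot(factor >= 1, factor == round(factor))
  nlon <- length(geom@lon) * factor
  dlon <- 360 / nlon
  lon0 <- geom@lon[1L] - (geom@lon[2L] - geom@lon[1L]) / 2
  lon <- lon0 + (seq_len(nlon) - 0.5) * dlon
  lon <- ((lon + 180) %% 360) - 180
  lon <- sort(lon)
  dy <- geom@lat[2L] - geom@lat[1L]
  edge0 <- max(-90, geom@lat[1L] - dy / 2)
  edge1 <- min(90, geom@lat[length(geom@lat)] + dy / 2)
  nlat <- length(geom@lat) * factor
  dlat <- (edge1 - edge0) / nlat
  lat <- edge0 + (seq_len(nlat) - 0.5) * dlat
  gridGeometry(lon, lat)
}

#' Bilinear regridding operator between two regular grids
#'
#' Precomputes, for every target cell, the indices of the four surrounding
#' source cell centers and their bilinear weights.  Longitude is treated as
#' periodic; target latitudes outside the source center range raise an
#' error.
#'
#' @param src,dst [GridGeometry-class] source and target geometries.
#' @return list with integer matrix `idx` (ndst x 4, flattened source
#'   indices, longitude fastest) and numeric matrix `w` (ndst x 4 weights
#'   summing to 1).
#' @export
makeRegridOperator <- function(src, dst) {
  nlo <- length(src@lon); nla <- length(src@lat)
  dx <- src@lon[2L] - src@lon[1L]
  ## longitude: periodic position in cell units
  p <- (dst@lon - src@lon[1L]) / dx
  p <- p %% nlo
  i0 <- floor(p)
  fx <- p - i0
  i0 <- (as.integer(i0) %% nlo) + 1L
  i1 <- (i0 %% nlo) + 1L
  ## latitude: clamped to the valid span, error outside
  latrange <- range(src@lat)
  if (any(dst@lat < latrange[1L] - 1e-9 | dst@lat > latrange[2L] + 1e-9))
    stop(sprintf(
      "target latitude outside source span [%g, %g] (latitude is not periodic)",
      latrange[1L], latrange[2L]))
  dyl <- src@lat[2L] - src@lat[1L]
  q <- (dst@lat - src@lat[1L]) / dyl
  q <- pmin(pmax(q, 0), nla - 1)
  j0 <- pmin(floor(q), nla - 2)
  fy <- q - j0
  j0 <- as.integer(j0) + 1L
  j1 <- j0 + 1L

  ndlo <- length(dst@lon); ndla <- length(dst@lat)
  I0 <- rep(i0, ndla); I1 <- rep(i1, ndla)
  FX <- rep(fx, ndla)
  J0 <- rep(j0, each = ndlo); J1 <- rep(j1, each = ndlo)
  FY <- rep(fy, each = ndlo)
  idx <- cbind(I0 + (J0 - 1L) * nlo, I1 + (J0 - 1L) * nlo,
               I0 + (J1 - 1L) * nlo, I1 + (J1 - 1L) * nlo)
  w <- cbind((1 - FX) * (1 - FY), FX * (1 - FY),
             (1 - FX) * FY, FX * FY)
  list(idx = idx, w = w, dims = c(ndlo, ndla))
}

#' Apply a precomputed regridding operator to one field slice
#'
#' @param op operator from [makeRegridOperator()].
#' @param srcValues numeric matrix (or flattened vector) on the source
#'   grid, longitude fastest.
#' @return numeric vector on the target grid, longitude fastest.
#' @export
applyRegrid <- function(op, srcValues) {
  v4 <- matrix(srcValues[op$idx], nrow(op$idx), 4L)
  out <- rowSums(op$w * v4)
  bad <- which(!is.finite(out))
  if (length(bad)) {
    ## coastal/unfit neighbors: fall back to the nearest (max-weight)
    ## finite source neighbor of the four
    wb <- op$w[bad, , drop = FALSE]
    vb <- v4[bad, , drop = FALSE]
    wb[!is.finite(vb)] <- -Inf
    pick <- max.col(wb, ties.method = "first")
    sel <- cbind(seq_along(bad), pick)
    repl <- vb[sel]
    repl[!is.finite(wb[sel]) | wb[sel] < 0] <- NA_real_
    out[bad] <- repl
  }
  out
}

#' Bilinearly regrid a climate field
#'
#' Standard bilinear interpolation from the four surrounding coarse cell
#' centers, longitude periodic.  Constant fields map to the same constant
#' and fields linear in lon/lat are reproduced exactly.  Target cells whose
#' four coarse neighbors include missing values take the nearest valid
#' neighbor's value (count reported via message); cells with no valid
#' neighbor stay missing.
#'
#' @param coarse a [ClimateField-class] on the source grid.
#' @param targetGeometry the output [GridGeometry-class].
#' @param op optional precomputed operator from [makeRegridOperator()]
#'   (saves rebuilding it across fields on the same grids).
#' @return a [ClimateField-class] on the target grid.
#' @export
bilinearRegrid <- function(coarse, targetGeometry, op = NULL) {
  if (is.null(op)) op <- makeRegridOperator(coarse@geometry, targetGeometry)
  nT <- length(coarse@epochs)
  out <- array(NA_real_, c(op$dims, nT))
  for (t in seq_len(nT))
    out[, , t] <- applyRegrid(op, coarse@values[, , t])
  climateField(coarse@variable, coarse@units, targetGeometry,
               coarse@epochs, out)
}

#' Additive delta bias correction
#'
#' Corrects an emulated field stack against a reference climatology at the
#' reference epoch: the corrected value is the reference plus the emulated
#' anomaly relative to the emulated reference-epoch field, i.e.
#' \eqn{\hat Y(x,t) = Y_{ref}(x,0) + [Y_{LM}(x,t) - Y_{LM}(x,0)]},
#' applied per cell and month.  The formulation guarantees that the
#' corrected reference epoch reproduces the reference exactly, and the
#' additive delta preserves all simulated anomalies between epochs.
#'
#' Cells where the reference is invalid keep the raw emulated value by
#' default (flagged in the provenance layer) or are set missing.
#' Bounded variables are clamped post hoc (precipitation floored at 0,
#' cloud to [0, 1]); clamp counts are reported and attached.
#'
#' @param emulated a [ClimateField-class] stack on the fine grid.
#' @param emulatedAtReference a single-epoch [ClimateField-class] of the
#'   emulation at the reference epoch, same grid.
#' @param reference a single-epoch [ClimateField-class] (NA = invalid
#'   cell) or numeric matrix of the reference climatology.
#' @param validMask optional logical matrix overriding the reference's
#'   NA pattern.
#' @param clamp apply post-hoc bound clamping (default TRUE).  Disable to
#'   verify anomaly preservation exactly.
#' @param fillInvalid "raw" (default) keeps raw emulated values outside
#'   the reference mask; "missing" masks them.
#' @return a [ClimateField-class]; `attr(fieldValues(x), "provenance")`
#'   is a matrix marking "corrected"/"raw"/"missing" cells and
#'   `attr(fieldValues(x), "clamped")` the clamp count.
#' @export
deltaCorrect <- function(emulated, emulatedAtReference, reference,
                         validMask = NULL, clamp = TRUE,
                         fillInvalid = c("raw", "missing")) {
  fillInvalid <- match.arg(fillInvalid)
  refM <- if (is(reference, "ClimateField")) {
    if (!identical(reference@units, emulated@units))
      stop(sprintf("unit mismatch: reference '%s' vs emulated '%s'",
                   reference@units, emulated@units))
    reference@values[, , 1L]
  } else reference
  emu0 <- emulatedAtReference@values[, , 1L]
  d <- dim(emulated@values)
  if (!all(dim(refM) == d[1:2]) || !all(dim(emu0) == d[1:2]))
    stop("geometry mismatch between emulated, reference and reference-epoch fields")
  valid <- if (is.null(validMask)) is.finite(refM) else validMask

  out <- array(NA_real_, d)
  for (t in seq_len(d[3L])) {
    emut <- emulated@values[, , t]
    sl <- refM + (emut - emu0)
    sl[!valid] <- if (fillInvalid == "raw") emut[!valid] else NA_real_
    out[, , t] <- sl
  }
  nclamp <- 0L
  if (clamp) {
    if (emulated@variable == "precipitation") {
      low <- !is.na(out) & out < 0
      nclamp <- sum(low); out[low] <- 0
    } else if (emulated@variable == "cloud") {
      bad <- !is.na(out) & (out < 0 | out > 1)
      nclamp <- sum(bad)
      out[!is.na(out)] <- pmin(pmax(out[!is.na(out)], 0), 1)
    }
    if (nclamp > 0L)
      message(sprintf("deltaCorrect: %d %s value(s) clamped to bounds",
                      nclamp, emulated@variable))
  }
  prov <- matrix(ifelse(valid, "corrected",
                        if (fillInvalid == "raw") "raw" else "missing"),
                 d[1L], d[2L])
  attr(out, "provenance") <- prov
  attr(out, "clamped") <- nclamp
  new("ClimateField", variable = emulated@variable, units = emulated@units,
      geometry = emulated@geometry, epochs = emulated@epochs, values = out)
}

#' Model bias map at the reference epoch
#'
#' Elementwise difference between the emulated reference-epoch field and
#' the observed reference climatology on valid cells.
#'
#' @param emulatedAtReference a single-epoch [ClimateField-class].
#' @param reference a single-epoch [ClimateField-class] or matrix
#'   (NA = invalid).
#' @param validMask optional logical matrix.
#' @return a single-epoch [ClimateField-class] of emulated minus reference.
#' @export
biasMap <- function(emulatedAtReference, reference, validMask = NULL) {
  refM <- if (is(reference, "ClimateField")) reference@values[, , 1L]
  else reference
  emu0 <- emulatedAtReference@values[, , 1L]
  if (!all(dim(refM) == dim(emu0)))
    stop("geometry mismatch between emulated and reference fields")
  valid <- if (is.null(validMask)) is.finite(refM) else validMask
  b <- emu0 - refM
  b[!valid] <- NA_real_
  climateField(paste0(emulatedAtReference@variable, "_bias"),
               emulatedAtReference@units, emulatedAtReference@geometry,
               emulatedAtReference@epochs[1L], b)
}

#' Extract one variable/month of a reference climatology as a field
#'
#' @param reference a [ReferenceClimatology-class].
#' @param variable variable name.
#' @param month month label, default "ann".
#' @return a single-epoch [ClimateField-class], NA outside the valid mask.
#' @export
referenceField <- function(reference, variable, month = "ann") {
  m <- match(month, reference@months)
  if (is.na(m)) stop("month not present in reference: ", month)
  v <- reference@fields[[variable]][, , m]
  v[!reference@valid] <- NA_real_
  units <- if (variable %in% names(VARIABLE_UNITS))
    VARIABLE_UNITS[[variable]] else "1"
  climateField(variable, units, reference@geometry, reference@epoch, v)
}
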