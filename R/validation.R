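#' Goodness maps: fit R-squared and held-out RMSE per pixel
#'
#' R-squared comes from the fit diagnostics (training data); RMSE is the
#' root mean squared prediction error over the held-out test epochs,
#' computed on the natural scale of each variable.
#'
#' @param model an [EmulatorModel-class].
#' @param testSnapshots a [SnapshotSet-class] at epochs disjoint from the
#'   training epochs.
#' @param forcings a [ForcingTable-class] covering the test epochs.
#' @return a [GoodnessMaps-class].
#' @export
goodnessMaps <- function(model, testSnapshots, forcings) {
  if (length(testSnapshots@epochs) == 0L)
    stop("empty test set")
  if (length(intersect(testSnapshots@epochs, model@trainEpochs)))
    stop("test epochs overlap the training epochs")
  pred <- suppressWarnings(
    predict(model, forcings, testSnapshots@mask,
            atEpochs = testSnapshots@epochs))
  r2 <- rmse <- list()
  for (v in model@variables) {
    r2[[v]] <- model@fits[[v]]$r2
    err <- pred@fields[[v]] - testSnapshots@fields[[v]]
    rmse[[v]] <- sqrt(apply(err^2, c(1L, 2L, 3L), mean))
  }
  new("GoodnessMaps", geometry = model@geometry, months = model@months,
      r2 = r2, rmse = rmse)
}

#' Spatial covariance matrix of a field stack
#'
#' The covariance between the time series of any two grid cells over the
#' stack's epochs (unbiased denominator).  Cells that are missing at any
#' epoch are dropped; the retained flattened cell indices (longitude
#' fastest) are attached as attribute `"pixels"`.
#'
#' @param fields a [ClimateField-class] stack (>= 2 epochs) or a matrix
#'   with one row per cell and one column per epoch.
#' @return symmetric covariance matrix of dimension = retained cell count.
#' @export
spatialCovariance <- function(fields) {
  m <- if (is(fields, "ClimateField")) {
    d <- dim(fields@values)
    matrix(fields@values, d[1L] * d[2L], d[3L])
  } else as.matrix(fields)
  if (ncol(m) < 2L)
    stop("need at least 2 epochs for a covariance")
  keep <- which(stats::complete.cases(m))
  cv <- stats::cov(t(m[keep, , drop = FALSE]))
  attr(cv, "pixels") <- keep
  cv
}

#' Compare the spatial covariance of truth and emulation
#'
#' Computes both pixel-by-pixel covariance matrices over the common cells
#' and epochs, their difference, and Frobenius norms, quantifying how well
#' the per-pixel emulator preserves the original model's spatial structure.
#'
#' @param truth,emulated [ClimateField-class] stacks on the same grid and
#'   epochs.
#' @return list with `truth`, `emulated`, `difference` matrices, their
#'   Frobenius norms `normTruth`, `normEmulated`, `normDifference`, and
#'   the retained `pixels`.
#' @export
covarianceSummary <- function(truth, emulated) {
  stopifnot(all(dim(truth@values) == dim(emulated@values)))
  d <- dim(truth@values)
  mt <- matrix(truth@values, d[1L] * d[2L], d[3L])
  me <- matrix(emulated@values, d[1L] * d[2L], d[3L])
  keep <- which(stats::complete.cases(mt) & stats::complete.cases(me))
  ct <- stats::cov(t(mt[keep, , drop = FALSE]))
  ce <- stats::cov(t(me[keep, , drop = FALSE]))
  dd <- ce - ct
  frob <- function(x) sqrt(sum(x^2))
  list(truth = ct, emulated = ce, difference = dd,
       normTruth = frob(ct), normEmulated = frob(ce),
       normDifference = frob(dd), pixels = keep)
}

## nearest grid cell containing a lon/lat point (longitude periodic)
.cellAt <- function(geom, lon, lat) {
  dl <- abs(((geom@lon - lon + 180) %% 360) - 180)
  i <- which.min(dl)
  j <- which.min(abs(geom@lat - lat))
  c(i, j)
}

#' Correlate an emulated series with a proxy record
#'
#' Extracts the model time series at the grid cell containing the proxy
#' location, pairs every proxy sample with the nearest model epoch within
#' `maxGap` ka (unmatched samples are dropped and counted), and returns
#' the correlation of the paired series.  Correlation is invariant to
#' affine rescaling of the proxy, so records in arbitrary units (d18O,
#' dust flux, ...) can be compared without conversion.
#'
#' @param fields a [ClimateField-class] stack (e.g. annual mean
#'   temperature over the reconstruction epochs).
#' @param proxy a [ProxyRecord-class].
#' @param maxGap maximum proxy-to-epoch age distance in ka (default 0.5,
#'   half the product resolution).
#' @param method "pearson" (default) or "spearman".
#' @return the correlation coefficient, with attributes `n` (pairs used)
#'   and `dropped` (unmatched proxy samples).
#' @export
proxyCorrelation <- function(fields, proxy, maxGap = 0.5,
                             method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ij <- .cellAt(fields@geometry, proxy@lon, proxy@lat)
  series <- fields@values[ij[1L], ij[2L], ]
  if (all(!is.finite(series))) {
    ## suggest the nearest cell with data
    d <- dim(fields@values)
    finiteCells <- which(apply(is.finite(fields@values), c(1L, 2L), all),
                         arr.ind = TRUE)
    hint <- if (nrow(finiteCells)) {
      dist2 <- (fields@geometry@lat[finiteCells[, 2L]] - proxy@lat)^2 +
        (((fields@geometry@lon[finiteCells[, 1L]] - proxy@lon + 180) %%
            360) - 180)^2
      nb <- finiteCells[which.min(dist2), ]
      sprintf("; nearest valid cell is (%.2fE, %.2fN)",
              fields@geometry@lon[nb[1L]], fields@geometry@lat[nb[2L]])
    } else ""
    stop(sprintf("proxy '%s' falls on a masked cell%s", proxy@name, hint))
  }
  nearest <- vapply(proxy@age, function(a) {
    k <- which.min(abs(fields@epochs - a))
    if (abs(fields@epochs[k] - a) <= maxGap) k else NA_integer_
  }, integer(1))
  keep <- !is.na(nearest) & is.finite(series[pmax(nearest, 1L)])
  if (sum(keep) < 3L)
    stop(sprintf("only %d proxy samples matched a model epoch (need >= 3)",
                 sum(keep)))
  r <- stats::cor(proxy@value[keep], series[nearest[keep]], method = method)
  attr(r, "n") <- sum(keep)
  attr(r, "dropped") <- sum(!keep)
  r
}

#' Proxy correlation table
#'
#' Applies [proxyCorrelation()] to a list of records and assembles the
#' standard validation table (name, lon, lat, correlation, type, samples
#' used).
#'
#' @param fields a [ClimateField-class] stack.
#' @param proxies list of [ProxyRecord-class] objects.
#' @param ... passed to [proxyCorrelation()].
#' @return data.frame with one row per record.
#' @export
proxyCorrelationTable <- function(fields, proxies, ...) {
  rows <- lapply(proxies, function(p) {
    r <- proxyCorrelation(fields, p, ...)
    data.frame(name = p@name, lon = p@lon, lat = p@lat,
               corr = as.numeric(r), type = p@type, n = attr(r, "n"))
  })
  do.call(rbind, rows)
}
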