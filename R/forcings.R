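#' Snapshot epoch schedule
#'
#' The canonical snapshot schedule of the underlying GCM ensemble: 120 to
#' 24 ka BP in 2 ka steps and 22 to 0 ka BP in 1 ka steps, 72 epochs in
#' total, ordered oldest first.
#'
#' @return integer vector of 72 epochs in ka BP.
#' @examples
#' length(snapshotEpochs())  # 72
#' @export
snapshotEpochs <- function() {
  as.integer(c(seq(120L, 24L, by = -2L), seq(22L, 0L, by = -1L)))
}

#' Interpolate an irregular CO2 series to a target epoch axis
#'
#' Piecewise-linear interpolation of an ice-core style CO2 record to the
#' regular epoch axis of the reconstruction.  Values at raw sample times
#' are reproduced exactly; extrapolation is refused.
#'
#' @param age numeric sample ages in ka BP (any order, no duplicates).
#' @param co2 numeric concentrations in ppm at `age`.
#' @param targetEpochs numeric epochs in ka BP to interpolate to.
#' @return numeric CO2 values at `targetEpochs`.
#' @examples
#' interpolateCO2(c(0, 2), c(280, 260), 1)  # 270
#' @export
interpolateCO2 <- function(age, co2, targetEpochs) {
  stopifnot(length(age) == length(co2), length(age) >= 2L)
  if (anyDuplicated(age)) stop("duplicate ages in the raw CO2 series")
  lo <- min(targetEpochs); hi <- max(targetEpochs)
  if (lo < min(age) || hi > max(age))
    stop(sprintf(
      "CO2 interpolation would extrapolate: raw series covers %g-%g ka but %g-%g ka requested",
      min(age), max(age), lo, hi))
  stats::approx(age, co2, xout = targetEpochs, method = "linear")$y
}

#' Z-score the forcing block
#'
#' Subtracts the mean and divides by the standard deviation of each forcing
#' column.  With `stats` absent the statistics are computed from `table`
#' and returned for reuse; with `stats` supplied (prediction time) the
#' stored fitting-time statistics are applied unchanged.
#'
#' @param table a [ForcingTable-class] (or an n x 4 matrix with the
#'   canonical column names).
#' @param stats optional [NormalizationStats-class] to reuse.
#' @return list with `block` (z-scored n x 4 matrix) and `stats`
#'   (the [NormalizationStats-class] that reproduces the transform).
#' @export
normalizeForcings <- function(table, stats = NULL) {
  m <- if (is(table, "ForcingTable")) forcingMatrix(table) else {
    stopifnot(is.matrix(table), identical(colnames(table), FORCING_NAMES))
    table
  }
  if (is.null(stats)) {
    mu <- colMeans(m)
    sg <- apply(m, 2L, stats::sd)
    zero <- sg <= 0 | !is.finite(sg)
    if (any(zero))
      stop("zero-variance forcing column(s): ",
           paste(colnames(m)[zero], collapse = ", "))
    stats <- new("NormalizationStats", mean = mu, sd = sg)
  } else {
    stopifnot(is(stats, "NormalizationStats"))
  }
  z <- sweep(sweep(m, 2L, stats@mean[colnames(m)]), 2L,
             stats@sd[colnames(m)], "/")
  list(block = z, stats = stats)
}

#' Undo the forcing z-scoring
#'
#' @param block z-scored matrix as returned by [normalizeForcings()].
#' @param stats the [NormalizationStats-class] used to produce it.
#' @return matrix on the original scale.
#' @export
denormalizeForcings <- function(block, stats) {
  sweep(sweep(block, 2L, stats@sd[colnames(block)], "*"), 2L,
        stats@mean[colnames(block)], "+")
}

#' Subset a forcing table by epoch
#'
#' @param table a [ForcingTable-class].
#' @param epochs epochs (ka BP) to keep, in the requested order.
#' @return a [ForcingTable-class] restricted to `epochs`.
#' @export
subsetForcings <- function(table, epochs) {
  idx <- match(epochs, table@epochs)
  if (anyNA(idx))
    stop("epochs missing from forcing table: ",
         paste(epochs[is.na(idx)], collapse = ", "))
  forcingTable(table@epochs[idx], table@co2[idx], table@obliquity[idx],
               table@precessionI[idx], table@precessionII[idx])
}

#' Read a forcing table from delimited text
#'
#' Expects columns `time` (ka BP), `co2` (ppm), `obliquity` (degrees),
#' `esinw` and `ecosw` (dimensionless precession indices), tab- or
#' comma-separated.
#'
#' @param path file path.
#' @return a [ForcingTable-class].
#' @export
readForcingTable <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else "\t"
  d <- utils::read.delim(path, sep = sep, check.names = FALSE)
  need <- c("time", "co2", "obliquity", "esinw", "ecosw")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("forcing file lacks column(s): ", paste(miss, collapse = ", "))
  forcingTable(d$time, d$co2, d$obliquity, d$esinw, d$ecosw)
}

#' Write a forcing table as delimited text
#'
#' @param table a [ForcingTable-class].
#' @param path file path.
#' @return invisibly, `path`.
#' @export
writeForcingTable <- function(table, path) {
  d <- data.frame(time = table@epochs, co2 = table@co2,
                  obliquity = table@obliquity, esinw = table@precessionI,
                  ecosw = table@precessionII)
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
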