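#' Quarter statistic of a monthly series
#'
#' Quarters are the 12 consecutive three-month windows, with December to
#' January wrap-around.  The window is selected by the extremal sum of the
#' selector series (maximal for "wettest"/"warmest", minimal for
#' "driest"/"coldest"; ties go to the earliest window) and the statistic of
#' the companion series over that window is returned.
#'
#' @param monthly numeric selector series of 12 values (e.g. monthly
#'   precipitation when selecting the wettest quarter).
#' @param mode "wettest", "driest", "warmest" or "coldest".
#' @param statSource numeric companion series of 12 values to summarize
#'   over the selected window; defaults to `monthly`.
#' @param stat "mean" or "sum" of the companion over the window.
#' @return list with `quarter` (index of the starting month) and `value`.
#' @examples
#' quarterStat(1:12, "warmest")        # quarter 10 (Oct-Dec), mean 11
#' @export
quarterStat <- function(monthly, mode = c("wettest", "driest", "warmest",
                                          "coldest"),
                        statSource = monthly, stat = c("mean", "sum")) {
  mode <- match.arg(mode)
  stat <- match.arg(stat)
  stopifnot(length(monthly) == 12L, length(statSource) == 12L,
            all(is.finite(monthly)))
  wrap <- function(m) ((m - 1L) %% 12L) + 1L
  sums <- vapply(1:12, function(w)
    sum(monthly[wrap(w:(w + 2L))]), numeric(1))
  q <- if (mode %in% c("wettest", "warmest")) which.max(sums)
  else which.min(sums)
  win <- statSource[wrap(q:(q + 2L))]
  list(quarter = as.integer(q),
       value = if (stat == "mean") mean(win) else sum(win))
}

## vectorized quarter machinery: x is an N x 12 matrix; returns N x 12
## window sums
.quarterSums <- function(x) {
  qs <- matrix(0, nrow(x), 12L)
  for (w in 1:12) {
    m <- ((w:(w + 2L) - 1L) %% 12L) + 1L
    qs[, w] <- x[, m[1L]] + x[, m[2L]] + x[, m[3L]]
  }
  qs
}

#' Derive the bioclimatic variables from monthly temperature and
#' precipitation
#'
#' Computes the 17 layers BIO1 and BIO4-BIO19 plus minimum annual
#' temperature.  BIO2 (diurnal range) and BIO3 (isothermality) require
#' monthly temperature extremes that monthly means do not contain and are
#' never emitted.  Conventions:
#' \itemize{
#'   \item temperatures are converted K to degrees C for the BIO layers;
#'     the extra minimum-annual-temperature layer stays in K;
#'   \item BIO4 is the population standard deviation of the 12 monthly
#'     means in degrees C (no x100 scaling);
#'   \item BIO5/BIO6 are the warmest/coldest monthly-mean extremes, so
#'     BIO7 = BIO5 - BIO6 >= 0;
#'   \item monthly precipitation is a rate in mm/yr; BIO12 is the annual
#'     mean rate, and month/quarter totals (BIO13/14, BIO16-19) convert
#'     the rate uniformly at 1/12 per month;
#'   \item BIO15 is 100 * sd/mean of monthly precipitation (population
#'     sd), 0 where the mean is 0;
#'   \item quarters are sliding 3-month windows with wrap-around, ties to
#'     the earliest window (see [quarterStat()]).
#' }
#'
#' @param temperature array (nlon, nlat, 12) or (nlon, nlat, 12, ntime)
#'   of monthly-mean temperature in K.
#' @param precipitation same shape, monthly precipitation rate in mm/yr.
#' @param geometry the [GridGeometry-class] of the fields.
#' @param epochs time axis in ka BP (default 0 for single-epoch input).
#' @return a [BioclimSet-class].
#' @export
computeBioclim <- function(temperature, precipitation, geometry,
                           epochs = NULL) {
  dT <- dim(temperature)
  if (length(dT) == 3L) {
    temperature <- array(temperature, c(dT, 1L))
    precipitation <- array(precipitation, c(dim(precipitation), 1L))
    dT <- dim(temperature)
  }
  if (dT[3L] != 12L) stop("need 12 monthly fields, got ", dT[3L])
  if (!all(dim(precipitation) == dT))
    stop("temperature and precipitation shapes differ")
  if (is.null(epochs)) epochs <- seq_len(dT[4L]) - 1
  nlon <- dT[1L]; nlat <- dT[2L]; nt <- dT[4L]
  N <- nlon * nlat * nt

  ## rows = (pixel, time), columns = month
  Tm <- matrix(aperm(temperature, c(1L, 2L, 4L, 3L)), N, 12L)
  Pm <- matrix(aperm(precipitation, c(1L, 2L, 4L, 3L)), N, 12L)
  okRow <- stats::complete.cases(Tm) & stats::complete.cases(Pm)
  Tm0 <- Tm; Pm0 <- Pm
  Tm0[!okRow, ] <- 0; Pm0[!okRow, ] <- 0

  tC <- Tm0 - 273.15
  bio01 <- rowMeans(tC)
  bio04 <- sqrt(rowMeans((tC - bio01)^2))
  colMax <- function(x) Reduce(pmax, lapply(seq_len(ncol(x)), function(k) x[, k]))
  colMin <- function(x) Reduce(pmin, lapply(seq_len(ncol(x)), function(k) x[, k]))
  bio05 <- colMax(tC)
  bio06 <- colMin(tC)
  bio07 <- bio05 - bio06

  qsP <- .quarterSums(Pm0)
  qsT <- .quarterSums(tC)
  wet <- max.col(qsP, ties.method = "first")
  dry <- max.col(-qsP, ties.method = "first")
  warm <- max.col(qsT, ties.method = "first")
  cold <- max.col(-qsT, ties.method = "first")
  at <- function(m, idx) m[cbind(seq_len(nrow(m)), idx)]

  bio08 <- at(qsT, wet) / 3
  bio09 <- at(qsT, dry) / 3
  bio10 <- at(qsT, warm) / 3
  bio11 <- at(qsT, cold) / 3

  bio12 <- rowMeans(Pm0)
  bio13 <- colMax(Pm0) / 12
  bio14 <- colMin(Pm0) / 12
  sdP <- sqrt(rowMeans((Pm0 - bio12)^2))
  bio15 <- ifelse(bio12 > 0, 100 * sdP / bio12, 0)
  bio16 <- at(qsP, wet) / 12
  bio17 <- at(qsP, dry) / 12
  bio18 <- at(qsP, warm) / 12
  bio19 <- at(qsP, cold) / 12
  tmin <- colMin(Tm0)

  shape <- function(v) {
    v[!okRow] <- NA_real_
    aperm(array(v, c(nlon, nlat, nt)), c(1L, 2L, 3L))
  }
  layers <- list(bio01 = bio01, bio04 = bio04, bio05 = bio05,
                 bio06 = bio06, bio07 = bio07, bio08 = bio08,
                 bio09 = bio09, bio10 = bio10, bio11 = bio11,
                 bio12 = bio12, bio13 = bio13, bio14 = bio14,
                 bio15 = bio15, bio16 = bio16, bio17 = bio17,
                 bio18 = bio18, bio19 = bio19)
  layers <- lapply(layers, shape)
  units <- c(bio01 = "degC", bio04 = "degC", bio05 = "degC",
             bio06 = "degC", bio07 = "degC", bio08 = "degC",
             bio09 = "degC", bio10 = "degC", bio11 = "degC",
             bio12 = "mm year-1", bio13 = "mm", bio14 = "mm",
             bio15 = "1", bio16 = "mm", bio17 = "mm", bio18 = "mm",
             bio19 = "mm", tmin = "K")
  new("BioclimSet", geometry = geometry, epochs = as.numeric(epochs),
      layers = layers, tminAnnual = shape(tmin), units = units)
}

#' Derive bioclim layers from a snapshot set
#'
#' Convenience wrapper extracting the 12 monthly temperature and
#' precipitation fields of a [SnapshotSet-class] and calling
#' [computeBioclim()].
#'
#' @param snapshots a [SnapshotSet-class] containing `temperature` and
#'   `precipitation` with all 12 months.
#' @return a [BioclimSet-class].
#' @export
bioclimFromSnapshots <- function(snapshots) {
  mons <- tolower(month.abb)
  miss <- setdiff(mons, snapshots@months)
  if (length(miss))
    stop("missing month(s) for bioclim: ", paste(miss, collapse = ", "))
  mi <- match(mons, snapshots@months)
  for (v in c("temperature", "precipitation"))
    if (!v %in% names(snapshots@fields))
      stop("snapshot set lacks ", v)
  computeBioclim(snapshots@fields$temperature[, , mi, , drop = FALSE],
                 snapshots@fields$precipitation[, , mi, , drop = FALSE],
                 snapshots@geometry, snapshots@epochs)
}
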