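## Smooth pseudo-random field on the grid: a short sum of low-order
## harmonics with coefficients/phases drawn from the caller's RNG stream,
## rescaled to the requested amplitude.
.smoothField <- function(nlon, nlat, amplitude = 1) {
  u <- seq(0, 2 * pi, length.out = nlon + 1L)[seq_len(nlon)]
  v <- seq(0, pi, length.out = nlat)
  f <- matrix(0, nlon, nlat)
  for (h in 1:3) for (k in 1:3)
    f <- f + stats::rnorm(1, 0, 1 / (h + k)) *
      outer(cos(h * u + stats::runif(1, 0, 2 * pi)),
            cos(k * v + stats::runif(1, 0, 2 * pi)))
  amplitude * f / max(abs(f))
}

## Deterministic forcing curves.  CO2 is a ~100 ka sawtooth in
## [180, 300] ppm; obliquity a 41 ka cycle in [22, 24.5] degrees; the
## precession indices are an amplitude-modulated ~21 ka cycle bounded by
## 0.06.  The seed only shifts integer phases, so shared epochs of the
## snapshot and extended tables agree exactly.
.forcingCurves <- function(t, seed) {
  ph <- withSeed(seed, sample.int(100L, 4L))
  saw <- ((t + ph[1L]) %% 100) / 100
  co2 <- 180 + 120 * (1 - saw)
  obliquity <- 23.25 + 1.25 * sin(2 * pi * (t + ph[2L]) / 41)
  ecc <- 0.035 + 0.025 * sin(2 * pi * (t + ph[3L]) / 96)
  wph <- 2 * pi * (t + ph[4L]) / 21.7
  list(co2 = co2, obliquity = obliquity,
       precessionI = ecc * sin(wph), precessionII = ecc * cos(wph),
       ## glacial index quantized to 4 states so the surface-type history
       ## realizes the same level set over snapshots and extension
       glacial = floor(pmin(saw, 0.9999) * 4) / 3)
}

#' Generate a synthetic forcing table
#'
#' Smooth pseudo-periodic late Pleistocene style forcings: CO2 in
#' [180, 300] ppm with a ~100 ka sawtooth, obliquity in [22, 24.5] degrees
#' at a 41 ka period, precession indices bounded by 0.06 at a ~21 ka
#' period.
#'
#' @param seed integer seed (shifts the cycle phases).
#' @param atEpochs epochs in ka BP; default the 72-epoch snapshot schedule
#'   of [snapshotEpochs()].
#' @return a [ForcingTable-class].
#' @export
makeForcings <- function(seed = 1, atEpochs = snapshotEpochs()) {
  fc <- .forcingCurves(atEpochs, seed)
  forcingTable(atEpochs, fc$co2, fc$obliquity, fc$precessionI,
               fc$precessionII)
}

#' Build a complete synthetic world with known truth
#'
#' Generates forcings at the snapshot epochs and over the full 800 ka
#' extension, a topography/sea-level/ice driven surface-type history, and
#' true coefficient and mean fields for each variable and month on the
#' transformed scale, under the fitting model's own structure (linear
#' response to z-scored forcings plus per-surface-type intercepts).  The
#' stored truth supports parameter-recovery and end-to-end identity
#' checks.
#'
#' @param nlon,nlat coarse grid size, default 12 x 10 (latitudes include
#'   the poles, which the emulator excludes, mirroring the full-scale
#'   96 x 73 layout).
#' @param months month labels to generate, default all 12 plus "ann".
#' @param variables default temperature, precipitation, cloud.
#' @param noiseSd named transformed-scale noise standard deviations.
#' @param seed integer seed.
#' @return a [SyntheticWorld-class].
#' @export
syntheticWorld <- function(nlon = 12L, nlat = 10L,
                           months = MONTH_LABELS,
                           variables = c("temperature", "precipitation",
                                         "cloud"),
                           noiseSd = c(temperature = 0.2,
                                       precipitation = 0.1, cloud = 0.1),
                           seed = 1) {
  geom <- gridGeometry(seq(-180, 180 - 360 / nlon, by = 360 / nlon),
                       seq(-90, 90, length.out = nlat))
  extEpochs <- seq(800, 0, by = -1)
  forcings <- makeForcings(seed, snapshotEpochs())
  forcingsExt <- makeForcings(seed, extEpochs)
  stats <- normalizeForcings(forcings)$stats

  fc <- .forcingCurves(extEpochs, seed)
  seaLevel <- -130 * fc$glacial
  topo <- withSeed(seed + 1L, .smoothField(nlon, nlat, 2500))
  iceLat <- 80 - 20 * fc$glacial
  latM <- matrix(rep(geom@lat, each = nlon), nlon, nlat)
  ice <- array(FALSE, c(nlon, nlat, length(extEpochs)))
  for (t in seq_along(extEpochs))      # ice sheets ground on present land
    ice[, , t] <- abs(latM) > iceLat[t] & topo > 0
  surface <- buildSurfaceMask(topo, seaLevel, ice, geometry = geom,
                              epochs = extEpochs)

  ## transformed-scale truth per variable: spatial amplitude of the
  ## forcing responses, surface-type offsets and mean fields
  amp <- list(
    temperature = list(beta = 1.5, land = 1.5, ice = -8,
                       base = 285 - 25 * abs(latM) / 90, var = 6),
    precipitation = list(beta = 0.15, land = 0.12, ice = -0.5,
                         base = log(700) - 0.8 * abs(latM) / 90, var = 0.5),
    cloud = list(beta = 0.2, land = -0.15, ice = 0.25,
                 base = 0.3 - 0.6 * abs(latM) / 90, var = 0.6))
  betaTrue <- meanTrue <- list()
  nm <- length(months)
  withSeed(seed + 2L, {
    for (v in variables) {
      a <- amp[[v]]
      bt <- array(0, c(nlon, nlat, nm, 6L))
      mt <- array(0, c(nlon, nlat, nm))
      for (m in seq_len(nm)) {
        for (k in 1:4) bt[, , m, k] <- .smoothField(nlon, nlat, a$beta)
        bt[, , m, 5L] <- a$land + .smoothField(nlon, nlat, abs(a$land) / 3)
        bt[, , m, 6L] <- a$ice + .smoothField(nlon, nlat, abs(a$ice) / 4)
        mt[, , m] <- a$base + .smoothField(nlon, nlat, a$var)
      }
      betaTrue[[v]] <- bt
      meanTrue[[v]] <- mt
    }
  })
  new("SyntheticWorld", geometry = geom, months = months,
      variables = variables, forcings = forcings,
      forcingsExtended = forcingsExt, surface = surface,
      betaTrue = betaTrue, meanTrue = meanTrue, stats = stats,
      noiseSd = noiseSd[variables], topography = topo,
      seaLevel = seaLevel, seed = seed)
}

#' Noise-free truth fields of a synthetic world
#'
#' Evaluates the world's generating model at the requested epochs on the
#' natural scale of each variable.
#'
#' @param world a [SyntheticWorld-class].
#' @param atEpochs epochs in ka BP (must lie on the extended axis).
#' @param variables subset of the world's variables.
#' @return named list of arrays (nlon, nlat, nmonth, nepoch).
#' @export
trueFields <- function(world, atEpochs = world@forcings@epochs,
                       variables = world@variables) {
  z <- normalizeForcings(subsetForcings(world@forcingsExtended, atEpochs),
                         stats = world@stats)$block
  msk <- subsetMask(world@surface, atEpochs)
  nlon <- length(world@geometry@lon); nlat <- length(world@geometry@lat)
  nm <- length(world@months); nT <- length(atEpochs)
  out <- list()
  for (v in variables) {
    kind <- VARIABLE_TRANSFORM[[v]]
    bt <- world@betaTrue[[v]]
    arr <- array(NA_real_, c(nlon, nlat, nm, nT))
    for (m in seq_len(nm)) {
      for (t in seq_len(nT)) {
        lin <- world@meanTrue[[v]][, , m] +
          bt[, , m, 1L] * z[t, 1L] + bt[, , m, 2L] * z[t, 2L] +
          bt[, , m, 3L] * z[t, 3L] + bt[, , m, 4L] * z[t, 4L]
        sl <- msk@codes[, , t]
        lin <- lin + bt[, , m, 5L] * (sl == SURFACE_LEVELS[["land"]]) +
          bt[, , m, 6L] * (sl == SURFACE_LEVELS[["land_ice"]])
        arr[, , m, t] <- inverseTransform(lin, kind)
      }
    }
    out[[v]] <- arr
  }
  out
}

#' Generate snapshot climatologies from a synthetic world
#'
#' Transformed-scale fields are the world's linear truth plus Gaussian
#' noise at the stored per-variable standard deviation, inverse-
#' transformed per variable; bounded variables therefore respect their
#' bounds by construction.
#'
#' @param world a [SyntheticWorld-class].
#' @param atEpochs snapshot epochs, default the world's 72.
#' @param noiseSd optional override of the per-variable noise sd.
#' @return a [SnapshotSet-class].
#' @export
makeSnapshots <- function(world, atEpochs = world@forcings@epochs,
                          noiseSd = world@noiseSd) {
  truth <- trueFields(world, atEpochs)
  fields <- withSeed(world@seed + 3L, {
    lapply(world@variables, function(v) {
      kind <- VARIABLE_TRANSFORM[[v]]
      arr <- transformValues(truth[[v]], kind)
      sdv <- if (v %in% names(noiseSd)) noiseSd[[v]] else 0
      if (sdv > 0)
        arr <- arr + array(stats::rnorm(length(arr), 0, sdv), dim(arr))
      array(inverseTransform(arr, kind), dim(arr))
    })
  })
  names(fields) <- world@variables
  new("SnapshotSet", geometry = world@geometry,
      epochs = as.numeric(atEpochs), months = world@months,
      fields = fields, mask = subsetMask(world@surface, atEpochs))
}

#' Generate a fine-grid present-day reference climatology
#'
#' The reference is the regridded world truth at the reference epoch plus
#' a smooth synthetic observation-bias field (emulating the systematic
#' difference between a climate model and gridded observations), valid on
#' land cells only.
#'
#' @param world a [SyntheticWorld-class].
#' @param fineFactor integer refinement factor of the output grid.
#' @param biasAmplitude named natural-scale bias amplitudes; zero gives a
#'   bias-free reference (the delta correction then becomes the identity
#'   at the reference epoch).
#' @param epoch reference epoch, default 0 ka.
#' @return a [ReferenceClimatology-class].
#' @export
makeReference <- function(world, fineFactor = 2L,
                          biasAmplitude = c(temperature = 2,
                                            precipitation = 100,
                                            cloud = 0.05),
                          epoch = 0) {
  fine <- refineGeometry(world@geometry, fineFactor)
  op <- makeRegridOperator(world@geometry, fine)
  truth <- trueFields(world, atEpochs = epoch)
  nlon <- length(fine@lon); nlat <- length(fine@lat)
  nm <- length(world@months)
  fields <- list()
  withSeed(world@seed + 4L, {
    for (v in world@variables) {
      a <- if (v %in% names(biasAmplitude)) biasAmplitude[[v]] else 0
      arr <- array(NA_real_, c(nlon, nlat, nm))
      for (m in seq_len(nm)) {
        f <- matrix(applyRegrid(op, truth[[v]][, , m, 1L]), nlon, nlat)
        if (a != 0) {
          f <- f + .smoothField(nlon, nlat, a)
          if (v == "precipitation") f <- pmax(f, 0.1)
          if (v == "cloud") f <- pmin(pmax(f, 0.001), 0.999)
        }
        arr[, , m] <- f
      }
      fields[[v]] <- arr
    }
  })
  ## land-only validity (no ocean, no ice), nearest-neighbor class
  msk0 <- subsetMask(world@surface, epoch)@codes[, , 1L]
  iNear <- vapply(fine@lon, function(x)
    which.min(abs(((world@geometry@lon - x + 180) %% 360) - 180)),
    integer(1))
  jNear <- vapply(fine@lat, function(y)
    which.min(abs(world@geometry@lat - y)), integer(1))
  valid <- matrix(msk0[iNear, jNear] == SURFACE_LEVELS[["land"]],
                  nlon, nlat)
  new("ReferenceClimatology", geometry = fine, months = world@months,
      fields = fields, valid = valid, epoch = epoch)
}

#' Generate synthetic proxy records
#'
#' Places `n` sites on land cells, samples the local true annual-mean
#' temperature at irregular ages, and adds Gaussian noise at the requested
#' signal-to-noise ratio (sd of noise = sd of signal / snr).  Records can
#' be affine-rescaled to mimic non-temperature proxy units; correlation
#' against the reconstruction is invariant to that.
#'
#' @param world a [SyntheticWorld-class].
#' @param n number of records.
#' @param snr signal-to-noise ratio; `Inf` gives noise-free records.
#' @param seed integer seed.
#' @param nSamples samples per record.
#' @param scale,offset affine transform applied to the proxy values.
#' @return list of [ProxyRecord-class] objects.
#' @export
makeProxies <- function(world, n = 5L, snr = 2, seed = world@seed,
                        nSamples = 120L, scale = 1, offset = 0) {
  mAnn <- match("ann", world@months)
  if (is.na(mAnn)) stop("world has no annual month for proxy truth")
  ext <- world@forcingsExtended@epochs
  truth <- trueFields(world, atEpochs = ext,
                      variables = "temperature")$temperature
  msk0 <- subsetMask(world@surface, 0)@codes[, , 1L]
  nonPole <- matrix(rep(abs(world@geometry@lat) < 90,
                        each = length(world@geometry@lon)),
                    nrow(msk0), ncol(msk0))
  landCells <- which(msk0 == SURFACE_LEVELS[["land"]] & nonPole,
                     arr.ind = TRUE)
  if (nrow(landCells) < 1L) stop("no land cells to place proxies on")
  withSeed(seed + 5L, {
    picks <- landCells[sample.int(nrow(landCells), n, replace = n >
                                    nrow(landCells)), , drop = FALSE]
    lapply(seq_len(n), function(r) {
      i <- picks[r, 1L]; j <- picks[r, 2L]
      ages <- sort(stats::runif(nSamples, 0, 800))
      sig <- stats::approx(ext, truth[i, j, mAnn, ], xout = ages)$y
      noise <- if (is.finite(snr)) stats::rnorm(nSamples, 0,
                                                stats::sd(sig) / snr)
      else 0
      proxyRecord(sprintf("SYN-%02d", r),
                  world@geometry@lon[i], world@geometry@lat[j],
                  ages, scale * (sig + noise) + offset,
                  type = "synthetic temperature")
    })
  })
}
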