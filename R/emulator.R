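COEF_NAMES <- c(FORCING_NAMES, "land", "land_ice")

#' Fit the regression for a single grid box
#'
#' Ordinary least squares of the transformed-scale anomaly (the series
#' minus its training-epoch mean) on the four z-scored forcings plus a
#' treatment-coded surface-type factor.  Surface levels never observed at
#' the pixel get no dummy column; the reference level is the first
#' observed level in the canonical order (ocean, land, land ice), so ocean
#' carries a zero offset by construction whenever it occurs.  The dummies
#' act as level-specific intercepts; the fitted reference-level intercept
#' is folded into the stored mean term, so a prediction at the forcing
#' origin over the reference surface type reproduces `meanTerm` exactly.
#'
#' @param y numeric transformed-scale values at the training epochs.
#' @param forcings n x 4 z-scored forcing matrix (canonical column order).
#' @param surface character or integer surface-type per epoch (codes 0/1/2
#'   or names "ocean"/"land"/"land_ice").
#' @param transform transform label recorded in the result.
#' @return a [PixelModel-class]; rank-deficient designs yield an unfit
#'   model (`ok = FALSE`) with a reason, never an error.
#' @export
fitPixel <- function(y, forcings, surface, transform = "identity") {
  n <- length(y)
  stopifnot(nrow(forcings) == n, length(surface) == n)
  if (n < 7L) stop("need at least 7 training epochs, got ", n)
  if (is.numeric(surface))
    surface <- names(SURFACE_LEVELS)[match(surface, SURFACE_LEVELS)]
  unfit <- function(reason)
    new("PixelModel", transform = transform, meanTerm = NA_real_,
        beta = setNames(rep(NA_real_, 4L), FORCING_NAMES),
        betaSurface = c(land = NA_real_, land_ice = NA_real_),
        se = setNames(rep(NA_real_, 6L), COEF_NAMES),
        pvalues = setNames(rep(NA_real_, 6L), COEF_NAMES),
        r2 = NA_real_, rmse = NA_real_, fittedLevels = character(0),
        ok = FALSE, reason = reason)
  if (any(!is.finite(y))) return(unfit("nonfinite_response"))

  meanY <- mean(y)
  dy <- y - meanY
  levels_here <- intersect(names(SURFACE_LEVELS), unique(surface))
  ref <- levels_here[1L]
  dat <- as.data.frame(forcings)
  names(dat) <- FORCING_NAMES
  dummies <- setdiff(levels_here, ref)
  for (lev in dummies) dat[[lev]] <- as.numeric(surface == lev)
  dat$.dy <- dy
  fit <- stats::lm(.dy ~ ., data = dat)
  cf <- stats::coef(fit)
  if (anyNA(cf)) return(unfit("rank_deficient"))

  res <- stats::residuals(fit)
  sst <- sum(dy^2)
  ssr <- sum(res^2)
  r2 <- if (sst <= 0) 0 else 1 - ssr / sst
  rmse <- sqrt(mean(res^2))
  ct <- suppressWarnings(stats::coef(summary(fit)))  # est, se, t, p

  beta <- setNames(cf[FORCING_NAMES], FORCING_NAMES)
  betaSurface <- c(land = NA_real_, land_ice = NA_real_)
  if (ref != "ocean") betaSurface[ref] <- 0
  betaSurface[dummies] <- cf[dummies]
  se <- pv <- setNames(rep(NA_real_, 6L), COEF_NAMES)
  keepRows <- intersect(rownames(ct), COEF_NAMES)
  se[keepRows] <- ct[keepRows, 2L]
  pv[keepRows] <- ct[keepRows, 4L]

  new("PixelModel", transform = transform,
      meanTerm = meanY + cf[["(Intercept)"]],
      beta = beta, betaSurface = betaSurface, se = se, pvalues = pv,
      r2 = r2, rmse = rmse, fittedLevels = levels_here, ok = TRUE,
      reason = "")
}

#' Fit the per-pixel emulator over a whole snapshot set
#'
#' Applies the variable transform, then fits every non-pole pixel for each
#' month (and the annual mean) of each variable with [fitPixel()].  Pole
#' rows (|lat| = 90) are excluded: the underlying GCM's bounded variables
#' reach exact zeros there and the log/logit transforms are undefined.
#' Forcing normalization statistics are computed from the training epochs
#' and stored for prediction-time reuse.
#'
#' @param snapshots a [SnapshotSet-class].
#' @param trainEpochs epochs (ka BP) to fit on; default all snapshot
#'   epochs.
#' @param forcings a [ForcingTable-class] covering the training epochs.
#' @param precipFloor positive floor (mm/yr) applied to non-positive
#'   precipitation before the log transform; clamped cells are counted and
#'   reported.
#' @return an [EmulatorModel-class].
#' @export
fitGrid <- function(snapshots, trainEpochs = NULL, forcings,
                    precipFloor = 0.1) {
  if (is.null(trainEpochs)) trainEpochs <- snapshots@epochs
  if (!all(trainEpochs %in% snapshots@epochs))
    stop("training epochs missing from snapshots: ",
         paste(setdiff(trainEpochs, snapshots@epochs), collapse = ", "))
  norm <- normalizeForcings(subsetForcings(forcings, trainEpochs))
  z <- norm$block
  tIdx <- match(trainEpochs, snapshots@epochs)
  geom <- snapshots@geometry
  nlon <- length(geom@lon); nlat <- length(geom@lat)
  months <- snapshots@months
  nm <- length(months)
  codes <- snapshots@mask@codes[, , tIdx, drop = FALSE]

  levelsObserved <- array(FALSE, c(nlon, nlat, 3L),
                          dimnames = list(NULL, NULL, names(SURFACE_LEVELS)))
  for (l in seq_along(SURFACE_LEVELS))
    levelsObserved[, , l] <- apply(codes == SURFACE_LEVELS[l], c(1L, 2L), any)

  polar <- abs(geom@lat) == 90
  fits <- list()
  for (v in names(snapshots@fields)) {
    kind <- VARIABLE_TRANSFORM[[v]]
    vals <- snapshots@fields[[v]][, , , tIdx, drop = FALSE]
    if (kind == "log") {
      low <- !is.na(vals) & vals < precipFloor
      if (any(low)) {
        message(sprintf("fitGrid: %d %s value(s) below the %g mm/yr floor clamped",
                        sum(low), v, precipFloor))
        vals[low] <- precipFloor
      }
    }
    coefA <- seA <- pvA <- array(NA_real_, c(nlon, nlat, nm, 6L))
    meanA <- r2A <- rmseA <- array(NA_real_, c(nlon, nlat, nm))
    okA <- array(FALSE, c(nlon, nlat, nm))
    reasonA <- array("", c(nlon, nlat, nm))
    for (j in seq_len(nlat)) {
      if (polar[j]) { reasonA[, j, ] <- "pole"; next }
      for (i in seq_len(nlon)) {
        surf <- codes[i, j, ]
        for (m in seq_len(nm)) {
          yv <- vals[i, j, m, ]
          if (any(!is.finite(yv))) { reasonA[i, j, m] <- "nonfinite_response"; next }
          y <- transformValues(yv, kind,
                               context = sprintf("%s/%s pixel (%d,%d)", v, months[m], i, j))
          pm <- fitPixel(y, z, surf, transform = kind)
          okA[i, j, m] <- pm@ok
          reasonA[i, j, m] <- pm@reason
          if (pm@ok) {
            coefA[i, j, m, ] <- c(pm@beta, pm@betaSurface)
            seA[i, j, m, ] <- pm@se
            pvA[i, j, m, ] <- pm@pvalues
            meanA[i, j, m] <- pm@meanTerm
            r2A[i, j, m] <- pm@r2
            rmseA[i, j, m] <- pm@rmse
          }
        }
      }
    }
    fits[[v]] <- list(transform = kind, coef = coefA, se = seA, pval = pvA,
                      meanTerm = meanA, r2 = r2A, rmse = rmseA, ok = okA,
                      reason = reasonA)
  }
  new("EmulatorModel", geometry = geom, months = months,
      variables = names(snapshots@fields), stats = norm$stats,
      trainEpochs = as.numeric(trainEpochs),
      levelsObserved = levelsObserved, fits = fits)
}

#' Extract the regression record of one pixel
#'
#' @param model an [EmulatorModel-class].
#' @param variable variable name.
#' @param i,j longitude/latitude cell indices.
#' @param month month label ("jan".."dec", "ann").
#' @return a [PixelModel-class].
#' @export
pixelModel <- function(model, variable, i, j, month = "ann") {
  f <- model@fits[[variable]]
  if (is.null(f)) stop("variable not in model: ", variable)
  m <- match(month, model@months)
  if (is.na(m)) stop("month not in model: ", month)
  lv <- names(SURFACE_LEVELS)[levelsAt(model, i, j)]
  new("PixelModel", transform = f$transform,
      meanTerm = f$meanTerm[i, j, m],
      beta = setNames(f$coef[i, j, m, 1:4], FORCING_NAMES),
      betaSurface = setNames(f$coef[i, j, m, 5:6], c("land", "land_ice")),
      se = setNames(f$se[i, j, m, ], COEF_NAMES),
      pvalues = setNames(f$pval[i, j, m, ], COEF_NAMES),
      r2 = f$r2[i, j, m], rmse = f$rmse[i, j, m],
      fittedLevels = lv, ok = f$ok[i, j, m], reason = f$reason[i, j, m])
}

levelsAt <- function(model, i, j) which(model@levelsObserved[i, j, ])

## Effective surface-type offsets per pixel, substituting the nearest
## fitted level (by code distance, ties toward the smaller code) for
## levels never observed at that pixel during training.
effectiveSurfaceBeta <- function(model, variable, m) {
  f <- model@fits[[variable]]
  nlon <- dim(f$coef)[1L]; nlat <- dim(f$coef)[2L]
  bLand <- f$coef[, , m, 5L]
  bIce <- f$coef[, , m, 6L]
  obsL <- model@levelsObserved[, , "land"]
  obsI <- model@levelsObserved[, , "land_ice"]
  obsO <- model@levelsObserved[, , "ocean"]
  ## land missing: nearest fitted is ocean (dist 1, code 0) before ice
  ## (dist 1, code 2) -- ties to the smaller code
  fixL <- !obsL
  if (any(fixL)) {
    bLand[fixL & obsO] <- 0
    onlyIce <- fixL & !obsO & obsI
    bLand[onlyIce] <- bIce[onlyIce]
  }
  ## ice missing: nearest fitted is land (dist 1) before ocean (dist 2)
  fixI <- !obsI
  if (any(fixI)) {
    useLand <- fixI & obsL
    bIce[useLand] <- bLand[useLand]
    bIce[fixI & !obsL] <- 0
  }
  bLand[is.na(bLand)] <- 0
  bIce[is.na(bIce)] <- 0
  list(land = bLand, land_ice = bIce,
       missing = list(ocean = !obsO, land = fixL, land_ice = fixI))
}

#' Predict climate fields from a fitted emulator
#'
#' Evaluates the per-pixel regressions at arbitrary epochs: the forcings
#' are z-scored with the model's fitting-time statistics, the linear
#' response and the surface-type offset for each epoch's mask are added to
#' the mean term, and the result is mapped back to the natural scale.
#' Bounded variables therefore respect their bounds strictly.  Pixels whose
#' mask level at an epoch was never observed during training receive the
#' offset of the nearest fitted level (a warning reports the count).
#' Unfit and pole pixels propagate as NA.
#'
#' @param object an [EmulatorModel-class].
#' @param forcings a [ForcingTable-class] covering the requested epochs.
#' @param masks a [SurfaceTypeGrid-class] covering the requested epochs.
#' @param atEpochs epochs (ka BP) to reconstruct; default all epochs of
#'   `forcings`.
#' @return a [SnapshotSet-class] of reconstructed fields.
#' @export
setMethod("predict", "EmulatorModel",
          function(object, forcings, masks, atEpochs = NULL) {
  if (is.null(atEpochs)) atEpochs <- forcings@epochs
  ft <- subsetForcings(forcings, atEpochs)          # errors on missing epoch
  msk <- subsetMask(masks, atEpochs)
  z <- normalizeForcings(ft, stats = object@stats)$block
  geom <- object@geometry
  nlon <- length(geom@lon); nlat <- length(geom@lat)
  nm <- length(object@months)
  nT <- length(atEpochs)
  polar <- matrix(rep(abs(geom@lat) == 90, each = nlon), nlon, nlat)

  fields <- list()
  totalSub <- 0L
  for (v in object@variables) {
    f <- object@fits[[v]]
    out <- array(NA_real_, c(nlon, nlat, nm, nT))
    for (m in seq_len(nm)) {
      eff <- effectiveSurfaceBeta(object, v, m)
      b <- lapply(1:4, function(k) f$coef[, , m, k])
      mu <- f$meanTerm[, , m]
      okm <- f$ok[, , m] & !polar
      for (t in seq_len(nT)) {
        lin <- mu + b[[1L]] * z[t, 1L] + b[[2L]] * z[t, 2L] +
          b[[3L]] * z[t, 3L] + b[[4L]] * z[t, 4L]
        sl <- msk@codes[, , t]
        isLand <- sl == SURFACE_LEVELS[["land"]]
        isIce <- sl == SURFACE_LEVELS[["land_ice"]]
        lin <- lin + eff$land * isLand + eff$land_ice * isIce
        totalSub <- totalSub +
          sum(okm & ((isLand & eff$missing$land) |
                     (isIce & eff$missing$land_ice) |
                     (sl == SURFACE_LEVELS[["ocean"]] & eff$missing$ocean)))
        lin[!okm] <- NA_real_
        out[, , m, t] <- inverseTransform(lin, f$transform)
      }
    }
    fields[[v]] <- out
  }
  if (totalSub > 0L)
    warning(sprintf(
      "predict: %d pixel-months used a substituted surface level (level never observed in training)",
      totalSub))
  new("SnapshotSet", geometry = geom, epochs = as.numeric(atEpochs),
      months = object@months, fields = fields, mask = msk)
})

#' Extract one variable/month stack as a climate field
#'
#' @param snapshots a [SnapshotSet-class].
#' @param variable variable name.
#' @param month month label, default "ann".
#' @return a [ClimateField-class] with the variable's conventional units.
#' @export
snapshotField <- function(snapshots, variable, month = "ann") {
  m <- match(month, snapshots@months)
  if (is.na(m)) stop("month not present: ", month)
  if (!variable %in% names(snapshots@fields))
    stop("variable not present: ", variable)
  units <- if (variable %in% names(VARIABLE_UNITS))
    VARIABLE_UNITS[[variable]] else "1"
  climateField(variable, units, snapshots@geometry, snapshots@epochs,
               snapshots@fields[[variable]][, , m, , drop = TRUE])
}
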