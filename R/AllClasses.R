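## Surface-type integer codes used throughout (NetCDF flag_values convention)
SURFACE_LEVELS <- c(ocean = 0L, land = 1L, land_ice = 2L)

## Forcing columns in canonical order; beta_1..beta_4 follow this order
FORCING_NAMES <- c("obliquity", "precession_i", "precession_ii", "co2")

## Monthly + annual climatology labels
MONTH_LABELS <- c(tolower(month.abb), "ann")

## Variable -> transform / units conventions
VARIABLE_TRANSFORM <- c(temperature = "identity", precipitation = "log",
                        cloud = "logit")
VARIABLE_UNITS <- c(temperature = "K", precipitation = "mm year-1",
                    cloud = "1")

.check_regular <- function(x, what) {
  if (length(x) < 2L) return(sprintf("%s needs at least 2 points", what))
  d <- diff(x)
  if (any(d <= 0)) return(sprintf("%s must be strictly increasing", what))
  if (max(abs(d - d[1])) > 1e-6 * abs(d[1]))
    return(sprintf("%s spacing is not regular", what))
  NULL
}

#' Regular longitude/latitude grid geometry
#'
#' Cell-center coordinates of a regular lon/lat grid.  Longitudes are kept in
#' [-180, 180) and treated as periodic; latitudes are in [-90, 90].
#'
#' @slot lon numeric vector of cell-center longitudes (degrees east),
#'   strictly increasing and regularly spaced.
#' @slot lat numeric vector of cell-center latitudes (degrees north),
#'   strictly increasing and regularly spaced.
#' @exportClass GridGeometry
setClass("GridGeometry", representation(lon = "numeric", lat = "numeric"),
         validity = function(object) {
           errs <- c(.check_regular(object@lon, "lon"),
                     .check_regular(object@lat, "lat"))
           if (any(object@lat < -90 | object@lat > 90))
             errs <- c(errs, "lat outside [-90, 90]")
           if (any(object@lon < -180 | object@lon >= 180))
             errs <- c(errs, "lon outside [-180, 180)")
           if (length(errs)) errs else TRUE
         })

#' Construct a grid geometry from center coordinates
#' @param lon,lat numeric vectors of cell-center coordinates.
#' @return A [GridGeometry-class] object.
#' @export
gridGeometry <- function(lon, lat) new("GridGeometry", lon = lon, lat = lat)

#' External forcing table
#'
#' Per-epoch external predictors of the emulator: atmospheric CO2, obliquity
#' and the two precession indices.  Epochs are integers in ka BP (thousands
#' of years before present, positive into the past).
#'
#' @slot epochs numeric, strictly monotonic, in ka BP.
#' @slot co2 numeric, ppm, positive.
#' @slot obliquity numeric, degrees.
#' @slot precessionI numeric, e sin(w), dimensionless.
#' @slot precessionII numeric, e cos(w), dimensionless.
#' @exportClass ForcingTable
setClass("ForcingTable",
         representation(epochs = "numeric", co2 = "numeric",
                        obliquity = "numeric", precessionI = "numeric",
                        precessionII = "numeric"),
         validity = function(object) {
           n <- length(object@epochs)
           errs <- character()
           if (any(lengths(list(object@co2, object@obliquity,
                                object@precessionI, object@precessionII)) != n))
             errs <- c(errs, "all forcing columns must match length(epochs)")
           d <- diff(object@epochs)
           if (n > 1L && !(all(d > 0) || all(d < 0)))
             errs <- c(errs, "epochs must be strictly monotonic")
           if (any(!is.finite(c(object@co2, object@obliquity,
                                object@precessionI, object@precessionII))))
             errs <- c(errs, "forcing columns must be finite")
           if (any(object@co2 <= 0))
             errs <- c(errs, "co2 must be positive")
           if (length(errs)) errs else TRUE
         })

#' Construct a forcing table
#'
#' @param epochs numeric epochs in ka BP.
#' @param co2 CO2 concentration in ppm.
#' @param obliquity obliquity in degrees.
#' @param precessionI precession index I (e sin w).
#' @param precessionII precession index II (e cos w).
#' @return A [ForcingTable-class] object.
#' @export
forcingTable <- function(epochs, co2, obliquity, precessionI, precessionII) {
  new("ForcingTable", epochs = as.numeric(epochs), co2 = co2,
      obliquity = obliquity, precessionI = precessionI,
      precessionII = precessionII)
}

#' Normalization statistics for the forcing block
#'
#' Per-forcing mean and standard deviation used to z-score the predictors.
#' The statistics computed at fitting time must be reused for all prediction
#' epochs, since the fitted coefficients are only meaningful under the
#' fitting-time scaling.
#'
#' @slot mean named numeric means, one per forcing.
#' @slot sd named numeric standard deviations, one per forcing, all positive.
#' @exportClass NormalizationStats
setClass("NormalizationStats",
         representation(mean = "numeric", sd = "numeric"),
         validity = function(object) {
           errs <- character()
           if (!identical(names(object@mean), names(object@sd)))
             errs <- c(errs, "mean and sd must share names")
           if (any(object@sd <= 0))
             errs <- c(errs, "all standard deviations must be positive")
           if (length(errs)) errs else TRUE
         })

#' Categorical surface-type history on a grid
#'
#' Per-epoch classification of every grid cell as ocean (0), land (1) or
#' land ice (2).
#'
#' @slot geometry the [GridGeometry-class] shared by all epochs.
#' @slot epochs numeric epochs in ka BP.
#' @slot codes integer array (nlon, nlat, nepoch) with values in {0, 1, 2}.
#' @exportClass SurfaceTypeGrid
setClass("SurfaceTypeGrid",
         representation(geometry = "GridGeometry", epochs = "numeric",
                        codes = "array"),
         validity = function(object) {
           d <- dim(object@codes)
           errs <- character()
           if (length(d) != 3L ||
               !all(d == c(length(object@geometry@lon),
                           length(object@geometry@lat),
                           length(object@epochs))))
             errs <- c(errs, "codes must be (nlon, nlat, nepoch)")
           if (!all(object@codes %in% SURFACE_LEVELS))
             errs <- c(errs, "codes must be 0 (ocean), 1 (land) or 2 (land_ice)")
           if (length(errs)) errs else TRUE
         })

#' A gridded climate variable with time axis
#'
#' @slot variable one of "temperature", "precipitation", "cloud" (or a
#'   derived-layer name).
#' @slot units physical units ("K", "mm year-1", "1", ...).
#' @slot geometry the [GridGeometry-class].
#' @slot epochs numeric time axis in ka BP.
#' @slot values numeric array (nlon, nlat, ntime); NA marks masked/unfit
#'   cells.
#' @exportClass ClimateField
setClass("ClimateField",
         representation(variable = "character", units = "character",
                        geometry = "GridGeometry", epochs = "numeric",
                        values = "array"),
         validity = function(object) {
           d <- dim(object@values)
           if (length(d) != 3L ||
               !all(d == c(length(object@geometry@lon),
                           length(object@geometry@lat),
                           length(object@epochs))))
             return("values must be (nlon, nlat, ntime)")
           TRUE
         })

#' Construct a climate field
#' @param variable variable name.
#' @param units units string.
#' @param geometry a [GridGeometry-class].
#' @param epochs time axis in ka BP.
#' @param values array (nlon, nlat, ntime); a matrix is promoted to a
#'   single-epoch array.
#' @return A [ClimateField-class].
#' @export
climateField <- function(variable, units, geometry, epochs, values) {
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  new("ClimateField", variable = variable, units = units,
      geometry = geometry, epochs = as.numeric(epochs), values = values)
}

#' A stack of snapshot climatologies with their surface-type masks
#'
#' Holds, for each climate variable, monthly (and annual) mean fields at a
#' set of dated epochs, plus the surface-type grid at the same epochs.
#'
#' @slot geometry the coarse [GridGeometry-class].
#' @slot epochs numeric snapshot epochs in ka BP.
#' @slot months character subset of `c("jan", ..., "dec", "ann")`.
#' @slot fields named list (by variable) of arrays
#'   (nlon, nlat, nmonth, nepoch) on the natural scale.
#' @slot mask the [SurfaceTypeGrid-class] at the same epochs.
#' @exportClass SnapshotSet
setClass("SnapshotSet",
         representation(geometry = "GridGeometry", epochs = "numeric",
                        months = "character", fields = "list",
                        mask = "SurfaceTypeGrid"),
         validity = function(object) {
           dexp <- c(length(object@geometry@lon), length(object@geometry@lat),
                     length(object@months), length(object@epochs))
           for (v in names(object@fields)) {
             if (!all(dim(object@fields[[v]]) == dexp))
               return(sprintf("field '%s' must be (nlon, nlat, nmonth, nepoch)", v))
           }
           if (!all(object@months %in% MONTH_LABELS))
             return("months must be jan..dec or ann")
           if (!isTRUE(all.equal(object@mask@epochs, object@epochs)))
             return("mask epochs must equal snapshot epochs")
           TRUE
         })

#' Single-pixel regression record
#'
#' The fitted emulator for one grid box, one month, one variable: the
#' transform, the transformed-scale mean term, the four forcing coefficients
#' and the surface-type intercept shifts, with diagnostics.
#'
#' @slot transform "identity", "log" or "logit".
#' @slot meanTerm transformed-scale baseline: the training-epoch mean plus
#'   the fitted reference-level intercept, i.e. the predicted level at the
#'   forcing origin over the reference surface type.
#' @slot beta named numeric (obliquity, precession_i, precession_ii, co2)
#'   for the z-scored forcings.
#' @slot betaSurface named numeric (land, land_ice); the ocean level is the
#'   reference and fixed at 0; NA for levels never observed at this pixel.
#' @slot se,pvalues standard errors and two-sided t-test p-values for the
#'   fitted coefficients (same layout as `c(beta, betaSurface)`).
#' @slot r2 coefficient of determination on the training data (0 when the
#'   response has no variance).
#' @slot rmse transformed-scale root mean squared residual.
#' @slot fittedLevels character levels observed at this pixel.
#' @slot ok logical; FALSE when the pixel could not be fit.
#' @slot reason skip reason when `ok` is FALSE ("" otherwise).
#' @exportClass PixelModel
setClass("PixelModel",
         representation(transform = "character", meanTerm = "numeric",
                        beta = "numeric", betaSurface = "numeric",
                        se = "numeric", pvalues = "numeric", r2 = "numeric",
                        rmse = "numeric", fittedLevels = "character",
                        ok = "logical", reason = "character"))

#' Grid-wide emulator model
#'
#' One regression record per (pixel, month, variable), stored as dense
#' arrays, together with the normalization statistics used at fit time.
#' Coefficient arrays have a trailing dimension of length 6 ordered
#' (obliquity, precession_i, precession_ii, co2, land, land_ice).
#'
#' @slot geometry the coarse [GridGeometry-class].
#' @slot months character month labels fitted.
#' @slot variables character variables fitted.
#' @slot stats the [NormalizationStats-class] used to z-score forcings.
#' @slot trainEpochs epochs used for fitting, ka BP.
#' @slot levelsObserved logical array (nlon, nlat, 3): surface levels seen
#'   at each pixel over the training epochs.
#' @slot fits named list (by variable) of lists with arrays `coef`, `se`,
#'   `pval` (nlon, nlat, nmonth, 6), `meanTerm`, `r2`, `rmse`
#'   (nlon, nlat, nmonth), `ok` logical and `reason` character arrays, and
#'   the scalar `transform`.
#' @exportClass EmulatorModel
setClass("EmulatorModel",
         representation(geometry = "GridGeometry", months = "character",
                        variables = "character", stats = "NormalizationStats",
                        trainEpochs = "numeric", levelsObserved = "array",
                        fits = "list"))

#' Fine-grid present-day reference climatology
#'
#' Observation-based monthly/annual fields at the reference epoch on the
#' output grid, with a validity mask (typically land only).
#'
#' @slot geometry the fine [GridGeometry-class].
#' @slot months character month labels available.
#' @slot fields named list (by variable) of arrays (nlon, nlat, nmonth) on
#'   the natural scale.
#' @slot valid logical matrix (nlon, nlat): cells where the reference is
#'   defined.
#' @slot epoch reference epoch in ka BP (0 = present day).
#' @exportClass ReferenceClimatology
setClass("ReferenceClimatology",
         representation(geometry = "GridGeometry", months = "character",
                        fields = "list", valid = "matrix", epoch = "numeric"))

#' Bioclimatic variable set
#'
#' The 17 bioclimatic layers derivable from monthly-mean temperature and
#' precipitation (BIO1, BIO4-BIO19), plus minimum annual temperature.
#' BIO2 and BIO3 require monthly temperature extremes and are not derivable
#' from monthly means, hence never emitted.
#'
#' @slot geometry the [GridGeometry-class].
#' @slot epochs numeric time axis in ka BP.
#' @slot layers named list of 17 arrays (nlon, nlat, ntime): bio01,
#'   bio04..bio19.
#' @slot tminAnnual array (nlon, nlat, ntime), minimum monthly-mean
#'   temperature in K.
#' @slot units named character units per layer.
#' @exportClass BioclimSet
setClass("BioclimSet",
         representation(geometry = "GridGeometry", epochs = "numeric",
                        layers = "list", tminAnnual = "array",
                        units = "character"),
         validity = function(object) {
           if (length(object@layers) != 17L)
             return("exactly 17 bioclim layers expected (bio01, bio04..bio19)")
           if (any(c("bio02", "bio03") %in% names(object@layers)))
             return("bio02/bio03 cannot be derived from monthly means")
           TRUE
         })

#' Training-set selection configuration
#'
#' @slot trainFraction proportion of epochs used for training, in (0, 1].
#' @slot nIterations number of random subsets drawn.
#' @slot seed integer seed for the random stream.
#' @exportClass SelectionConfig
setClass("SelectionConfig",
         representation(trainFraction = "numeric", nIterations = "numeric",
                        seed = "numeric"),
         validity = function(object) {
           errs <- character()
           if (object@trainFraction <= 0 || object@trainFraction > 1)
             errs <- c(errs, "trainFraction must be in (0, 1]")
           if (object@nIterations < 1)
             errs <- c(errs, "nIterations must be >= 1")
           if (length(errs)) errs else TRUE
         })

#' Construct a selection configuration
#' @param trainFraction training proportion, default 0.8.
#' @param nIterations resampling count, default 10000.
#' @param seed integer seed, default 1.
#' @return A [SelectionConfig-class].
#' @export
selectionConfig <- function(trainFraction = 0.8, nIterations = 10000,
                            seed = 1) {
  new("SelectionConfig", trainFraction = trainFraction,
      nIterations = nIterations, seed = seed)
}

#' Result of the training/test split
#'
#' @slot trainIndices,testIndices integer indices into the epoch rows;
#'   disjoint, union = all epochs.
#' @slot counts integer appearance counts of each epoch in candidate
#'   subsets.
#' @slot candidateCount number of subsets that passed the eigenvalue
#'   dominance check.
#' @slot nIterations number of subsets examined.
#' @exportClass SelectionResult
setClass("SelectionResult",
         representation(trainIndices = "integer", testIndices = "integer",
                        counts = "integer", candidateCount = "integer",
                        nIterations = "integer"),
         validity = function(object) {
           n <- length(object@counts)
           if (length(intersect(object@trainIndices, object@testIndices)))
             return("train and test indices must be disjoint")
           if (!setequal(c(object@trainIndices, object@testIndices), seq_len(n)))
             return("train and test must partition the epochs")
           TRUE
         })

#' Per-pixel goodness maps
#'
#' R-squared of the fit (training data) and natural-scale RMSE against
#' held-out test snapshots, per variable and month.
#'
#' @slot geometry the coarse [GridGeometry-class].
#' @slot months character month labels.
#' @slot r2 named list (by variable) of arrays (nlon, nlat, nmonth).
#' @slot rmse named list (by variable) of arrays (nlon, nlat, nmonth).
#' @exportClass GoodnessMaps
setClass("GoodnessMaps",
         representation(geometry = "GridGeometry", months = "character",
                        r2 = "list", rmse = "list"))

#' A dated proxy record at a point location
#'
#' @slot name record identifier.
#' @slot lon,lat location in degrees.
#' @slot age numeric sample ages in ka BP, within [0, 800].
#' @slot value numeric proxy values (arbitrary units).
#' @slot type proxy type label (e.g. "SST", "d18O").
#' @slot unit optional unit string.
#' @exportClass ProxyRecord
setClass("ProxyRecord",
         representation(name = "character", lon = "numeric", lat = "numeric",
                        age = "numeric", value = "numeric", type = "character",
                        unit = "character"),
         validity = function(object) {
           errs <- character()
           if (length(object@age) != length(object@value))
             errs <- c(errs, "age and value must have equal length")
           if (any(object@age < 0 | object@age > 800))
             errs <- c(errs, "ages must lie within 0-800 ka BP")
           if (abs(object@lat) > 90)
             errs <- c(errs, "lat outside [-90, 90]")
           if (length(errs)) errs else TRUE
         })

#' Construct a proxy record
#' @param name record identifier.
#' @param lon,lat location in degrees.
#' @param age sample ages in ka BP.
#' @param value proxy values.
#' @param type proxy type label.
#' @param unit optional unit.
#' @return A [ProxyRecord-class].
#' @export
proxyRecord <- function(name, lon, lat, age, value, type = "unknown",
                        unit = "") {
  new("ProxyRecord", name = name, lon = lon, lat = lat,
      age = as.numeric(age), value = as.numeric(value), type = type,
      unit = unit)
}

#' Synthetic world: complete generated inputs with known truth
#'
#' Holds the true coefficient and mean fields per variable/month, the
#' forcing history (snapshot epochs and the 800 ka extension), the
#' surface-type history and the noise levels, so that every pipeline stage
#' can be exercised and checked against stored truth.
#'
#' @slot geometry the coarse [GridGeometry-class].
#' @slot months,variables labels generated.
#' @slot forcings [ForcingTable-class] at the snapshot epochs.
#' @slot forcingsExtended [ForcingTable-class] at 800..0 ka (1 ka steps).
#' @slot surface [SurfaceTypeGrid-class] over the extended epochs (which
#'   include every snapshot epoch).
#' @slot betaTrue named list (by variable) of arrays (nlon, nlat, nmonth, 6)
#'   of true coefficients on the transformed scale.
#' @slot meanTrue named list (by variable) of arrays (nlon, nlat, nmonth).
#' @slot stats the [NormalizationStats-class] defining the z-scoring under
#'   which the truth is expressed (snapshot-epoch statistics).
#' @slot noiseSd named numeric transformed-scale noise sd per variable.
#' @slot topography elevation matrix (m) used for the mask history.
#' @slot seaLevel numeric sea-level offsets (m) along the extended epochs.
#' @slot seed integer seed the world was built from.
#' @exportClass SyntheticWorld
setClass("SyntheticWorld",
         representation(geometry = "GridGeometry", months = "character",
                        variables = "character", forcings = "ForcingTable",
                        forcingsExtended = "ForcingTable",
                        surface = "SurfaceTypeGrid", betaTrue = "list",
                        meanTrue = "list", stats = "NormalizationStats",
                        noiseSd = "numeric", topography = "matrix",
                        seaLevel = "numeric", seed = "numeric"))
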