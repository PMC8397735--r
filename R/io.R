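#' Write a climate field to NetCDF
#'
#' CF-style layout: dimensions (lon, lat, time) with coordinate variables
#' `lon` (degrees_east), `lat` (degrees_north) and `time` in ka BP
#' (positive into the past), one data variable carrying a `units`
#' attribute.
#'
#' @param field a [ClimateField-class].
#' @param path output file path.
#' @param name NetCDF variable name; default the field's variable.
#' @return invisibly, `path`.
#' @export
writeClimateNetcdf <- function(field, path, name = field@variable) {
  dlon <- ncdf4::ncdim_def("lon", "degrees_east", field@geometry@lon)
  dlat <- ncdf4::ncdim_def("lat", "degrees_north", field@geometry@lat)
  dtim <- ncdf4::ncdim_def("time", "ka BP", field@epochs,
                           unlim = FALSE)
  var <- ncdf4::ncvar_def(name, field@units, list(dlon, dlat, dtim),
                          missval = 1e30, prec = "double")
  nc <- ncdf4::nc_create(path, var)
  on.exit(ncdf4::nc_close(nc))
  ## substitute the fill value ourselves: ncvar_put would otherwise
  ## replace NAs in place and mutate the caller's (shared) array
  v <- field@values
  v[is.na(v)] <- 1e30
  ncdf4::ncvar_put(nc, var, v)
  ncdf4::ncatt_put(nc, "time", "positive", "past")
  invisible(path)
}

#' Read a climate field from NetCDF
#'
#' Expects lon/lat (and optionally time) coordinate variables and a data
#' variable with a `units` attribute.  Longitudes on a 0-360 convention
#' are remapped to [-180, 180) with the value columns permuted
#' accordingly; fill values become NA.
#'
#' @param path NetCDF file path.
#' @param name data variable to read; default the first non-coordinate
#'   variable.
#' @return a [ClimateField-class].
#' @export
readClimateNetcdf <- function(path, name = NULL) {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  dims <- names(nc$dim)
  lonName <- intersect(c("lon", "longitude"), dims)[1L]
  latName <- intersect(c("lat", "latitude"), dims)[1L]
  if (is.na(lonName) || is.na(latName))
    stop("file lacks lon/lat coordinate variables: ", path)
  if (is.null(name)) name <- names(nc$var)[1L]
  if (is.null(name) || !name %in% names(nc$var))
    stop("no data variable found in ", path)
  units <- ncdf4::ncatt_get(nc, name, "units")
  if (!units$hasatt)
    stop(sprintf("variable '%s' in %s lacks a 'units' attribute",
                 name, path))
  lon <- as.numeric(ncdf4::ncvar_get(nc, lonName))
  lat <- as.numeric(ncdf4::ncvar_get(nc, latName))
  hasTime <- "time" %in% dims && nc$dim$time$len > 0
  tim <- if (hasTime) as.numeric(ncdf4::ncvar_get(nc, "time")) else 0
  vals <- ncdf4::ncvar_get(nc, name, collapse_degen = FALSE)
  if (length(dim(vals)) == 2L) vals <- array(vals, c(dim(vals), 1L))

  ## normalize longitudes to [-180, 180)
  lonW <- ((lon + 180) %% 360) - 180
  ord <- order(lonW)
  lonW <- lonW[ord]
  vals <- vals[ord, , , drop = FALSE]
  if (lat[1L] > lat[length(lat)]) {
    lat <- rev(lat)
    vals <- vals[, rev(seq_along(lat)), , drop = FALSE]
  }
  climateField(name, units$value, gridGeometry(lonW, lat), tim, vals)
}

#' Write a surface-type history to NetCDF
#'
#' Integer codes 0 = ocean, 1 = land, 2 = land_ice with `flag_values` /
#' `flag_meanings` attributes.
#'
#' @param mask a [SurfaceTypeGrid-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeMaskNetcdf <- function(mask, path) {
  dlon <- ncdf4::ncdim_def("lon", "degrees_east", mask@geometry@lon)
  dlat <- ncdf4::ncdim_def("lat", "degrees_north", mask@geometry@lat)
  dtim <- ncdf4::ncdim_def("time", "ka BP", mask@epochs)
  var <- ncdf4::ncvar_def("mask", "1", list(dlon, dlat, dtim),
                          missval = -1, prec = "integer")
  nc <- ncdf4::nc_create(path, var)
  on.exit(ncdf4::nc_close(nc))
  ncdf4::ncvar_put(nc, var, mask@codes)
  ncdf4::ncatt_put(nc, "mask", "flag_values", "0 1 2")
  ncdf4::ncatt_put(nc, "mask", "flag_meanings", "ocean land land_ice")
  invisible(path)
}

#' Read a surface-type history from NetCDF
#'
#' @param path NetCDF path written by [writeMaskNetcdf()] (or compatible:
#'   integer codes 0/1/2 on lon/lat/time).
#' @return a [SurfaceTypeGrid-class].
#' @export
readMaskNetcdf <- function(path) {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  lon <- as.numeric(ncdf4::ncvar_get(nc, "lon"))
  lat <- as.numeric(ncdf4::ncvar_get(nc, "lat"))
  tim <- as.numeric(ncdf4::ncvar_get(nc, "time"))
  codes <- ncdf4::ncvar_get(nc, "mask", collapse_degen = FALSE)
  new("SurfaceTypeGrid", geometry = gridGeometry(lon, lat),
      epochs = tim, codes = array(as.integer(codes), dim(codes)))
}

#' Serialize an emulator's diagnostics to NetCDF
#'
#' One file per variable/month: the coefficient, standard-error and
#' p-value grids for every predictor, plus the mean-term, R-squared and
#' RMSE grids, mirroring the per-month diagnostic products of the
#' reconstruction.
#'
#' @param model an [EmulatorModel-class].
#' @param path output path.
#' @param variable,month which fit to serialize.
#' @return invisibly, `path`.
#' @export
writeEmulatorNetcdf <- function(model, path, variable, month = "ann") {
  f <- model@fits[[variable]]
  if (is.null(f)) stop("variable not in model: ", variable)
  m <- match(month, model@months)
  if (is.na(m)) stop("month not in model: ", month)
  dlon <- ncdf4::ncdim_def("lon", "degrees_east", model@geometry@lon)
  dlat <- ncdf4::ncdim_def("lat", "degrees_north", model@geometry@lat)
  mk <- function(nm) ncdf4::ncvar_def(nm, "1", list(dlon, dlat),
                                      missval = 1e30, prec = "double")
  vars <- c(lapply(paste0("beta_", COEF_NAMES), mk),
            lapply(paste0("se_", COEF_NAMES), mk),
            lapply(paste0("pvalue_", COEF_NAMES), mk),
            lapply(c("mean_term", "r_squared", "rmse"), mk))
  nc <- ncdf4::nc_create(path, vars)
  on.exit(ncdf4::nc_close(nc))
  for (k in seq_along(COEF_NAMES)) {
    ncdf4::ncvar_put(nc, paste0("beta_", COEF_NAMES[k]), f$coef[, , m, k])
    ncdf4::ncvar_put(nc, paste0("se_", COEF_NAMES[k]), f$se[, , m, k])
    ncdf4::ncvar_put(nc, paste0("pvalue_", COEF_NAMES[k]), f$pval[, , m, k])
  }
  ncdf4::ncvar_put(nc, "mean_term", f$meanTerm[, , m])
  ncdf4::ncvar_put(nc, "r_squared", f$r2[, , m])
  ncdf4::ncvar_put(nc, "rmse", f$rmse[, , m])
  invisible(path)
}

#' Read proxy records from delimited text
#'
#' Expects columns `name`, `lon`, `lat`, `age_ka`, `value` and optionally
#' `type`/`unit`, tab- or comma-separated, one row per sample.
#'
#' @param path file path.
#' @return list of [ProxyRecord-class] objects, one per distinct name.
#' @examples
#' path <- system.file("extdata", "synthetic_proxies.tsv",
#'                     package = "paleoemu")
#' proxies <- readProxyTable(path)
#' proxies[[1]]
#' @export
readProxyTable <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else "\t"
  d <- utils::read.delim(path, sep = sep, check.names = FALSE)
  need <- c("name", "lon", "lat", "age_ka", "value")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("proxy file lacks column(s): ", paste(miss, collapse = ", "))
  lapply(split(d, d$name), function(g)
    proxyRecord(as.character(g$name[1L]), g$lon[1L], g$lat[1L],
                g$age_ka, g$value,
                type = if ("type" %in% names(g)) as.character(g$type[1L])
                else "unknown",
                unit = if ("unit" %in% names(g)) as.character(g$unit[1L])
                else ""))
}

#' Write proxy records as delimited text
#'
#' @param proxies list of [ProxyRecord-class] objects.
#' @param path output path (tab-separated).
#' @return invisibly, `path`.
#' @export
writeProxyTable <- function(proxies, path) {
  rows <- lapply(proxies, function(p)
    data.frame(name = p@name, lon = p@lon, lat = p@lat, age_ka = p@age,
               value = p@value, type = p@type, unit = p@unit))
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
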