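#' Pipeline configuration
#'
#' Assembles (and validates) the options steering [runPipeline()]:
#' synthetic-world size and noise, the training-selection settings, the
#' reconstruction epoch axis, the downscaling factor and bias amplitudes,
#' and the output directory.  A configuration can be round-tripped through
#' YAML with [readPipelineConfig()] / [writePipelineConfig()].
#'
#' @param outDir output directory for the NetCDF products and manifest.
#' @param seed integer master seed for all stochastic stages.
#' @param nlon,nlat coarse synthetic grid size.
#' @param months month labels to process.
#' @param variables climate variables to process.
#' @param trainFraction,nIterations training-selection settings.
#' @param epochs reconstruction epoch axis in ka BP (default 800..0,
#'   1 ka steps including the present).
#' @param fineFactor integer downscaling refinement factor.
#' @param noiseSd named per-variable transformed-scale noise sd of the
#'   synthetic snapshots.
#' @param biasAmplitude named natural-scale amplitudes of the synthetic
#'   observation bias.
#' @param proxyCount,proxySnr synthetic proxy records to validate against.
#' @param correlationStage "coarse" correlates proxies against the raw
#'   coarse reconstruction (the marine-proxy convention); "corrected"
#'   against the bias-corrected product.
#' @return a named list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(outDir = tempfile("paleoemu"), seed = 1,
                           nlon = 12L, nlat = 10L,
                           months = MONTH_LABELS,
                           variables = c("temperature", "precipitation",
                                         "cloud"),
                           trainFraction = 0.8, nIterations = 2000L,
                           epochs = seq(800, 0, by = -1),
                           fineFactor = 2L,
                           noiseSd = c(temperature = 0.2,
                                       precipitation = 0.1, cloud = 0.1),
                           biasAmplitude = c(temperature = 2,
                                             precipitation = 100,
                                             cloud = 0.05),
                           proxyCount = 5L, proxySnr = 2,
                           correlationStage = c("coarse", "corrected")) {
  cfg <- list(outDir = outDir, seed = seed, nlon = nlon, nlat = nlat,
              months = months, variables = variables,
              trainFraction = trainFraction, nIterations = nIterations,
              epochs = epochs, fineFactor = fineFactor, noiseSd = noiseSd,
              biasAmplitude = biasAmplitude, proxyCount = proxyCount,
              proxySnr = proxySnr,
              correlationStage = match.arg(correlationStage))
  class(cfg) <- c("pipelineConfig", "list")
  cfg
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with keys matching [pipelineConfig()] arguments.
#' @return a `pipelineConfig` list.
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  for (nm in c("noiseSd", "biasAmplitude"))
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  do.call(pipelineConfig, raw)
}

#' Write a pipeline configuration as YAML
#' @param config a `pipelineConfig` list.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

.filePrefix <- c(temperature = "temp", precipitation = "prec",
                 cloud = "tcc")

.logStage <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf(paste0("[paleoemu] ", fmt), ...))
}

#' Run the full reconstruction pipeline on a synthetic world
#'
#' Executes select - fit - predict - regrid - delta-correct - bioclim -
#' validate and writes the product files (one NetCDF per variable/month
#' plus bioclim layers, the surface mask and a machine-readable run
#' manifest) into the configured output directory.  The validation model
#' is fit on the selected training epochs and scored on the held-out
#' test epochs; the product model is refit on all snapshot epochs to make
#' full use of the data.
#'
#' @param config a [pipelineConfig()] list.
#' @param quiet suppress per-stage progress messages.
#' @return invisibly, a list with the in-memory stage results (`world`,
#'   `selection`, `model`, `goodness`, `covariance`, `proxyTable`,
#'   `manifest`, ...).
#' @export
runPipeline <- function(config = pipelineConfig(), quiet = FALSE) {
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  clampTotal <- 0L

  .logStage(quiet, "synth: %d x %d world, seed %d", config$nlon,
            config$nlat, config$seed)
  world <- syntheticWorld(config$nlon, config$nlat, config$months,
                          config$variables, config$noiseSd, config$seed)
  snapshots <- makeSnapshots(world)

  .logStage(quiet, "select: %d iterations at fraction %.2f",
            config$nIterations, config$trainFraction)
  sel <- selectTraining(world@forcings,
                        selectionConfig(config$trainFraction,
                                        config$nIterations, config$seed))
  trainEpochs <- snapshots@epochs[sel@trainIndices]
  testEpochs <- snapshots@epochs[sel@testIndices]

  .logStage(quiet, "fit: validation model on %d epochs, product model on %d",
            length(trainEpochs), length(snapshots@epochs))
  valModel <- fitGrid(snapshots, trainEpochs, world@forcings)
  model <- fitGrid(snapshots, NULL, world@forcings)

  .logStage(quiet, "predict: %d epochs", length(config$epochs))
  recon <- predict(model, world@forcingsExtended, world@surface,
                   atEpochs = config$epochs)

  .logStage(quiet, "downscale + bias-correct: factor %d", config$fineFactor)
  reference <- makeReference(world, config$fineFactor,
                             config$biasAmplitude)
  op <- makeRegridOperator(world@geometry, reference@geometry)
  refEpochIdx <- match(reference@epoch, config$epochs)
  corrected <- list()
  for (v in config$variables) {
    corrected[[v]] <- vector("list", length(config$months))
    names(corrected[[v]]) <- config$months
    for (mo in config$months) {
      emu <- bilinearRegrid(snapshotField(recon, v, mo),
                            reference@geometry, op = op)
      emuRef <- if (!is.na(refEpochIdx)) {
        climateField(v, emu@units, reference@geometry, reference@epoch,
                     emu@values[, , refEpochIdx])
      } else {
        refRecon <- predict(model, world@forcingsExtended, world@surface,
                            atEpochs = reference@epoch)
        bilinearRegrid(snapshotField(refRecon, v, mo),
                       reference@geometry, op = op)
      }
      cf <- deltaCorrect(emu, emuRef, referenceField(reference, v, mo))
      clampTotal <- clampTotal + attr(cf@values, "clamped")
      corrected[[v]][[mo]] <- cf
      fn <- sprintf("%s_800ka_%s.nc", .filePrefix[[v]], mo)
      writeClimateNetcdf(cf, file.path(config$outDir, fn))
      files <- c(files, fn)
    }
  }

  bioclim <- NULL
  mons <- tolower(month.abb)
  if (all(mons %in% config$months) &&
      all(c("temperature", "precipitation") %in% config$variables)) {
    .logStage(quiet, "bioclim: 17 layers over %d epochs",
              length(config$epochs))
    tArr <- abind4(lapply(mons, function(mo)
      corrected$temperature[[mo]]@values))
    pArr <- abind4(lapply(mons, function(mo)
      corrected$precipitation[[mo]]@values))
    bioclim <- computeBioclim(tArr, pArr, reference@geometry,
                              config$epochs)
    for (ly in names(bioclim@layers)) {
      fn <- sprintf("%s_800ka.nc", ly)
      writeClimateNetcdf(climateField(ly, bioclim@units[[ly]],
                                      reference@geometry, config$epochs,
                                      bioclim@layers[[ly]]),
                         file.path(config$outDir, fn))
      files <- c(files, fn)
    }
    fn <- "temp_800ka_min.nc"
    writeClimateNetcdf(climateField("temperature_min", "K",
                                    reference@geometry, config$epochs,
                                    bioclim@tminAnnual),
                       file.path(config$outDir, fn))
    files <- c(files, fn)
  }

  fn <- "icesheets_000-800.nc"
  writeMaskNetcdf(subsetMask(world@surface, config$epochs),
                  file.path(config$outDir, fn))
  files <- c(files, fn)

  .logStage(quiet, "validate: goodness maps, covariance, %d proxies",
            config$proxyCount)
  testSnaps <- new("SnapshotSet", geometry = world@geometry,
                   epochs = as.numeric(testEpochs),
                   months = config$months,
                   fields = lapply(snapshots@fields, function(a)
                     a[, , , match(testEpochs, snapshots@epochs),
                       drop = FALSE]),
                   mask = subsetMask(snapshots@mask, testEpochs))
  goodness <- goodnessMaps(valModel, testSnaps, world@forcings)
  reconAtSnaps <- predict(model, world@forcings, snapshots@mask)
  covar <- covarianceSummary(snapshotField(snapshots, "temperature"),
                             snapshotField(reconAtSnaps, "temperature"))
  proxies <- makeProxies(world, config$proxyCount, config$proxySnr,
                         config$seed)
  proxyFields <- if (config$correlationStage == "coarse")
    snapshotField(recon, "temperature")
  else corrected$temperature$ann
  ## match proxies within half the product's temporal resolution
  gap <- max(0.5, stats::median(abs(diff(config$epochs))) / 2)
  proxyTab <- proxyCorrelationTable(proxyFields, proxies, maxGap = gap)
  fn <- "proxy_correlations.tsv"
  utils::write.table(proxyTab, file.path(config$outDir, fn), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  files <- c(files, fn)
  writeSelection(sel, snapshots@epochs, file.path(config$outDir,
                                                  "selection"))
  files <- c(files, "selection.json", "selection_counts.tsv")

  manifest <- list(
    seed = config$seed,
    grid = c(nlon = config$nlon, nlat = config$nlat),
    fine_grid = c(nlon = length(reference@geometry@lon),
                  nlat = length(reference@geometry@lat)),
    n_epochs = length(config$epochs),
    months = config$months,
    variables = config$variables,
    train_epochs = trainEpochs,
    test_epochs = testEpochs,
    candidate_count = sel@candidateCount,
    clamped_values = clampTotal,
    files = sort(files))
  jsonlite::write_json(manifest, file.path(config$outDir,
                                           "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .logStage(quiet, "done: %d files in %s", length(files) + 1L,
            config$outDir)
  invisible(list(world = world, snapshots = snapshots, selection = sel,
                 valModel = valModel, model = model, recon = recon,
                 reference = reference, corrected = corrected,
                 bioclim = bioclim, goodness = goodness,
                 covariance = covar, proxyTable = proxyTab,
                 manifest = manifest))
}

## bind a list of (nlon, nlat, ntime) arrays into (nlon, nlat, 12, ntime)
abind4 <- function(lst) {
  d <- dim(lst[[1L]])
  out <- array(NA_real_, c(d[1L], d[2L], length(lst), d[3L]))
  for (m in seq_along(lst)) out[, , m, ] <- lst[[m]]
  out
}
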