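test_that("goodness maps are perfect on a noiseless world and guard inputs", {
  w <- noiselessWorld(seed = 51)
  s <- makeSnapshots(w)
  trainE <- s@epochs[1:58]
  testE <- s@epochs[59:72]
  m <- fitGrid(s, trainE, w@forcings)
  testSnaps <- new("SnapshotSet", geometry = w@geometry,
                   epochs = testE, months = w@months,
                   fields = lapply(s@fields, function(a)
                     a[, , , 59:72, drop = FALSE]),
                   mask = subsetMask(s@mask, testE))
  gm <- goodnessMaps(m, testSnaps, w@forcings)
  poleRows <- which(abs(w@geometry@lat) == 90)
  r2 <- gm@r2$temperature[, -poleRows, ]
  expect_equal(max(abs(r2 - 1)), 0, tolerance = 1e-10)
  expect_lt(max(gm@rmse$temperature[, -poleRows, ]), 1e-6)
  ## pole rows carry no fit
  expect_true(all(is.na(gm@r2$temperature[, poleRows, ])))

  expect_error(goodnessMaps(m, s, w@forcings), "overlap")
  empty <- new("SnapshotSet", geometry = w@geometry, epochs = numeric(0),
               months = w@months,
               fields = lapply(s@fields, function(a)
                 a[, , , 0, drop = FALSE]),
               mask = subsetMask(s@mask, numeric(0)))
  expect_error(goodnessMaps(m, empty, w@forcings), "empty")
})

test_that("held-out RMSE of a pure-noise world centers on the noise sd", {
  ## a flat-truth world: the response is mean + noise, no forcing signal
  set.seed(303)
  g <- gridGeometry(seq(-180, 162, by = 18), seq(-80, 80, by = 16))
  nlon <- 20; nlat <- 11; sigma <- 0.5
  epochsAll <- snapshotEpochs()
  vals <- array(280 + rnorm(nlon * nlat * 72, 0, sigma),
                c(nlon, nlat, 1, 72))
  msk <- new("SurfaceTypeGrid", geometry = g, epochs = epochsAll,
             codes = array(1L, c(nlon, nlat, 72)))
  s <- new("SnapshotSet", geometry = g, epochs = as.numeric(epochsAll),
           months = "ann", fields = list(temperature = vals), mask = msk)
  ft <- makeForcings(seed = 4)
  trainE <- epochsAll[1:58]; testE <- epochsAll[59:72]
  m <- fitGrid(s, trainE, ft)
  testSnaps <- new("SnapshotSet", geometry = g, epochs = as.numeric(testE),
                   months = "ann",
                   fields = list(temperature = vals[, , , 59:72,
                                                    drop = FALSE]),
                   mask = subsetMask(msk, testE))
  gm <- goodnessMaps(m, testSnaps, ft)
  pixRmse <- gm@rmse$temperature[, , 1]   # 220 pixels
  expect_gt(median(pixRmse), 0.8 * sigma)
  expect_lt(median(pixRmse), 1.3 * sigma)
})

test_that("spatial covariance matches a double-loop oracle and its identities", {
  set.seed(307)
  m <- matrix(rnorm(50), 5, 10)
  cv <- spatialCovariance(m)
  expect_equal(unname(cv), oracle_spatial_cov(m), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_lt(max(abs(cv - t(cv))), 1e-10)

  ## perfectly correlated duplicated pixels
  dup <- rbind(m[1, ], m[1, ])
  cvd <- spatialCovariance(dup)
  expect_equal(cvd[1, 2], cvd[1, 1], tolerance = 1e-12)
  expect_equal(cvd[2, 2], cvd[1, 1], tolerance = 1e-12)

  ## constant-in-time fields have zero covariance
  expect_true(all(abs(spatialCovariance(matrix(3, 4, 6))) < 1e-14))
  expect_error(spatialCovariance(matrix(1, 5, 1)), "2 epochs")

  ## PSD up to numerical noise
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8 * sum(diag(cv)))
})

test_that("covariance dimension equals the unmasked pixel count and the emulator preserves structure", {
  w <- noiselessWorld(seed = 53)
  s <- makeSnapshots(w)
  m <- fitGrid(s, NULL, w@forcings)
  p <- predict(m, w@forcings, s@mask)
  truthF <- snapshotField(s, "temperature")
  emuF <- snapshotField(p, "temperature")
  ## mask the truth like the emulation (pole rows are NA in the emulation)
  tv <- truthF@values; tv[is.na(emuF@values)] <- NA
  truthF@values <- tv
  cs <- covarianceSummary(truthF, emuF)
  nUnmasked <- sum(apply(!is.na(emuF@values), c(1, 2), all))
  expect_identical(dim(cs$truth), c(nUnmasked, nUnmasked))
  ## noiseless linear world: difference matrix vanishes
  expect_lt(cs$normDifference, 1e-8 * cs$normTruth)
})

test_that("proxy correlation behaves like a correlation", {
  w <- tinyWorld(seed = 55)
  ext <- w@forcingsExtended@epochs
  truth <- trueFields(w, ext, "temperature")$temperature
  g <- w@geometry
  fld <- climateField("temperature", "K", g, ext, truth[, , 1, ])

  i <- 3; j <- 3
  ages <- seq(0, 800, by = 10)
  series <- truth[i, j, 1, match(ages, ext)]
  p1 <- proxyRecord("exact", g@lon[i], g@lat[j], ages, series)
  expect_equal(as.numeric(proxyCorrelation(fld, p1)), 1, tolerance = 1e-12)
  p2 <- proxyRecord("neg", g@lon[i], g@lat[j], ages, -series)
  expect_equal(as.numeric(proxyCorrelation(fld, p2)), -1,
               tolerance = 1e-12)
  ## affine rescaling leaves r unchanged (d18O-style units)
  p3 <- proxyRecord("scaled", g@lon[i], g@lat[j], ages,
                    -0.25 * series + 4)
  expect_equal(as.numeric(proxyCorrelation(fld, p3)), -1,
               tolerance = 1e-12)

  ## a masked cell fails with a pointer to the nearest valid cell
  fldNA <- fld
  v <- fldNA@values; v[i, j, ] <- NA; fldNA@values <- v
  expect_error(proxyCorrelation(fldNA, p1), "nearest valid")

  ## unmatched samples are dropped and counted
  sparse <- climateField("temperature", "K", g, seq(800, 0, by = -100),
                         truth[, , 1, match(seq(800, 0, by = -100), ext)])
  r <- proxyCorrelation(sparse, p1)
  expect_identical(attr(r, "dropped"), sum(ages %% 100 != 0))
})

test_that("noisy synthetic proxies land in the expected correlation envelope", {
  w <- tinyWorld(seed = 57)
  ext <- w@forcingsExtended@epochs
  truth <- trueFields(w, ext, "temperature")$temperature
  fld <- climateField("temperature", "K", w@geometry, ext, truth[, , 1, ])
  rs <- unlist(lapply(1:40, function(k) {
    pr <- makeProxies(w, n = 1, snr = 2, seed = 1000 + k)[[1]]
    as.numeric(proxyCorrelation(fld, pr))
  }))
  ## SNR 2: r should concentrate near 2/sqrt(5) ~ 0.89
  expect_gt(mean(rs > 0.6 & rs < 0.98), 0.9)
  ## infinite SNR drives r to 1 (up to sub-ka age-matching error)
  pr <- makeProxies(w, n = 1, snr = Inf, seed = 9)[[1]]
  expect_gt(as.numeric(proxyCorrelation(fld, pr)), 0.99)
})
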