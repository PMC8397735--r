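## shared fixture: a design with all three surface levels over 72 epochs
makeDesign <- function(seed = 1) {
  set.seed(seed)
  z <- scale(matrix(rnorm(72 * 4), 72, 4))[, ]
  colnames(z) <- c("obliquity", "precession_i", "precession_ii", "co2")
  surface <- sample(c("ocean", "land", "land_ice"), 72, replace = TRUE)
  list(z = z, surface = surface)
}

test_that("fitPixel recovers known coefficients exactly on noiseless data", {
  d <- makeDesign(2)
  beta <- c(1.2, -0.7, 0.3, 2.0)
  delta <- c(land = 1.5, land_ice = -6)
  y <- 280 + d$z %*% beta +
    delta["land"] * (d$surface == "land") +
    delta["land_ice"] * (d$surface == "land_ice")
  pm <- fitPixel(as.numeric(y), d$z, d$surface)
  expect_true(pm@ok)
  expect_equal(unname(pm@beta), beta, tolerance = 1e-8)
  expect_equal(pm@betaSurface, delta, tolerance = 1e-8)
  expect_equal(pm@meanTerm, 280, tolerance = 1e-8)
  expect_equal(pm@r2, 1, tolerance = 1e-10)
  expect_lt(pm@rmse, 1e-8)
})

test_that("fitted coefficients match a normal-equations solve on random designs", {
  for (k in 1:20) {
    d <- makeDesign(100 + k)
    set.seed(200 + k)
    y <- rnorm(72, 10, 2)
    pm <- fitPixel(y, d$z, d$surface)
    ## oracle: intercept + forcings + dummies against the reference level
    ref <- intersect(c("ocean", "land", "land_ice"), unique(d$surface))[1]
    others <- setdiff(intersect(c("ocean", "land", "land_ice"),
                                unique(d$surface)), ref)
    X <- cbind(1, d$z)
    for (lev in others) X <- cbind(X, as.numeric(d$surface == lev))
    th <- oracle_ols(X, y - mean(y))
    expect_equal(unname(pm@beta), unname(th[2:5]), tolerance = 1e-8)
    expect_equal(unname(pm@betaSurface[others]),
                 unname(th[-(1:5)]), tolerance = 1e-8)
  }
})

test_that("degenerate pixels follow the stated conventions", {
  d <- makeDesign(3)
  ## constant response: zero coefficients, R2 = 0, RMSE = 0
  pm <- fitPixel(rep(5, 72), d$z, d$surface)
  expect_true(pm@ok)
  expect_equal(unname(pm@beta), rep(0, 4), tolerance = 1e-12)
  expect_identical(pm@r2, 0)
  expect_equal(pm@rmse, 0, tolerance = 1e-12)

  ## single surface level: no dummy columns, 4-predictor fit proceeds
  pm2 <- fitPixel(rnorm(72), d$z, rep("ocean", 72))
  expect_true(pm2@ok)
  expect_identical(pm2@fittedLevels, "ocean")
  expect_true(all(is.na(pm2@betaSurface)))

  ## rank-deficient design flags the pixel, no exception
  zz <- d$z
  zz[, "co2"] <- as.numeric(d$surface == "land")
  pm3 <- fitPixel(rnorm(72), zz, d$surface)
  expect_false(pm3@ok)
  expect_identical(pm3@reason, "rank_deficient")

  expect_error(fitPixel(rnorm(5), d$z[1:5, ], d$surface[1:5]), "7")
})

test_that("fitGrid fits every non-pole pixel and is exact on a noiseless world", {
  w <- noiselessWorld(seed = 21)
  s <- makeSnapshots(w)
  m <- fitGrid(s, NULL, w@forcings)
  lat <- m@geometry@lat
  poleRows <- which(abs(lat) == 90)
  f <- m@fits$temperature
  expect_true(all(!f$ok[, poleRows, ]))
  expect_true(all(f$reason[, poleRows, ] == "pole"))
  inner <- f$ok[, -poleRows, , drop = FALSE]
  expect_true(all(inner))
  expect_equal(max(abs(f$r2[, -poleRows, ] - 1)), 0, tolerance = 1e-10)
  ## coefficient recovery against stored truth, all variables
  for (v in w@variables) {
    err <- abs(m@fits[[v]]$coef[, -poleRows, 1, 1:4] -
                 w@betaTrue[[v]][, -poleRows, 1, 1:4])
    expect_lt(max(err), 1e-7)
  }
})

test_that("predictions reproduce training snapshots and respect structure", {
  w <- noiselessWorld(seed = 22)
  s <- makeSnapshots(w)
  m <- fitGrid(s, NULL, w@forcings)
  p <- predict(m, w@forcings, s@mask)
  for (v in w@variables) {
    d <- abs(p@fields[[v]] - s@fields[[v]])
    expect_lt(max(d, na.rm = TRUE), 1e-6)
  }

  ## at the forcing origin over ocean, prediction equals the mean term
  st <- m@stats
  origin <- forcingTable(0, st@mean[["co2"]], st@mean[["obliquity"]],
                         st@mean[["precession_i"]],
                         st@mean[["precession_ii"]])
  oceanMask <- new("SurfaceTypeGrid", geometry = w@geometry, epochs = 0,
                   codes = array(0L, c(length(w@geometry@lon),
                                       length(w@geometry@lat), 1)))
  p0 <- suppressWarnings(predict(m, origin, oceanMask))
  f <- m@fits$temperature
  ij <- which(f$ok[, , 1] &
                m@levelsObserved[, , "ocean"], arr.ind = TRUE)[1, ]
  expect_identical(p0@fields$temperature[ij[1], ij[2], 1, 1],
                   f$meanTerm[ij[1], ij[2], 1])

  ## a positive-CO2-coefficient pixel responds monotonically to CO2
  ij <- which(f$ok[, , 1] & f$coef[, , 1, 4] > 0.1, arr.ind = TRUE)[1, ]
  ramp <- forcingTable(5:1, seq(180, 300, length.out = 5),
                       rep(st@mean[["obliquity"]], 5),
                       rep(st@mean[["precession_i"]], 5),
                       rep(st@mean[["precession_ii"]], 5))
  rampMask <- new("SurfaceTypeGrid", geometry = w@geometry, epochs = 5:1,
                  codes = array(s@mask@codes[, , 1],
                                c(dim(s@mask@codes)[1:2], 5)))
  pr <- suppressWarnings(predict(m, ramp, rampMask))
  series <- pr@fields$temperature[ij[1], ij[2], 1, ]
  expect_true(all(diff(series) > 0))

  expect_error(predict(m, w@forcings, s@mask, atEpochs = c(0, 9999)),
               "9999")
})

test_that("parameter recovery under noise stays within standard errors", {
  w <- tinyWorld(nlon = 10L, nlat = 8L, seed = 25)   # noise sd 0.2
  s <- makeSnapshots(w)
  m <- fitGrid(s, NULL, w@forcings)
  f <- m@fits$temperature
  ok <- f$ok[, , 1]
  err <- abs(f$coef[, , 1, 1:4] - w@betaTrue$temperature[, , 1, 1:4])
  ratio <- err / f$se[, , 1, 1:4]
  expect_lt(median(ratio[is.finite(ratio)]), 3)
})

test_that("bounded variables stay within bounds for extreme forcings", {
  w <- tinyWorld(seed = 26)
  s <- makeSnapshots(w)
  m <- fitGrid(s, NULL, w@forcings)
  set.seed(77)
  n <- 300
  wild <- forcingTable(seq(n, 1), runif(n, 120, 500), runif(n, 20, 27),
                       runif(n, -0.1, 0.1), runif(n, -0.1, 0.1))
  wildMask <- new("SurfaceTypeGrid", geometry = w@geometry,
                  epochs = seq(n, 1),
                  codes = array(sample(0:2, 48 * n, replace = TRUE),
                                c(8, 6, n)))
  p <- suppressWarnings(predict(m, wild, wildMask))
  pr <- p@fields$precipitation
  cl <- p@fields$cloud
  expect_true(all(pr[!is.na(pr)] > 0))
  expect_true(all(cl[!is.na(cl)] > 0 & cl[!is.na(cl)] < 1))
})

test_that("held-out RMSE matches the generating noise level", {
  w <- tinyWorld(nlon = 10L, nlat = 8L, months = "ann", seed = 27)
  s <- makeSnapshots(w)
  sel <- selectTraining(w@forcings, selectionConfig(0.8, 800, seed = 3))
  trainE <- s@epochs[trainIndices(sel)]
  testE <- s@epochs[testIndices(sel)]
  m <- fitGrid(s, trainE, w@forcings)
  p <- suppressWarnings(
    predict(m, w@forcings, s@mask, atEpochs = testE))
  tIdx <- match(testE, s@epochs)
  err <- p@fields$temperature[, , 1, ] - s@fields$temperature[, , 1, tIdx]
  rmse <- sqrt(mean(err^2, na.rm = TRUE))
  expect_gt(rmse, 0.8 * 0.2)
  expect_lt(rmse, 1.2 * 0.2)
})
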