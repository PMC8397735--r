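test_that("quarter selection handles ties, wrap-around and ramps", {
  ## constant selector: first window wins the tie
  expect_identical(quarterStat(rep(1, 12), "wettest")$quarter, 1L)
  ## peak across the year boundary selects the wrap-around window
  sel <- c(9, 8, 1, 1, 1, 1, 1, 1, 1, 1, 1, 10)
  expect_identical(quarterStat(sel, "wettest")$quarter, 12L)
  ## warmest quarter of a monotone ramp is the last three months
  qs <- quarterStat(1:12, "warmest")
  expect_identical(qs$quarter, 10L)
  expect_equal(qs$value, mean(10:12))
  ## exhaustive check against all 12 windows on random series
  set.seed(83)
  for (k in 1:25) {
    s <- runif(12); comp <- rnorm(12)
    got <- quarterStat(s, "driest", comp, stat = "sum")
    wrap <- function(w) ((w:(w + 2) - 1) %% 12) + 1
    sums <- sapply(1:12, function(w) sum(s[wrap(w)]))
    w0 <- which.min(sums)
    expect_identical(got$quarter, as.integer(w0))
    expect_equal(got$value, sum(comp[wrap(w0)]))
  }
})

test_that("a constant climate zeroes all variability measures", {
  g <- gridGeometry(c(-90, 0, 90), c(-30, 0, 30))
  tK <- array(283.15, c(3, 3, 12))
  p <- array(600, c(3, 3, 12))
  b <- computeBioclim(tK, p, g)
  expect_equal(unname(bioclimLayer(b, "bio01")[, , 1]),
               matrix(10, 3, 3), tolerance = 1e-10)
  expect_true(all(bioclimLayer(b, "bio04") == 0))
  expect_true(all(bioclimLayer(b, "bio07") == 0))
  expect_true(all(bioclimLayer(b, "bio15") == 0))
  expect_equal(unname(bioclimLayer(b, "bio12")[, , 1]),
               matrix(600, 3, 3))
  ## exactly 17 layers, never bio02/bio03
  expect_length(b@layers, 17)
  expect_false(any(c("bio02", "bio03") %in% names(b@layers)))
})

test_that("bioclim layers agree with the definition-literal oracle", {
  set.seed(89)
  g <- gridGeometry(c(-90, 90), c(-30, 30))
  for (k in 1:50) {
    tK <- 273.15 + rnorm(12, 10, 12)
    p <- exp(rnorm(12, 6, 1))
    b <- computeBioclim(array(rep(tK, each = 4), c(2, 2, 12)),
                        array(rep(p, each = 4), c(2, 2, 12)), g)
    want <- oracle_bioclim(tK, p)
    got <- vapply(names(want), function(nm)
      bioclimLayer(b, nm)[1, 1, 1], numeric(1))
    expect_equal(got, want, tolerance = 1e-10)
    expect_equal(b@tminAnnual[1, 1, 1], min(tK), tolerance = 1e-12)
  }
})

test_that("ordering and symmetry invariants hold on random climates", {
  set.seed(97)
  g <- gridGeometry(seq(-150, 150, by = 60), seq(-60, 60, by = 30))
  nlon <- 6; nlat <- 5
  tK <- array(273.15 + rnorm(nlon * nlat * 12, 8, 15), c(nlon, nlat, 12))
  p <- array(exp(rnorm(nlon * nlat * 12, 6, 0.8)), c(nlon, nlat, 12))
  b <- computeBioclim(tK, p, g)
  expect_true(all(bioclimLayer(b, "bio07") >= 0))
  expect_true(all(bioclimLayer(b, "bio13") >= bioclimLayer(b, "bio14")))
  expect_true(all(bioclimLayer(b, "bio16") >= bioclimLayer(b, "bio17")))
  expect_true(all(bioclimLayer(b, "bio05") >= bioclimLayer(b, "bio06")))
  ## BIO12 consistent with the monthly aggregate
  expect_equal(bioclimLayer(b, "bio12"),
               array(apply(p, c(1, 2), mean), c(nlon, nlat, 1)),
               tolerance = 1e-12, ignore_attr = TRUE)

  ## permuting months preserves aggregation-symmetric layers
  perm <- sample(12)
  b2 <- computeBioclim(tK[, , perm], p[, , perm], g)
  for (ly in c("bio01", "bio04", "bio12", "bio13", "bio14"))
    expect_equal(bioclimLayer(b2, ly), bioclimLayer(b, ly),
                 tolerance = 1e-12)
})

test_that("missing months are reported by name", {
  w <- tinyWorld(months = c("jan", "feb", "ann"), seed = 41)
  s <- makeSnapshots(w)
  expect_error(bioclimFromSnapshots(s), "mar")
})
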