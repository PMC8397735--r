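coarse4 <- function(vals, epochs = 0) {
  g <- gridGeometry(c(-135, -45, 45, 135), c(-60, -20, 20, 60))
  climateField("temperature", "K", g, epochs,
               array(vals, c(4, 4, length(epochs))))
}

test_that("bilinear regrid reproduces constants and planes", {
  f <- coarse4(5)
  tg <- gridGeometry(seq(-170, 170, by = 20), seq(-55, 55, by = 10))
  out <- bilinearRegrid(f, tg)
  expect_equal(unname(out@values[, , 1]),
               matrix(5, 18, 12), tolerance = 1e-12)

  ## linear in longitude within a non-wrapping span
  g <- gridGeometry(c(-135, -45, 45, 135), c(-60, -20, 20, 60))
  vals <- outer(g@lon, rep(1, 4))
  f2 <- climateField("temperature", "K", g, 0, vals)
  tg2 <- gridGeometry(seq(-130, 130, by = 10), c(-30, -10, 10))
  out2 <- bilinearRegrid(f2, tg2)
  expect_equal(unname(out2@values[, 1, 1]), tg2@lon, tolerance = 1e-12)
})

test_that("regrid weights match a direct per-point oracle", {
  set.seed(61)
  g <- gridGeometry(c(-135, -45, 45, 135), c(-60, -20, 20, 60))
  vals <- matrix(rnorm(16), 4, 4)
  f <- climateField("temperature", "K", g, 0, vals)
  qlon <- runif(16, -180, 168)
  qlat <- runif(16, -60, 58)
  for (k in seq_along(qlon)) {
    tg <- gridGeometry(c(qlon[k], qlon[k] + 10), c(qlat[k], qlat[k] + 1))
    out <- bilinearRegrid(f, tg)
    want <- oracle_bilinear_point(g@lon, g@lat, vals, qlon[k], qlat[k])
    expect_equal(out@values[1, 1, 1], want, tolerance = 1e-12)
  }
  expect_error(bilinearRegrid(f, gridGeometry(c(0, 10), c(-89, -80))),
               "latitude")
})

test_that("missing coarse neighbors fall back to the nearest valid one", {
  g <- gridGeometry(c(-135, -45, 45, 135), c(-60, -20, 20, 60))
  vals <- matrix(1:16, 4, 4) * 1.0
  vals[2, 2] <- NA
  f <- climateField("temperature", "K", g, 0, vals)
  ## a point close to the NA cell but closest to its valid neighbor (3,2)
  tg <- gridGeometry(c(20, 30), c(-22, -21))
  out <- bilinearRegrid(f, tg)
  expect_identical(out@values[1, 1, 1], vals[3, 2])
  ## a point in an all-NA neighborhood stays missing
  vals2 <- vals; vals2[] <- NA
  f2 <- climateField("temperature", "K", g, 0, vals2)
  out2 <- bilinearRegrid(f2, tg)
  expect_true(is.na(out2@values[1, 1, 1]))
})

test_that("delta correction implements the additive rule and its identities", {
  g <- gridGeometry(c(0, 90), c(-10, 10))
  mk <- function(v, e = 0, var = "temperature", un = "K")
    climateField(var, un, g, e, array(v, c(2, 2, length(e))))
  ## Y_LM(t)=10, Y_LM(0)=11, Y_CRU(0)=12 -> 11
  out <- deltaCorrect(mk(10), mk(11), mk(12))
  expect_equal(unname(out@values[, , 1]), matrix(11, 2, 2))

  ## reference-epoch identity is exact (bit for bit on valid cells)
  set.seed(71)
  emu <- mk(rnorm(8, 280, 5), e = c(5, 0))
  emu0 <- mk(emu@values[, , 2])
  ref <- mk(rnorm(4, 281, 5))
  cor1 <- deltaCorrect(emu, emu0, ref)
  expect_identical(cor1@values[, , 2], ref@values[, , 1])

  ## zero-bias reference: corrected equals emulated everywhere
  cor2 <- deltaCorrect(emu, emu0, mk(emu0@values[, , 1]))
  expect_equal(cor2@values, emu@values, ignore_attr = TRUE)

  ## anomaly preservation pre-clamp
  emuS <- mk(rnorm(12, 500, 80), e = c(9, 4, 0), var = "precipitation",
             un = "mm year-1")
  emuS0 <- mk(emuS@values[, , 3], var = "precipitation", un = "mm year-1")
  refS <- mk(rnorm(4, 450, 60), var = "precipitation", un = "mm year-1")
  corS <- deltaCorrect(emuS, emuS0, refS, clamp = FALSE)
  dHat <- corS@values[, , 1] - corS@values[, , 2]
  dRaw <- emuS@values[, , 1] - emuS@values[, , 2]
  expect_equal(dHat, dRaw, tolerance = 1e-12)

  ## invalid reference cells: raw passthrough or missing, flagged
  refNA <- ref; refNA@values[1, 1, 1] <- NA
  corRaw <- deltaCorrect(emu, emu0, refNA)
  expect_identical(corRaw@values[1, 1, 1], emu@values[1, 1, 1])
  expect_identical(attr(corRaw@values, "provenance")[1, 1], "raw")
  corMiss <- deltaCorrect(emu, emu0, refNA, fillInvalid = "missing")
  expect_true(is.na(corMiss@values[1, 1, 1]))

  expect_error(deltaCorrect(emu, emu0, mk(12, un = "degC")), "unit")
})

test_that("bias maps are elementwise differences on valid cells", {
  g <- gridGeometry(c(-90, 0, 90), c(-10, 0, 10))
  set.seed(72)
  a <- matrix(rnorm(9), 3, 3)
  b <- matrix(rnorm(9), 3, 3)
  b[2, 2] <- NA
  fa <- climateField("temperature", "K", g, 0, a)
  fb <- climateField("temperature", "K", g, 0, b)
  expect_true(all(biasMap(fa, fa)@values == 0))
  shifted <- climateField("temperature", "K", g, 0, a + 2)
  expect_equal(unname(biasMap(shifted, fa)@values[, , 1]),
               matrix(2, 3, 3))
  bm <- biasMap(fa, fb)@values[, , 1]
  for (i in 1:3) for (j in 1:3) {
    if (is.na(b[i, j])) expect_true(is.na(bm[i, j]))
    else expect_identical(bm[i, j], a[i, j] - b[i, j])
  }
})

test_that("a known injected observation bias is recovered by biasMap", {
  w <- noiselessWorld(seed = 31)
  ref0 <- makeReference(w, fineFactor = 2L,
                        biasAmplitude = c(temperature = 0,
                                          precipitation = 0, cloud = 0))
  set.seed(5)
  inj <- matrix(rnorm(prod(dim(ref0@valid)), 0, 3), nrow(ref0@valid))
  refB <- ref0
  refB@fields$temperature[, , 1] <- refB@fields$temperature[, , 1] + inj
  ## emulated-at-reference = regridded truth = unbiased reference field
  emu0 <- climateField("temperature", "K", ref0@geometry, 0,
                       ref0@fields$temperature[, , 1])
  bm <- biasMap(emu0, referenceField(refB, "temperature", "ann"))
  v <- bm@values[, , 1]
  expect_equal(v[ref0@valid], -inj[ref0@valid], tolerance = 1e-10)
})
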