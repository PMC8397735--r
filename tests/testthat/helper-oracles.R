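## Independent reference implementations used as test oracles.  These
## deliberately take the dumbest correct route (explicit loops, exhaustive
## enumeration, normal equations) so they share no code with the package
## internals they check.

## piecewise-linear interpolation by explicit segment search
oracle_interp <- function(x, y, xq) {
  ord <- order(x)
  x <- x[ord]; y <- y[ord]
  vapply(xq, function(q) {
    for (k in seq_len(length(x) - 1L)) {
      if (q >= x[k] && q <= x[k + 1L]) {
        w <- (q - x[k]) / (x[k + 1L] - x[k])
        return((1 - w) * y[k] + w * y[k + 1L])
      }
    }
    NA_real_
  }, numeric(1))
}

## eigenvalue dominance via singular values (valid for PSD matrices)
oracle_dominates <- function(S, F) {
  es <- sort(svd(S)$d, decreasing = TRUE)
  ef <- sort(svd(F)$d, decreasing = TRUE)
  all(es >= ef)
}

## OLS through the normal equations
oracle_ols <- function(X, y) {
  solve(t(X) %*% X, t(X) %*% y)[, 1L]
}

## per-cell surface classification loop
oracle_mask <- function(topo, sl, ice, lakes) {
  out <- matrix(NA_integer_, nrow(topo), ncol(topo))
  for (i in seq_len(nrow(topo))) for (j in seq_len(ncol(topo))) {
    if (lakes[i, j]) {
      out[i, j] <- if (topo[i, j] <= 0) 0L else 1L
    } else if (topo[i, j] <= sl) {
      out[i, j] <- 0L
    } else if (ice[i, j]) {
      out[i, j] <- 2L
    } else out[i, j] <- 1L
  }
  out
}

## bilinear weight computation for a single target point on a periodic-in-
## longitude regular source grid
oracle_bilinear_point <- function(srcLon, srcLat, vals, qlon, qlat) {
  nlo <- length(srcLon)
  dx <- srcLon[2L] - srcLon[1L]
  p <- ((qlon - srcLon[1L]) / dx) %% nlo
  i0 <- floor(p); fx <- p - i0
  i0 <- (i0 %% nlo) + 1L; i1 <- (i0 %% nlo) + 1L
  dyl <- srcLat[2L] - srcLat[1L]
  q <- (qlat - srcLat[1L]) / dyl
  j0 <- min(max(floor(q), 0), length(srcLat) - 2L)
  fy <- q - j0
  j0 <- j0 + 1L; j1 <- j0 + 1L
  (1 - fx) * (1 - fy) * vals[i0, j0] + fx * (1 - fy) * vals[i1, j0] +
    (1 - fx) * fy * vals[i0, j1] + fx * fy * vals[i1, j1]
}

## definition-literal bioclim from 12-month vectors (T in K, P in mm/yr)
oracle_bioclim <- function(tK, p) {
  tc <- tK - 273.15
  win <- function(w) ((w:(w + 2L) - 1L) %% 12L) + 1L
  qT <- vapply(1:12, function(w) sum(tc[win(w)]), numeric(1))
  qP <- vapply(1:12, function(w) sum(p[win(w)]), numeric(1))
  wet <- which.max(qP); dry <- which.min(qP)
  warm <- which.max(qT); cold <- which.min(qT)
  popsd <- function(x) sqrt(sum((x - mean(x))^2) / length(x))
  c(bio01 = mean(tc),
    bio04 = popsd(tc),
    bio05 = max(tc), bio06 = min(tc), bio07 = max(tc) - min(tc),
    bio08 = mean(tc[win(wet)]), bio09 = mean(tc[win(dry)]),
    bio10 = mean(tc[win(warm)]), bio11 = mean(tc[win(cold)]),
    bio12 = mean(p),
    bio13 = max(p) / 12, bio14 = min(p) / 12,
    bio15 = if (mean(p) > 0) 100 * popsd(p) / mean(p) else 0,
    bio16 = qP[wet] / 12, bio17 = qP[dry] / 12,
    bio18 = qP[warm] / 12, bio19 = qP[cold] / 12)
}

## covariance of pixel time series by explicit double loop
oracle_spatial_cov <- function(m) {
  n <- nrow(m)
  out <- matrix(NA_real_, n, n)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    xa <- m[a, ]; xb <- m[b, ]
    out[a, b] <- sum((xa - mean(xa)) * (xb - mean(xb))) /
      (length(xa) - 1L)
  }
  out
}

## small worlds shared across tests
tinyWorld <- function(..., months = "ann", nlon = 8L, nlat = 6L, seed = 11) {
  syntheticWorld(nlon = nlon, nlat = nlat, months = months, seed = seed,
                 ...)
}

noiselessWorld <- function(..., seed = 12) {
  tinyWorld(noiseSd = c(temperature = 0, precipitation = 0, cloud = 0),
            seed = seed, ...)
}

## a random symmetric positive definite matrix
randomSPD <- function(p) {
  A <- matrix(rnorm(p * p), p)
  crossprod(A) + diag(p) * 0.1
}
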