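test_that("eigenvalue dominance check matches an SVD oracle and handles equality", {
  set.seed(17)
  F <- randomSPD(4)
  expect_true(candidateCheck(2 * F, F))   # eigenvalues scale by 2
  expect_true(candidateCheck(F, F))       # >= holds with equality
  for (k in 1:100) {
    S <- randomSPD(3); G <- randomSPD(3)
    expect_identical(candidateCheck(S, G), oracle_dominates(S, G))
  }
  A <- F; A[1, 2] <- A[1, 2] + 1e-6
  expect_error(candidateCheck(A, F), "symmetric")
})

test_that("the 80/20 split of 72 epochs yields 58 training and 14 test epochs", {
  ft <- makeForcings(seed = 3)
  sel <- selectTraining(ft, selectionConfig(0.8, 1500, seed = 5))
  expect_length(trainIndices(sel), 58)
  expect_length(testIndices(sel), 14)
  expect_setequal(c(trainIndices(sel), testIndices(sel)), 1:72)

  ## same seed reproduces; different seed keeps |train|
  sel2 <- selectTraining(ft, selectionConfig(0.8, 1500, seed = 5))
  expect_identical(trainIndices(sel2), trainIndices(sel))
  sel3 <- selectTraining(ft, selectionConfig(0.8, 1500, seed = 6))
  expect_length(trainIndices(sel3), 58)

  ## fraction 1: everything is training, no resampling
  selAll <- selectTraining(ft, selectionConfig(1, 10, seed = 1))
  expect_identical(trainIndices(selAll), 1:72)
  expect_length(testIndices(selAll), 0)
})

test_that("exhaustive enumeration reproduces brute-force appearance counts", {
  set.seed(23)
  block <- matrix(rnorm(6 * 2), 6, 2)
  subsets <- combn(6, 4, simplify = FALSE)   # all 15 subsets
  sel <- selectTraining(block, selectionConfig(4 / 6, 1, seed = 1),
                        subsets = subsets)
  ## brute force: count each epoch's appearances in dominating subsets
  full <- cov(block)
  counts <- integer(6)
  for (s in subsets) {
    es <- sort(eigen(cov(block[s, ]), symmetric = TRUE)$values,
               decreasing = TRUE)
    ef <- sort(eigen(full, symmetric = TRUE)$values, decreasing = TRUE)
    if (all(es >= ef)) counts[s] <- counts[s] + 1L
  }
  expect_identical(sel@counts, counts)
  expect_identical(sel@candidateCount,
                   sum(vapply(subsets, function(s)
                     candidateCheck(cov(block[s, ]), full), logical(1))))
  ord <- order(-counts, seq_len(6))  # rows oldest first
  expect_setequal(trainIndices(sel), ord[1:4])
})

test_that("every drawn candidate passes the dominance check post hoc", {
  ft <- makeForcings(seed = 9)
  cfg <- selectionConfig(0.8, 400, seed = 21)
  sel <- selectTraining(ft, cfg)
  ## regenerate the identical subset stream and re-assert each candidate
  block <- forcingMatrix(ft)
  full <- cov(block)
  nCand <- 0L
  counts <- integer(72)
  set.seed(cfg@seed)
  for (i in seq_len(cfg@nIterations)) {
    idx <- sample.int(72, 58)
    if (candidateCheck(cov(block[idx, ]), full)) {
      nCand <- nCand + 1L
      counts[idx] <- counts[idx] + 1L
    }
  }
  expect_identical(sel@candidateCount, nCand)
  expect_identical(sel@counts, counts)
})

test_that("selection concentrates training epochs on forcing extremes", {
  ## 1-D toy: i.i.d. standard normal forcing
  set.seed(31)
  x <- matrix(rnorm(60), 60, 1)
  sel <- selectTraining(x, selectionConfig(0.5, 3000, seed = 2))
  z <- abs((x - mean(x)) / sd(x))
  expect_gt(mean(z[trainIndices(sel)]), mean(z[testIndices(sel)]))
})

test_that("an all-failing candidate stream raises a helpful error", {
  set.seed(53)
  block <- matrix(rnorm(20 * 3), 20, 3)
  ## a subset deliberately chosen near the centroid fails dominance
  z <- rowSums(scale(block)^2)
  weak <- list(order(z)[1:10])
  expect_error(selectTraining(block, selectionConfig(0.5, 1, seed = 1),
                              subsets = weak), "iteration")
})
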