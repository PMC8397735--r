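#' Eigenvalue dominance check for a candidate training subset
#'
#' A subsample of epochs is a candidate training set when it contains at
#' least as much forcing variance as the full set: after sorting both
#' eigenvalue spectra in descending order, every eigenvalue of the
#' subsample covariance must be at least the corresponding eigenvalue of
#' the full-set covariance.
#'
#' @param sampleCov p x p covariance matrix of the subsample's forcings.
#' @param fullCov p x p covariance matrix of all forcings.
#' @return logical: does the subsample dominate?
#' @export
candidateCheck <- function(sampleCov, fullCov) {
  stopifnot(is.matrix(sampleCov), is.matrix(fullCov),
            all(dim(sampleCov) == dim(fullCov)))
  for (m in list(sampleCov, fullCov))
    if (max(abs(m - t(m))) > 1e-10)
      stop("covariance input is not symmetric (beyond 1e-10)")
  es <- eigen(sampleCov, symmetric = TRUE, only.values = TRUE)$values
  ef <- eigen(fullCov, symmetric = TRUE, only.values = TRUE)$values
  all(sort(es, decreasing = TRUE) >= sort(ef, decreasing = TRUE))
}

## run expr under a temporary seed, restoring the caller's RNG state
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Variance-maximizing training/test split of the snapshot epochs
#'
#' Draws `nIterations` uniformly random subsets of size k (k =
#' round(trainFraction * n), ties rounded up) from the n epochs.  Every
#' subset whose forcing covariance spectrum dominates the full-set spectrum
#' (see [candidateCheck()]) is a candidate; each epoch's appearances in
#' candidates are counted, epochs are ranked by count (ties broken toward
#' the older epoch), and the top k form the training set.  This
#' concentrates training epochs on the edges of the forcing phase space, so
#' the fitted model interpolates rather than extrapolates for the test
#' epochs.
#'
#' @param forcings a [ForcingTable-class] (the four continuous forcings
#'   enter the covariance) or an n x p numeric matrix of predictor values,
#'   rows ordered oldest epoch first.
#' @param config a [SelectionConfig-class].
#' @param subsets optional list of integer index vectors to examine instead
#'   of random draws (e.g. an exhaustive enumeration); overrides
#'   `nIterations`.
#' @return a [SelectionResult-class].
#' @examples
#' ft <- makeForcings(seed = 1)
#' sel <- selectTraining(ft, selectionConfig(0.8, 2000, seed = 7))
#' length(trainIndices(sel))  # 58 of the 72 snapshot epochs
#' @export
selectTraining <- function(forcings, config = selectionConfig(),
                           subsets = NULL) {
  if (is(forcings, "ForcingTable")) {
    block <- forcingMatrix(forcings)
    age <- forcings@epochs
  } else {
    block <- as.matrix(forcings)
    age <- rev(seq_len(nrow(block)))   # rows assumed oldest first
  }
  n <- nrow(block)
  p <- ncol(block)
  if (n < p + 2L)
    stop("need at least p + 2 epochs to compare covariances")
  k <- floor(config@trainFraction * n + 0.5)
  if (k == n) {
    return(new("SelectionResult", trainIndices = seq_len(n),
               testIndices = integer(0), counts = rep(0L, n),
               candidateCount = 0L, nIterations = 0L))
  }
  fullCov <- stats::cov(block)
  counts <- integer(n)
  nCand <- 0L
  runOne <- function(idx) {
    if (candidateCheck(stats::cov(block[idx, , drop = FALSE]), fullCov)) {
      counts[idx] <<- counts[idx] + 1L
      nCand <<- nCand + 1L
    }
  }
  if (is.null(subsets)) {
    nIter <- as.integer(config@nIterations)
    withSeed(config@seed, {
      for (i in seq_len(nIter)) runOne(sample.int(n, k))
    })
  } else {
    nIter <- length(subsets)
    for (idx in subsets) runOne(as.integer(idx))
  }
  if (nCand == 0L)
    stop("no candidate training subsets found; increase the iteration ",
         "count or reduce the training fraction")
  ranked <- order(-counts, -age)      # ties: older epoch (larger ka BP) first
  train <- sort(ranked[seq_len(k)])
  test <- sort(setdiff(seq_len(n), train))
  new("SelectionResult", trainIndices = as.integer(train),
      testIndices = as.integer(test), counts = counts,
      candidateCount = nCand, nIterations = as.integer(nIter))
}

#' Write a selection result as JSON plus a counts table
#'
#' Emits `<stem>.json` with the train/test epoch lists and
#' `<stem>_counts.tsv` with per-epoch candidate appearance counts.
#'
#' @param result a [SelectionResult-class].
#' @param epochs numeric epochs the indices refer to.
#' @param stem output path stem (no extension).
#' @return invisibly, the two file paths.
#' @export
writeSelection <- function(result, epochs, stem) {
  js <- list(train_epochs = epochs[result@trainIndices],
             test_epochs = epochs[result@testIndices],
             candidate_count = result@candidateCount,
             n_iterations = result@nIterations)
  jsonlite::write_json(js, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  tab <- data.frame(epoch_ka = epochs, count = result@counts,
                    train = seq_along(epochs) %in% result@trainIndices)
  utils::write.table(tab, paste0(stem, "_counts.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(c(paste0(stem, ".json"), paste0(stem, "_counts.tsv")))
}
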