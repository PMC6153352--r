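## Class-imbalance subsampling lasso (CISL): stability-selection variant
## with outcome-upweighted resampling and the pi-hat statistic.

## pi-hat from a list of per-subsample coefficient matrices (covariates x
## path points) given the normalising size E.  For each subsample the path
## is indexed by active-set size eta; when several penalties share a size
## the most-regularised fit of that size is used once.
.cislPi <- function(betaList, E, constraint = c("positive", "nonzero")) {
  constraint <- match.arg(constraint)
  out <- vapply(betaList, function(b) {
    sizes <- Matrix::colSums(b != 0)
    keep <- sizes >= 1L & !duplicated(sizes)
    if (!any(keep)) return(numeric(nrow(b)))
    bk <- b[, keep, drop = FALSE]
    hit <- if (constraint == "positive") bk > 0 else bk != 0
    as.numeric(Matrix::rowSums(hit)) / E
  }, numeric(nrow(betaList[[1]])))
  rownames(out) <- rownames(betaList[[1]])
  out
}

#' Class-imbalance subsampling lasso
#'
#' Stability selection adapted to the extreme outcome imbalance of
#' spontaneous-reporting data.  `B` subsamples of `round(sampleFraction*N)`
#' reports are drawn with replacement, with per-report sampling probability
#' upweighting outcome cases so the expected case fraction among draws is
#' `targetCaseFraction`.  A lasso logistic path (shared penalty grid,
#' computed on the full data) is fitted on each subsample; `E` is the
#' largest active-set size observed on any path.  For covariate `i` and
#' subsample `b` the statistic `pi_hat` is the number of distinct model
#' sizes `eta in 1..E` at which its coefficient satisfies the sign
#' constraint, divided by `E`.  A covariate is selected when a low quantile
#' of its `pi_hat` distribution over the `B` subsamples is positive.
#'
#' @param y binary outcome with both classes.
#' @param X covariate matrix with column names.
#' @param B number of subsamples (default 100).
#' @param lambdas optional shared penalty grid (default [lambdaGrid()]).
#' @param signConstraint `"positive"` for signal detection, `"nonzero"` for
#'   propensity-score covariate selection.
#' @param sampleFraction subsample size as a fraction of N (default 0.5).
#' @param targetCaseFraction expected case share among draws (default 0.25).
#' @param seed RNG seed; fixed seed gives bit-reproducible results.
#' @param maxRetries redraw attempts for a single-class subsample.
#' @return a [CislResult-class].
#' @export
cisl <- function(y, X, B = 100, lambdas = NULL,
                 signConstraint = c("positive", "nonzero"),
                 sampleFraction = 0.5, targetCaseFraction = 0.25,
                 seed = 1L, maxRetries = 10L) {
  signConstraint <- match.arg(signConstraint)
  y <- as.numeric(y)
  if (B < 2L) stop("need at least B = 2 subsamples")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L)
    stop("outcome has a single class; cannot run CISL")
  if (is.null(lambdas)) lambdas <- lambdaGrid(y, X)

  ## per-draw probability making the expected case fraction the target
  wCase <- targetCaseFraction * n0 / ((1 - targetCaseFraction) * n1)
  prob <- ifelse(y == 1, wCase, 1)
  m <- max(2L, round(sampleFraction * length(y)))

  set.seed(seed)
  betaList <- vector("list", B)
  for (b in seq_len(B)) {
    for (try in seq_len(maxRetries + 1L)) {
      idx <- sample.int(length(y), m, replace = TRUE, prob = prob)
      if (length(unique(y[idx])) == 2L) break
      if (try > maxRetries) stop("could not draw a two-class subsample")
      message("single-class subsample redrawn (b = ", b, ")")
    }
    path <- lassoLogisticPath(y[idx], X[idx, , drop = FALSE], lambdas = lambdas)
    betaList[[b]] <- path@beta
  }
  E <- max(1L, max(vapply(betaList, function(b) max(Matrix::colSums(b != 0)), 0)))
  piHat <- .cislPi(betaList, E, signConstraint)
  rownames(piHat) <- colnames(X)
  new("CislResult", piHat = piHat, E = as.integer(E),
      signConstraint = signConstraint)
}

#' @rdname accessors
#' @param q quantile of the per-covariate `pi_hat` distribution
#'   (lower/type-1 empirical quantile); a covariate is selected when that
#'   quantile is strictly positive, i.e. when fewer than `ceiling(q * B)` of
#'   its `B` values are zero.  Lower `q` is stricter, so
#'   `selectedCovariates(x, 0.05)` is always a subset of
#'   `selectedCovariates(x, 0.10)`.
setMethod("selectedCovariates", "CislResult", function(object, q = 0.10) {
  qs <- apply(object@piHat, 1, stats::quantile, probs = q, type = 1)
  rownames(object@piHat)[qs > 0]
})
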