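## L1-penalized logistic paths and BIC-based model selection.

#' Default penalty grid for a lasso logistic path
#'
#' 50 log-spaced values from `lambda_max` -- the smallest penalty at which
#' every coefficient is zero, `max |X'(y - ybar)| / N` for an
#' unstandardized, intercept-only null -- down to `ratio * lambda_max`.
#'
#' @param y binary outcome.
#' @param X covariate matrix.
#' @param nLambda grid length (default 50).
#' @param ratio smallest penalty as a fraction of `lambda_max`
#'   (default 0.01).
#' @return strictly decreasing numeric grid.
#' @export
lambdaGrid <- function(y, X, nLambda = 50, ratio = 0.01) {
  lmax <- max(abs(as.numeric(Matrix::crossprod(X, y - mean(y))))) / length(y)
  if (lmax <= 0) lmax <- 1e-3
  exp(seq(log(lmax), log(lmax * ratio), length.out = nLambda))
}

#' Fit an L1-penalized logistic regression path
#'
#' Maximizes the binomial log-likelihood penalized by `lambda * sum |beta|`
#' (intercept unpenalized) over a decreasing penalty grid, via coordinate
#' descent (glmnet).  Covariates are binary indicators on a common scale,
#' so no standardization is applied.
#'
#' @param y binary outcome with both classes present.
#' @param X covariate matrix (sparse or dense); column names required.
#' @param lambdas optional penalty grid; default [lambdaGrid()].
#' @param nLambda,lambdaMinRatio grid parameters when `lambdas` is `NULL`.
#' @param thresh coordinate-descent convergence tolerance.
#' @return a [LassoPath-class].
#' @export
lassoLogisticPath <- function(y, X, lambdas = NULL, nLambda = 50,
                              lambdaMinRatio = 0.01, thresh = 1e-9) {
  y <- as.numeric(y)
  if (length(unique(y)) < 2L)
    stop("outcome has a single class; cannot fit a logistic model")
  if (is.null(colnames(X))) stop("covariate matrix must have column names")
  if (is.null(lambdas)) lambdas <- lambdaGrid(y, X, nLambda, lambdaMinRatio)
  if (any(diff(lambdas) >= 0)) stop("lambdas must be strictly decreasing")

  ## all-degenerate designs (every column constant) have the null model as
  ## the exact solution at every penalty
  nOn <- as.numeric(Matrix::colSums(X != 0))
  if (all(nOn == 0 | nOn == nrow(X))) {
    beta <- Matrix::Matrix(0, ncol(X), length(lambdas), sparse = TRUE,
                           dimnames = list(colnames(X), NULL))
    return(new("LassoPath", lambda = lambdas,
               beta = as(as(as(beta, "dMatrix"), "generalMatrix"),
                         "CsparseMatrix"),
               intercept = rep(stats::qlogis(mean(y)), length(lambdas))))
  }

  Xfit <- X
  pad <- ncol(X) == 1L  # glmnet requires >= 2 columns
  if (pad) Xfit <- cbind(X, `.pad.` = rep(0, nrow(X)))
  fit <- glmnet::glmnet(Xfit, y, family = "binomial", lambda = lambdas,
                        standardize = FALSE, thresh = thresh)
  beta <- fit$beta
  if (pad) beta <- beta[seq_len(ncol(X)), , drop = FALSE]
  ## glmnet may truncate the path; keep the lambdas actually fitted
  new("LassoPath", lambda = fit$lambda,
      beta = as(as(as(beta, "dMatrix"), "generalMatrix"), "CsparseMatrix"),
      intercept = as.numeric(fit$a0))
}

#' Active covariate sets along a path
#'
#' @param path a [LassoPath-class].
#' @param constraint `"nonzero"` (default) or `"positive"`: which
#'   coefficients count as active.
#' @return list (one element per penalty) of covariate-name vectors.
#' @export
activeSets <- function(path, constraint = c("nonzero", "positive")) {
  constraint <- match.arg(constraint)
  b <- path@beta
  lapply(seq_along(path@lambda), function(k) {
    col <- b[, k]
    rownames(b)[if (constraint == "positive") col > 0 else col != 0]
  })
}

#' Select a model along a lasso path by BIC
#'
#' Each distinct active set along the path is refitted as an ordinary
#' (unpenalized) logistic regression and scored by
#' `BIC = -2 ln L + k ln N`, where `k` counts the fitted parameters
#' (intercept included) and `N` the observations.  The intercept-only model
#' is always a candidate, so an empty selection is returned when nothing
#' beats it.  Candidates whose refit fails to converge (e.g. separation)
#' are skipped with a warning.
#'
#' Because the criterion deteriorates steadily once the active set has grown
#' past the well-supported model, the scan stops early after `patience`
#' consecutive distinct sets without a new minimum; `patience = Inf` forces
#' a full scan.
#'
#' @param path a [LassoPath-class].
#' @param y,X the data the path was fitted on.
#' @param patience early-stopping window (default 10 distinct sets).
#' @return list with elements `selected` (covariate names), `coefficients`
#'   (named, intercept first), `fitted`, `vcov`, `bic` (winning value) and
#'   `candidates` (data frame of set sizes and BICs scanned).
#' @export
bicSelect <- function(path, y, X, patience = 10) {
  y <- as.numeric(y)
  N <- length(y)
  sets <- activeSets(path, "nonzero")
  keys <- vapply(sets, paste, "", collapse = "\r")
  sets <- sets[!duplicated(keys)]
  if (!any(lengths(sets) == 0L)) sets <- c(list(character()), sets)

  best <- NULL; bestBic <- Inf; sinceBest <- 0L
  cand <- data.frame(size = integer(), bic = numeric())
  for (s in sets) {
    Xs <- cbind(`(Intercept)` = rep(1, N),
                if (length(s)) as.matrix(X[, s, drop = FALSE]))
    fit <- .logisticFit(Xs, y)
    if (!fit$converged) {
      warning("BIC refit failed to converge for a set of size ", length(s),
              "; candidate skipped")
      next
    }
    bic <- -2 * fit$logLik + (length(s) + 1L) * log(N)
    cand <- rbind(cand, data.frame(size = length(s), bic = bic))
    if (bic < bestBic) {
      bestBic <- bic
      best <- list(set = s, fit = fit)
      sinceBest <- 0L
    } else sinceBest <- sinceBest + 1L
    if (sinceBest >= patience) break
  }
  if (is.null(best)) stop("no candidate model could be refitted")
  coefs <- best$fit$coefficients
  names(coefs) <- c("(Intercept)", best$set)
  list(selected = best$set, coefficients = coefs, fitted = best$fit$fitted,
       vcov = best$fit$vcovModel, bic = bestBic, candidates = cand)
}
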