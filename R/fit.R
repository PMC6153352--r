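## Internal (weighted) maximum-likelihood logistic fitting shared by the
## BIC refits, the PS refits and the association tests.
##
## Newton-Raphson with step-halving on the weighted binomial
## log-likelihood.  Returns coefficients, fitted values, the log-likelihood
## and both model-based and sandwich covariance; `converged = FALSE` flags
## non-convergence or quasi-separation (|slope| >= maxCoef), which callers
## treat as a failed fit.
.logisticFit <- function(Xmat, y, weights = NULL, maxCoef = 30,
                         maxIter = 50L, tol = 1e-10) {
  Xmat <- as.matrix(Xmat)
  storage.mode(Xmat) <- "double"
  w <- if (is.null(weights)) rep(1, length(y)) else as.numeric(weights)

  k <- ncol(Xmat)
  beta <- numeric(k)
  eta <- drop(Xmat %*% beta)
  mu <- stats::plogis(eta)
  ll <- sum(w * stats::dbinom(y, 1, pmin(pmax(mu, 1e-12), 1 - 1e-12), log = TRUE))
  ok <- TRUE
  for (it in seq_len(maxIter)) {
    W <- w * mu * (1 - mu)
    info <- crossprod(Xmat, Xmat * W)
    score <- crossprod(Xmat, w * (y - mu))
    step <- tryCatch(solve(info, score), error = function(e) NULL)
    if (is.null(step)) { ok <- FALSE; break }
    llNew <- -Inf
    for (h in 0:12) {  # step-halving keeps the likelihood ascending
      betaNew <- beta + drop(step) / 2^h
      muNew <- stats::plogis(drop(Xmat %*% betaNew))
      llNew <- sum(w * stats::dbinom(y, 1, pmin(pmax(muNew, 1e-12), 1 - 1e-12),
                                     log = TRUE))
      if (is.finite(llNew) && llNew >= ll - 1e-12) break
    }
    if (!is.finite(llNew)) { ok <- FALSE; break }
    delta <- llNew - ll
    beta <- betaNew; mu <- muNew; ll <- llNew
    if (delta < tol * (abs(ll) + 1)) break
    if (it == maxIter) ok <- FALSE
  }
  if (anyNA(beta) || (k > 1L && any(abs(beta[-1]) >= maxCoef))) ok <- FALSE

  info <- crossprod(Xmat, Xmat * (w * mu * (1 - mu)))
  vcovModel <- vcovSandwich <- NULL
  bread <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(bread)) ok <- FALSE else {
    vcovModel <- bread
    score <- Xmat * (w * (y - mu))
    vcovSandwich <- bread %*% crossprod(score) %*% bread
  }
  list(coefficients = beta, fitted = as.vector(mu), logLik = ll,
       converged = ok, vcovModel = vcovModel, vcovSandwich = vcovSandwich)
}

.clampPs <- function(p, eps = 1e-6) pmin(pmax(p, eps), 1 - eps)
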