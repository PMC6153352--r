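## PS-based association tests: weights, weighted and adjusted logistic
## regressions, one-sided Wald p-values.

#' Inverse-probability-of-treatment and matching weights
#'
#' `iptwWeights` implements `w = X/e + (1 - X)/(1 - e)`: exposed reports
#' are weighted by the inverse of their propensity score, unexposed by the
#' inverse of its complement, so every weight is >= 1.  `mwWeights`
#' implements `w = min(e, 1 - e) * (X/e + (1 - X)/(1 - e))`, the matching
#' weights, which are bounded in \[0, 1\] and target the estimand of
#' one-to-one PS matching without discarding reports.
#'
#' @param ps a [PropensityScore-class] or a numeric score vector (clamped
#'   away from 0/1).
#' @param x binary exposure vector aligned with the scores.
#' @param trim optional cap for IPTW weights: weights above `trim` are set
#'   to `trim` (weight trimming, a common remedy for the instability of
#'   untrimmed IPTW under extreme scores).  Default `NULL`: no trimming.
#' @return numeric weight vector with attribute `kind` (`"IPTW"`/`"MW"`).
#' @examples
#' iptwWeights(c(0.2, 0.2), c(1, 0))  # 5, 1.25
#' mwWeights(c(0.2, 0.2), c(1, 0))    # 1, 0.25
#' @name ps-weights
NULL

.psVector <- function(ps) if (is(ps, "PropensityScore")) ps@scores else as.numeric(ps)

#' @rdname ps-weights
#' @export
iptwWeights <- function(ps, x, trim = NULL) {
  e <- .psVector(ps)
  x <- as.numeric(x)
  if (length(e) != length(x)) stop("scores and exposure must be aligned")
  w <- x / e + (1 - x) / (1 - e)
  if (!is.null(trim)) {
    stopifnot(trim >= 1)
    w <- pmin(w, trim)
  }
  structure(w, kind = "IPTW")
}

#' @rdname ps-weights
#' @export
mwWeights <- function(ps, x) {
  e <- .psVector(ps)
  w <- iptwWeights(e, x)
  structure(pmin(e, 1 - e) * as.numeric(w), kind = "MW")
}

.naResult <- function(drug, ae, strategy, reason) {
  data.frame(drug = drug, ae = ae, strategy = strategy,
             estimate = NA_real_, se = NA_real_, z = NA_real_,
             p = NA_real_, note = reason)
}

.waldRow <- function(drug, ae, strategy, est, se) {
  z <- est / se
  data.frame(drug = drug, ae = ae, strategy = strategy,
             estimate = est, se = se, z = z,
             p = stats::pnorm(z, lower.tail = FALSE), note = "")
}

#' Weighted univariate logistic association test
#'
#' Solves the weight-scaled logistic score equations for
#' `logit P(Y=1) = b0 + b x` with fixed per-report weights (IPTW or MW) and
#' reports the exposure log odds ratio with a one-sided
#' (harm-direction, `b > 0`) Wald p-value.  The default standard error is
#' the robust sandwich estimator treating the weights as known; model-based
#' variance is available for comparison.
#'
#' @param y binary outcome.
#' @param x binary exposure.
#' @param weights per-report weights from [iptwWeights()] or [mwWeights()]
#'   (unit weights reduce to the ordinary univariate fit).
#' @param variance `"sandwich"` (default) or `"model"`.
#' @param drug,ae labels carried into the result row.
#' @return one-row data frame (`drug`, `ae`, `strategy`, `estimate`, `se`,
#'   `z`, `p`, `note`); failed fits return `NA` estimates with the reason
#'   in `note`.
#' @export
weightedAssociationTest <- function(y, x, weights,
                                    variance = c("sandwich", "model"),
                                    drug = "drug", ae = "ae") {
  variance <- match.arg(variance)
  y <- as.numeric(y); x <- as.numeric(x); w <- as.numeric(weights)
  strategy <- tolower(attr(weights, "kind") %||% "weighted")
  cells <- c(sum(w[x == 1 & y == 1]), sum(w[x == 1 & y == 0]),
             sum(w[x == 0 & y == 1]), sum(w[x == 0 & y == 0]))
  if (any(cells <= 0))
    return(.naResult(drug, ae, strategy, "zero weighted cell"))
  fit <- .logisticFit(cbind(1, x), y, weights = w)
  if (!fit$converged)
    return(.naResult(drug, ae, strategy, "non-convergence"))
  V <- if (variance == "sandwich") fit$vcovSandwich else fit$vcovModel
  .waldRow(drug, ae, strategy, fit$coefficients[2], sqrt(V[2, 2]))
}

#' PS-adjusted logistic association test
#'
#' Fits `logit P(Y=1) = b0 + b x + c e` with the estimated propensity score
#' entering on the probability scale as an additional covariate, and
#' reports the exposure coefficient with a one-sided Wald p-value.  A
#' (numerically) constant PS is collinear with the intercept and is dropped
#' with a warning, reducing to the univariate fit.
#'
#' @param y binary outcome.
#' @param x binary exposure.
#' @param ps a [PropensityScore-class] or numeric score vector.
#' @param drug,ae labels carried into the result row.
#' @return one-row data frame as in [weightedAssociationTest()].
#' @export
adjustedAssociationTest <- function(y, x, ps, drug = "drug", ae = "ae") {
  y <- as.numeric(y); x <- as.numeric(x); e <- .psVector(ps)
  tab <- table(factor(x, 0:1), factor(y, 0:1))
  if (any(tab == 0))
    return(.naResult(drug, ae, "adjust", "degenerate 2x2 cell"))
  if (stats::sd(e) < 1e-10) {
    warning("constant PS dropped from adjustment model (collinear with intercept)")
    fit <- .logisticFit(cbind(1, x), y)
  } else {
    fit <- .logisticFit(cbind(1, x, e), y)
  }
  if (!fit$converged)
    return(.naResult(drug, ae, "adjust", "non-convergence"))
  .waldRow(drug, ae, "adjust", fit$coefficients[2], sqrt(fit$vcovModel[2, 2]))
}

#' Unadjusted univariate logistic association test
#'
#' The disproportionality-style reference: `logit P(Y=1) = b0 + b x` per
#' drug, equivalent to a reporting-odds-ratio analysis of the 2x2 table;
#' one-sided Wald p-value in the harm direction.
#'
#' @param y binary outcome.
#' @param x binary exposure.
#' @param drug,ae labels carried into the result row.
#' @return one-row data frame as in [weightedAssociationTest()].
#' @export
univariateAssociationTest <- function(y, x, drug = "drug", ae = "ae") {
  y <- as.numeric(y); x <- as.numeric(x)
  tab <- table(factor(x, 0:1), factor(y, 0:1))
  if (any(tab == 0))
    return(.naResult(drug, ae, "univariate", "degenerate 2x2 cell"))
  fit <- .logisticFit(cbind(1, x), y)
  if (!fit$converged)
    return(.naResult(drug, ae, "univariate", "non-convergence"))
  .waldRow(drug, ae, "univariate", fit$coefficients[2], sqrt(fit$vcovModel[2, 2]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
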