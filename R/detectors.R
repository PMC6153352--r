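## Signal detectors.  Every detector consumes a ReportMatrix (already
## restricted to eligible drugs) and one target AE column, and emits the
## same signal-table schema, so the evaluation harness is detector-agnostic.

.aeData <- function(rm, ae) {
  j <- .aeColumn(rm, ae)
  list(y = as.numeric(events(rm)[, j]), aeId = aeIds(rm)[j])
}

#' Univariate (disproportionality-style) detector
#'
#' One unadjusted logistic regression per drug
#' ([univariateAssociationTest()]), followed by BH adjustment of the
#' one-sided p-values and the FDR decision rule.
#'
#' @param rm a [ReportMatrix-class] restricted to eligible drugs.
#' @param ae target AE column.
#' @param fdrLevel FDR threshold (default 0.05).
#' @return a signal table: data frame with columns `drug`, `ae`, `method`,
#'   `strategy`, `estimate`, `se`, `z`, `p`, `p_fdr`, `signal`, `note`.
#' @export
univariateDetector <- function(rm, ae, fdrLevel = 0.05) {
  d <- .aeData(rm, ae)
  rows <- lapply(drugIds(rm), function(g)
    univariateAssociationTest(d$y, exposures(rm)[, g], drug = g, ae = d$aeId))
  .signalTable(rows, "univ", fdrLevel)
}

#' BIC-lasso multiple-regression detector
#'
#' A lasso path of the outcome on all drugs jointly, BIC-based model
#' selection ([bicSelect()]), then the sign rule: signals are the drugs
#' with a positive refit coefficient in the BIC-minimizing model (no test
#' is involved in the decision).  For ranking use each signal also carries
#' the refit one-sided Wald p-value.
#'
#' @inheritParams univariateDetector
#' @param nLambda,patience passed to the path / BIC scan.
#' @return a signal table; drugs outside the selected model carry a zero
#'   estimate and `NA` p-values.
#' @export
bicLassoDetector <- function(rm, ae, nLambda = 50, patience = 10) {
  d <- .aeData(rm, ae)
  X <- exposures(rm)
  path <- lassoLogisticPath(d$y, X, nLambda = nLambda)
  sel <- bicSelect(path, d$y, X, patience = patience)
  est <- se <- setNames(rep(0, nDrugs(rm)), drugIds(rm))
  p <- setNames(rep(NA_real_, nDrugs(rm)), drugIds(rm))
  if (length(sel$selected)) {
    co <- sel$coefficients[-1]
    ses <- sqrt(diag(sel$vcov))[-1]
    est[sel$selected] <- co
    se[sel$selected] <- ses
    p[sel$selected] <- stats::pnorm(co / ses, lower.tail = FALSE)
  }
  tbl <- data.frame(drug = drugIds(rm), ae = d$aeId, method = "bic-lasso",
                    strategy = "multiple", estimate = unname(est),
                    se = unname(se), z = unname(est / se),
                    p = unname(p), p_fdr = NA_real_,
                    signal = unname(est > 0), note = "")
  tbl[order(tbl$drug), ]
}

#' CISL multiple-regression detector
#'
#' [cisl()] with the positive sign constraint; the decision is the
#' selection itself (all selected drugs are signals, positivity being part
#' of the statistic), so no p-values are produced.  The reported estimate
#' is the `quantile`-level value of each drug's `pi_hat` distribution.
#'
#' @inheritParams univariateDetector
#' @param quantile selection quantile, conventionally 0.05 or 0.10.
#' @param B,seed,... passed to [cisl()].
#' @return a signal table with `NA` p-value columns.
#' @export
cislDetector <- function(rm, ae, quantile = 0.10, B = 100, seed = 1L, ...) {
  d <- .aeData(rm, ae)
  res <- cisl(d$y, exposures(rm), B = B, signConstraint = "positive",
              seed = seed, ...)
  qs <- apply(res@piHat, 1, stats::quantile, probs = quantile, type = 1)
  tbl <- data.frame(drug = drugIds(rm), ae = d$aeId,
                    method = sprintf("cisl-%d", round(100 * quantile)),
                    strategy = "multiple", estimate = unname(qs),
                    se = NA_real_, z = NA_real_, p = NA_real_,
                    p_fdr = NA_real_, signal = unname(qs > 0), note = "")
  tbl[order(tbl$drug), ]
}

#' Propensity-score detector
#'
#' For each drug, estimate (or reuse from `psCache`) a propensity score by
#' `psMethod`, then test its association with the AE by the chosen
#' `strategy`: PS adjustment ([adjustedAssociationTest()]) or IPTW / MW
#' weighted regression ([weightedAssociationTest()]).  One-sided p-values
#' are BH-adjusted and thresholded at `fdrLevel`.
#'
#' @inheritParams univariateDetector
#' @param psMethod `"BIC"`, `"CISL"`, `"hdPS"` or `"GTB"`.
#' @param strategy `"adjust"`, `"iptw"` or `"mw"`.
#' @param psCache optional environment mapping drug code to a precomputed
#'   [PropensityScore-class]; AE-independent scores computed here are added
#'   to it, so adjust/iptw/mw runs share one estimation pass.
#' @param variance variance estimator for weighted fits.
#' @param ... passed to the PS estimator.
#' @return a signal table; the method label is e.g. `"mwPS-BIC"`.
#' @export
psDetector <- function(rm, ae, psMethod = c("BIC", "CISL", "hdPS", "GTB"),
                       strategy = c("adjust", "iptw", "mw"),
                       fdrLevel = 0.05, psCache = NULL,
                       variance = c("sandwich", "model"), ...) {
  psMethod <- match.arg(psMethod)
  strategy <- match.arg(strategy)
  variance <- match.arg(variance)
  d <- .aeData(rm, ae)
  label <- paste0(c(adjust = "adjustPS-", iptw = "iptwPS-",
                    mw = "mwPS-")[strategy], psMethod)
  rows <- lapply(drugIds(rm), function(g) {
    ps <- NULL
    cacheable <- psMethod != "hdPS"
    if (cacheable && !is.null(psCache) && !is.null(psCache[[g]]))
      ps <- psCache[[g]]
    if (is.null(ps)) {
      ps <- estimatePs(rm, g, psMethod, ae = ae, ...)
      if (cacheable && !is.null(psCache)) psCache[[g]] <- ps
    }
    x <- as.numeric(exposures(rm)[, g])
    if (strategy == "adjust")
      adjustedAssociationTest(d$y, x, ps, drug = g, ae = d$aeId)
    else {
      w <- if (strategy == "iptw") iptwWeights(ps, x) else mwWeights(ps, x)
      weightedAssociationTest(d$y, x, w, variance = variance,
                              drug = g, ae = d$aeId)
    }
  })
  .signalTable(rows, label, fdrLevel)
}
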