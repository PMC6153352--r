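## Per-drug propensity-score estimation in high dimension.
##
## For a target drug the PS is its probability of being reported
## conditional on the other drugs on the report.  Three variable-selection
## routes (BIC-lasso, CISL with a nonzero sign constraint, hdPS confounder
## ranking) feed an unpenalized logistic refit; the fourth route fits a
## gradient-tree-boosting classifier on all co-reported drugs.

.psParts <- function(rm, drug) {
  i <- .drugColumn(rm, drug)
  x <- as.numeric(exposures(rm)[, i])
  if (all(x == 0) || all(x == 1))
    stop("degenerate exposure for drug ", drugIds(rm)[i],
         ": needs both exposed and unexposed reports")
  list(x = x, others = exposures(rm)[, -i, drop = FALSE], id = drugIds(rm)[i])
}

.psRefit <- function(x, others, selected) {
  Xs <- cbind(`(Intercept)` = rep(1, length(x)),
              if (length(selected)) as.matrix(others[, selected, drop = FALSE]))
  fit <- .logisticFit(Xs, x)
  if (!fit$converged)
    warning("PS refit convergence flagged; scores used as-is")
  fit$fitted
}

#' Propensity score via BIC-lasso covariate selection
#'
#' The exposure is regressed on all other drugs along a lasso path; the
#' covariates of the BIC-minimizing model ([bicSelect()]) define an
#' unpenalized logistic PS model whose fitted probabilities are the scores.
#'
#' @param rm a [ReportMatrix-class].
#' @param drug target drug (code or index).
#' @param nLambda,patience passed to [lassoLogisticPath()] / [bicSelect()].
#' @return a [PropensityScore-class] (AE-independent).
#' @export
psBic <- function(rm, drug, nLambda = 50, patience = 10) {
  p <- .psParts(rm, drug)
  path <- lassoLogisticPath(p$x, p$others, nLambda = nLambda)
  sel <- bicSelect(path, p$x, p$others, patience = patience)
  new("PropensityScore", drug = p$id, method = "BIC",
      scores = .clampPs(sel$fitted), covariatesUsed = sel$selected,
      aeDependent = FALSE)
}

#' Propensity score via CISL covariate selection
#'
#' [cisl()] with the sign constraint relaxed to "nonzero" (a PS model wants
#' any predictor of exposure, whatever its direction); covariates whose
#' `q` quantile of `pi_hat` is positive enter an unpenalized logistic
#' refit.  An empty selection falls back to the intercept-only model
#' (constant PS = drug prevalence) with a message.
#'
#' @inheritParams psBic
#' @param q selection quantile (default 0.10).
#' @param B,seed,... passed to [cisl()].
#' @return a [PropensityScore-class] (AE-independent).
#' @export
psCisl <- function(rm, drug, q = 0.10, B = 100, seed = 1L, ...) {
  p <- .psParts(rm, drug)
  res <- cisl(p$x, p$others, B = B, signConstraint = "nonzero", seed = seed, ...)
  sel <- selectedCovariates(res, q)
  if (!length(sel))
    message("CISL selected no covariate for ", p$id, "; intercept-only PS")
  new("PropensityScore", drug = p$id, method = "CISL",
      scores = .clampPs(.psRefit(p$x, p$others, sel)),
      covariatesUsed = sel, aeDependent = FALSE)
}

#' hdPS confounder ranking (Bross multiplicative bias)
#'
#' Scores every candidate drug for confounding potential with respect to an
#' exposure and an outcome: with `P_C1`/`P_C0` the candidate's prevalence
#' among exposed/unexposed reports and `RR_CD` its risk ratio for the
#' outcome (0.1 added to the four cells of the candidate x outcome table to
#' guard zero cells),
#' `Bias_M = (P_C1 (RR_CD - 1) + 1) / (P_C0 (RR_CD - 1) + 1)` and the
#' ranking score is `|log10 Bias_M|`.  Candidates unrelated to the outcome
#' (`RR_CD = 1`) or balanced across exposure arms (`P_C1 = P_C0`) score 0.
#'
#' @param rm a [ReportMatrix-class].
#' @param drug exposure drug (code or index).
#' @param ae outcome column (code or index).
#' @return data frame of candidates sorted by decreasing score, with
#'   columns `candidate`, `pc1`, `pc0`, `rr`, `score`.
#' @export
hdpsRank <- function(rm, drug, ae) {
  p <- .psParts(rm, drug)
  y <- as.numeric(events(rm)[, .aeColumn(rm, ae)])
  C <- p$others
  n1 <- sum(p$x); n0 <- length(p$x) - n1
  pc1 <- as.numeric(Matrix::crossprod(C, p$x)) / n1
  pc0 <- as.numeric(Matrix::crossprod(C, 1 - p$x)) / n0
  ## candidate x outcome table with 0.1 added to each cell
  a <- as.numeric(Matrix::crossprod(C, y))          # c=1, y=1
  cTot <- as.numeric(Matrix::colSums(C))
  b <- cTot - a                                      # c=1, y=0
  cc <- sum(y) - a                                   # c=0, y=1
  d <- length(y) - cTot - cc                         # c=0, y=0
  risk1 <- (a + 0.1) / (a + b + 0.2)
  risk0 <- (cc + 0.1) / (cc + d + 0.2)
  rr <- risk1 / risk0
  bias <- (pc1 * (rr - 1) + 1) / (pc0 * (rr - 1) + 1)
  out <- data.frame(candidate = colnames(C), pc1 = pc1, pc0 = pc0,
                    rr = rr, score = abs(log10(bias)))
  out[order(-out$score, out$candidate), , drop = FALSE]
}

#' Propensity score via hdPS top-ranked covariates
#'
#' The `nTop` candidates ranked highest by [hdpsRank()] form an unpenalized
#' logistic PS model.  Unlike the other estimators this PS depends on the
#' outcome through the ranking, so it must be re-estimated per adverse
#' event.
#'
#' @inheritParams hdpsRank
#' @param nTop number of top-ranked covariates (default 20).
#' @return a [PropensityScore-class] with `aeDependent = TRUE`.
#' @export
psHdps <- function(rm, drug, ae, nTop = 20) {
  p <- .psParts(rm, drug)
  rk <- hdpsRank(rm, drug, ae)
  sel <- utils::head(rk$candidate, nTop)
  new("PropensityScore", drug = p$id, method = "hdPS",
      scores = .clampPs(.psRefit(p$x, p$others, sel)),
      covariatesUsed = sel, aeDependent = TRUE)
}

#' Propensity score via gradient tree boosting
#'
#' Boosted classification trees of the exposure on all other drugs
#' (binary logistic objective, learning rate 0.1, other hyperparameters at
#' the library defaults).  Deterministic for a fixed seed and single
#' thread.
#'
#' @inheritParams psBic
#' @param learningRate shrinkage per boosting round (default 0.1).
#' @param nRounds boosting rounds (default 100).
#' @param seed RNG seed.
#' @return a [PropensityScore-class] (AE-independent,
#'   `covariatesUsed` empty: all co-reported drugs enter the trees).
#' @export
psGtb <- function(rm, drug, learningRate = 0.1, nRounds = 100, seed = 1L) {
  p <- .psParts(rm, drug)
  set.seed(seed)
  dtrain <- xgboost::xgb.DMatrix(p$others, label = p$x, nthread = 1)
  booster <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", eta = learningRate,
                  nthread = 1, seed = seed),
    data = dtrain, nrounds = nRounds, verbose = 0)
  new("PropensityScore", drug = p$id, method = "GTB",
      scores = .clampPs(stats::predict(booster, dtrain)),
      covariatesUsed = character(), aeDependent = FALSE)
}

#' Estimate a propensity score by name
#'
#' Dispatch helper used by the pipeline: `method` is one of `"BIC"`,
#' `"CISL"`, `"hdPS"`, `"GTB"`.
#'
#' @param rm a [ReportMatrix-class].
#' @param drug target drug.
#' @param method PS estimation method name.
#' @param ae outcome column, required for `"hdPS"` only.
#' @param ... passed to the specific estimator.
#' @return a [PropensityScore-class].
#' @export
estimatePs <- function(rm, drug, method = c("BIC", "CISL", "hdPS", "GTB"),
                       ae = NULL, ...) {
  method <- match.arg(method)
  switch(method,
         BIC = psBic(rm, drug, ...),
         CISL = psCisl(rm, drug, ...),
         hdPS = {
           if (is.null(ae)) stop("hdPS needs the target AE")
           psHdps(rm, drug, ae, ...)
         },
         GTB = psGtb(rm, drug, ...))
}
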