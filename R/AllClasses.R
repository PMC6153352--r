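#' @import methods
#' @importFrom Matrix Matrix colSums rowSums crossprod t readMM writeMM sparseMatrix
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' ReportMatrix: individual spontaneous reports as sparse indicator matrices
#'
#' The central data container: one row per spontaneous report, with a sparse
#' binary exposure matrix (reports x drugs) and a sparse binary event matrix
#' (reports x adverse events).  Column names carry the drug and AE
#' vocabularies; row names the report identifiers.
#'
#' @slot exposures sparse binary `dgCMatrix`, N reports x I drugs.
#' @slot events sparse binary `dgCMatrix`, N reports x J adverse events.
#'
#' @section Validity:
#' All entries must be 0/1; both matrices share the same report rows;
#' drug and AE codes must be non-empty and free of duplicates; N, I, J >= 1.
#'
#' @seealso [buildReportMatrix()], [filterEligibleDrugs()], [pairCounts()]
#' @export
setClass("ReportMatrix",
  representation(exposures = "dgCMatrix", events = "dgCMatrix"))

setValidity("ReportMatrix", function(object) {
  X <- object@exposures
  Y <- object@events
  msg <- character()
  if (nrow(X) < 1L || ncol(X) < 1L || ncol(Y) < 1L)
    msg <- c(msg, "need at least one report, one drug and one AE")
  if (nrow(X) != nrow(Y))
    msg <- c(msg, "exposure and event matrices must have the same rows")
  if (length(X@x) && any(X@x != 1))
    msg <- c(msg, "exposure entries must be 0/1")
  if (length(Y@x) && any(Y@x != 1))
    msg <- c(msg, "event entries must be 0/1")
  if (is.null(colnames(X)) || anyDuplicated(colnames(X)) || any(!nzchar(colnames(X))))
    msg <- c(msg, "drug codes must be non-empty and unique")
  if (is.null(colnames(Y)) || anyDuplicated(colnames(Y)) || any(!nzchar(colnames(Y))))
    msg <- c(msg, "AE codes must be non-empty and unique")
  if (length(msg)) msg else TRUE
})

#' LassoPath: coefficients of an L1-penalized logistic regression path
#'
#' Holds the solution of an L1-penalized binomial fit over a strictly
#' decreasing penalty grid: one sparse coefficient column per penalty value,
#' plus the unpenalized intercepts.
#'
#' @slot lambda strictly decreasing penalty grid.
#' @slot beta sparse coefficient matrix, covariates x penalties.
#' @slot intercept per-penalty intercepts.
#' @seealso [lassoLogisticPath()], [bicSelect()]
#' @export
setClass("LassoPath",
  representation(lambda = "numeric", beta = "dgCMatrix", intercept = "numeric"))

setValidity("LassoPath", function(object) {
  msg <- character()
  if (length(object@lambda) < 1L) msg <- c(msg, "empty penalty grid")
  if (any(diff(object@lambda) >= 0)) msg <- c(msg, "lambda must be strictly decreasing")
  if (ncol(object@beta) != length(object@lambda))
    msg <- c(msg, "one coefficient column per lambda required")
  if (length(object@intercept) != length(object@lambda))
    msg <- c(msg, "one intercept per lambda required")
  if (is.null(rownames(object@beta)))
    msg <- c(msg, "coefficient rows must carry covariate names")
  if (length(msg)) msg else TRUE
})

#' CislResult: subsampling selection frequencies of the CISL statistic
#'
#' For each covariate and each of B outcome-upweighted subsamples, the
#' fraction (out of E, the largest active-set size seen on any subsample
#' path) of model sizes at which the covariate's lasso coefficient satisfies
#' the sign constraint.
#'
#' @slot piHat covariates x subsamples matrix of selection frequencies in \[0,1\].
#' @slot E normalising maximum model size (>= 1).
#' @slot signConstraint `"positive"` (signal detection) or `"nonzero"`
#'   (propensity-score covariate selection).
#' @seealso [cisl()], [selectedCovariates()]
#' @export
setClass("CislResult",
  representation(piHat = "matrix", E = "integer", signConstraint = "character"))

setValidity("CislResult", function(object) {
  msg <- character()
  if (object@E < 1L) msg <- c(msg, "E must be >= 1")
  if (any(object@piHat < 0 | object@piHat > 1)) msg <- c(msg, "pi-hat values must lie in [0,1]")
  if (is.null(rownames(object@piHat))) msg <- c(msg, "pi-hat rows must carry covariate names")
  if (ncol(object@piHat) < 2L) msg <- c(msg, "need at least 2 subsamples")
  if (!object@signConstraint %in% c("positive", "nonzero"))
    msg <- c(msg, "signConstraint must be 'positive' or 'nonzero'")
  if (length(msg)) msg else TRUE
})

#' PropensityScore: per-report estimated exposure probability for one drug
#'
#' @slot drug the exposure drug code.
#' @slot method one of `"BIC"`, `"CISL"`, `"hdPS"`, `"GTB"`.
#' @slot scores per-report exposure probability, clamped to
#'   \[1e-6, 1 - 1e-6\] so downstream inverse-probability weights stay finite.
#' @slot covariatesUsed drug codes entering the PS model (empty for GTB,
#'   which uses all co-reported drugs); never contains the exposure itself.
#' @slot aeDependent `TRUE` only for hdPS, whose confounder ranking uses the
#'   outcome; the other methods yield one reusable PS per drug.
#' @seealso [psBic()], [psCisl()], [psHdps()], [psGtb()]
#' @export
setClass("PropensityScore",
  representation(drug = "character", method = "character", scores = "numeric",
                 covariatesUsed = "character", aeDependent = "logical"))

setValidity("PropensityScore", function(object) {
  msg <- character()
  eps <- 1e-6
  if (!object@method %in% c("BIC", "CISL", "hdPS", "GTB"))
    msg <- c(msg, "unknown PS method")
  if (any(object@scores < eps - 1e-12 | object@scores > 1 - eps + 1e-12))
    msg <- c(msg, "scores must be clamped to [1e-6, 1-1e-6]")
  if (object@drug %in% object@covariatesUsed)
    msg <- c(msg, "PS model must not contain the exposure drug itself")
  if (length(msg)) msg else TRUE
})

#' SimulationConfig: parameters of the synthetic spontaneous-reporting model
#'
#' Defines a database of `nReports` reports over `nDrugs` drugs with one
#' composite adverse-event column.  Drugs carrying a true effect and their
#' confounded null partners are grouped into co-prescription blocks driven by
#' a latent Bernoulli factor; remaining drugs are reported independently.
#'
#' @slot nReports,nDrugs,nBlocks,nTrueSignals,nConfoundedNulls integer sizes.
#' @slot withinBlockCorr co-prescription coupling in \[0, 1): 0 means
#'   independent reporting within blocks.
#' @slot blockFactorProb probability a report is a co-prescription episode.
#' @slot drugPrevalenceRange (low, high) marginal reporting probabilities.
#' @slot trueLogOrRange (low, high) log odds ratios for true signals.
#' @slot baselineAeLogit intercept of the outcome model (logit scale).
#' @slot seed RNG seed making the draw fully reproducible.
#' @seealso [simConfig()], [simulateReports()]
#' @export
setClass("SimulationConfig",
  representation(nReports = "integer", nDrugs = "integer", nBlocks = "integer",
                 withinBlockCorr = "numeric", blockFactorProb = "numeric",
                 drugPrevalenceRange = "numeric", nTrueSignals = "integer",
                 trueLogOrRange = "numeric", nConfoundedNulls = "integer",
                 baselineAeLogit = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nReports < 1L || object@nDrugs < 1L) msg <- c(msg, "need nReports, nDrugs >= 1")
  if (object@nBlocks < 1L) msg <- c(msg, "need nBlocks >= 1")
  if (object@nBlocks > object@nDrugs) msg <- c(msg, "more blocks than drugs")
  pr <- object@drugPrevalenceRange
  if (length(pr) != 2L || any(pr <= 0) || any(pr >= 1) || pr[1] > pr[2])
    msg <- c(msg, "drugPrevalenceRange must be increasing within (0,1)")
  if (object@withinBlockCorr < 0 || object@withinBlockCorr >= 1)
    msg <- c(msg, "withinBlockCorr must lie in [0,1)")
  if (object@blockFactorProb <= 0 || object@blockFactorProb >= 1)
    msg <- c(msg, "blockFactorProb must lie in (0,1)")
  if (object@nTrueSignals + object@nConfoundedNulls > object@nDrugs)
    msg <- c(msg, "nTrueSignals + nConfoundedNulls must not exceed nDrugs")
  if (object@nConfoundedNulls > 0L && object@nTrueSignals < 1L)
    msg <- c(msg, "confounded nulls need at least one true signal to share a block with")
  if (length(object@trueLogOrRange) != 2L || object@trueLogOrRange[1] > object@trueLogOrRange[2])
    msg <- c(msg, "trueLogOrRange must be (low, high) with low <= high")
  if (length(msg)) msg else TRUE
})

#' SimulatedDatabase: a synthetic reporting database with planted ground truth
#'
#' @slot rm the generated [ReportMatrix-class] (single composite AE column).
#' @slot truth data frame with columns `drug`, `label`
#'   (`true_signal` / `confounded_null` / `independent_null`) and `log_or`
#'   (nonzero exactly for true signals).
#' @slot config the [SimulationConfig-class] that produced the draw.
#' @seealso [simulateReports()], [referenceFromTruth()]
#' @export
setClass("SimulatedDatabase",
  representation(rm = "ReportMatrix", truth = "data.frame", config = "SimulationConfig"))

setValidity("SimulatedDatabase", function(object) {
  msg <- character()
  tr <- object@truth
  if (!all(c("drug", "label", "log_or") %in% names(tr)))
    msg <- c(msg, "truth must have columns drug, label, log_or")
  if (!setequal(tr$drug, colnames(object@rm@exposures)))
    msg <- c(msg, "truth rows must cover exactly the drug vocabulary")
  if (!all(tr$label %in% c("true_signal", "confounded_null", "independent_null")))
    msg <- c(msg, "unknown truth label")
  if (!all((tr$log_or != 0) == (tr$label == "true_signal")))
    msg <- c(msg, "log_or must be nonzero exactly on true_signal drugs")
  if (length(msg)) msg else TRUE
})
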