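## Synthetic spontaneous-reporting generator with planted ground truth.

#' Configure the synthetic spontaneous-reporting model
#'
#' The generator emulates the structural features of a national
#' spontaneous-reporting database that matter for detector behaviour:
#' sparse binary drug exposures, a rare composite outcome, co-prescription
#' correlation between drugs, a subset of drugs with a genuine effect on the
#' outcome, and confounded null drugs that share reports with effect drugs
#' but have no direct effect of their own.
#'
#' Exposures in a block follow a latent-factor model: per report and block a
#' Bernoulli co-prescription factor `U ~ Bern(blockFactorProb)` is drawn and
#' a block drug with marginal prevalence `p` is reported with probability
#' `pHigh` if `U = 1` and `pLow = (1 - withinBlockCorr) * p` otherwise,
#' with `pHigh` set so the marginal prevalence stays `p`.  Setting
#' `withinBlockCorr = 0` makes all drugs independent.  Each confounded null
#' is placed in the same block as a true-signal drug, so its univariate
#' association with the outcome is biased away from zero while its
#' coefficient in the full multiple logistic model is exactly zero.
#'
#' The outcome is drawn per report from
#' `logit P(Y = 1) = baselineAeLogit + sum_i beta_i X_i`, with `beta_i`
#' nonzero (uniform in `trueLogOrRange`) exactly for true-signal drugs.
#'
#' @param nReports,nDrugs database size; defaults 20000 reports, 200 drugs.
#' @param nBlocks number of co-prescription blocks (default 10).
#' @param withinBlockCorr coupling in \[0, 1) (default 0.90, giving
#'   within-block pairwise exposure correlations around 0.3, strong enough
#'   for confounded nulls to bias univariate measures).
#' @param blockFactorProb latent factor probability (default 0.10).
#' @param drugPrevalenceRange marginal reporting probabilities, drawn
#'   uniformly per drug (default 0.02--0.06).
#' @param nTrueSignals,nConfoundedNulls planted structure (defaults 10, 10).
#' @param trueLogOrRange log odds-ratio range for true signals
#'   (default 0.7--1.5).
#' @param baselineAeLogit outcome intercept; default `qlogis(0.05)`, i.e. a
#'   baseline event rate of 0.05.
#' @param seed RNG seed.
#' @return a [SimulationConfig-class].
#' @export
simConfig <- function(nReports = 20000, nDrugs = 200, nBlocks = 10,
                      withinBlockCorr = 0.90, blockFactorProb = 0.10,
                      drugPrevalenceRange = c(0.02, 0.06),
                      nTrueSignals = 10, trueLogOrRange = c(0.7, 1.5),
                      nConfoundedNulls = 10,
                      baselineAeLogit = stats::qlogis(0.05), seed = 1L) {
  new("SimulationConfig",
      nReports = as.integer(nReports), nDrugs = as.integer(nDrugs),
      nBlocks = as.integer(nBlocks),
      withinBlockCorr = as.numeric(withinBlockCorr),
      blockFactorProb = as.numeric(blockFactorProb),
      drugPrevalenceRange = as.numeric(drugPrevalenceRange),
      nTrueSignals = as.integer(nTrueSignals),
      trueLogOrRange = as.numeric(trueLogOrRange),
      nConfoundedNulls = as.integer(nConfoundedNulls),
      baselineAeLogit = as.numeric(baselineAeLogit),
      seed = as.integer(seed))
}

#' Draw a synthetic reporting database with known ground truth
#'
#' See [simConfig()] for the generating model.  The draw is fully
#' reproducible from `config@seed`: identical configs give byte-identical
#' matrices.
#'
#' @param config a [SimulationConfig-class].
#' @return a [SimulatedDatabase-class] holding the [ReportMatrix-class]
#'   (single composite AE column `"AE1"`), the per-drug truth table and the
#'   config.
#' @export
simulateReports <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  N <- config@nReports; I <- config@nDrugs
  nT <- config@nTrueSignals; nC <- config@nConfoundedNulls
  rho <- config@withinBlockCorr; f <- config@blockFactorProb

  set.seed(config@seed)
  drugs <- sprintf("D%03d", seq_len(I))
  label <- rep("independent_null", I)
  label[seq_len(nT)] <- "true_signal"
  if (nC > 0) label[nT + seq_len(nC)] <- "confounded_null"

  ## blocks hold the true signals and their confounded partners
  block <- rep(NA_integer_, I)
  if (nT > 0) block[seq_len(nT)] <- ((seq_len(nT) - 1L) %% config@nBlocks) + 1L
  if (nC > 0) block[nT + seq_len(nC)] <- ((seq_len(nC) - 1L) %% config@nBlocks) + 1L

  prev <- stats::runif(I, config@drugPrevalenceRange[1], config@drugPrevalenceRange[2])
  pLow <- (1 - rho) * prev
  pHigh <- (prev - (1 - f) * pLow) / f
  if (any(pHigh[!is.na(block)] > 1))
    stop("infeasible config: within-block high prevalence exceeds 1; ",
         "lower withinBlockCorr or drug prevalences, or raise blockFactorProb")

  X <- matrix(0L, N, I, dimnames = list(sprintf("R%05d", seq_len(N)), drugs))
  usedBlocks <- sort(unique(block[!is.na(block)]))
  U <- matrix(stats::rbinom(N * length(usedBlocks), 1L, f), N, length(usedBlocks))
  colnames(U) <- usedBlocks
  for (i in seq_len(I)) {
    p <- if (is.na(block[i])) rep(prev[i], N)
         else ifelse(U[, as.character(block[i])] == 1L, pHigh[i], pLow[i])
    X[, i] <- stats::rbinom(N, 1L, p)
  }

  beta <- numeric(I)
  beta[label == "true_signal"] <-
    stats::runif(nT, config@trueLogOrRange[1], config@trueLogOrRange[2])
  eta <- config@baselineAeLogit + as.vector(X %*% beta)
  y <- stats::rbinom(N, 1L, stats::plogis(eta))
  Y <- matrix(y, ncol = 1, dimnames = list(rownames(X), "AE1"))

  rm <- ReportMatrix(X, Y)
  truth <- data.frame(drug = drugs, label = label, log_or = beta)
  new("SimulatedDatabase", rm = rm, truth = truth, config = config)
}

#' Write a simulated database to disk
#'
#' Emits the sparse dialect of [writeSparseDir()] plus `truth.tsv`
#' (`drug<TAB>label<TAB>log_or`).
#'
#' @param db a [SimulatedDatabase-class].
#' @param path output directory.
#' @export
writeSimulatedDatabase <- function(db, path) {
  writeSparseDir(db@rm, path)
  utils::write.table(db@truth, file.path(path, "truth.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Derive a reference signal set from simulation truth
#'
#' True-signal drugs become positive controls; confounded and independent
#' nulls become negative controls (none of them has a causal effect).
#'
#' @param db a [SimulatedDatabase-class].
#' @param ae AE code used in the pairs (default the single simulated column).
#' @return a reference data frame as accepted by [evaluateSignals()].
#' @export
referenceFromTruth <- function(db, ae = aeIds(db@rm)[1]) {
  validateReferenceSet(data.frame(
    drug = db@truth$drug, ae = ae,
    label = ifelse(db@truth$label == "true_signal", "positive", "negative")))
}
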