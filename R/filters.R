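## Eligibility filtering and aggregate pair counts.

.aeColumn <- function(rm, ae) {
  Y <- events(rm)
  j <- if (is.character(ae)) match(ae, colnames(Y)) else as.integer(ae)
  if (is.na(j) || j < 1L || j > ncol(Y)) stop("unknown AE column: ", ae)
  j
}

.drugColumn <- function(rm, drug) {
  X <- exposures(rm)
  i <- if (is.character(drug)) match(drug, colnames(X)) else as.integer(drug)
  if (is.na(i) || i < 1L || i > ncol(X)) stop("unknown drug column: ", drug)
  i
}

#' Restrict a database to drugs eligible for signal testing
#'
#' Very rarely reported drugs make individual regressions numerically
#' fragile, so testing is limited to drugs with more than `minCoreports`
#' reports in common with the target adverse event and more than `minTotal`
#' reports overall.  Both bounds are strict (`>`), so a drug with exactly
#' `minCoreports` co-reports is dropped.
#'
#' @param rm a [ReportMatrix-class].
#' @param ae target AE column (code or index).
#' @param minCoreports,minTotal non-negative thresholds; defaults 3 and 10.
#' @return the [ReportMatrix-class] restricted to eligible drug columns
#'   (original order preserved).  If no drug qualifies, an error of class
#'   `pvsignal_no_eligible_drugs` is signalled.
#' @export
filterEligibleDrugs <- function(rm, ae, minCoreports = 3, minTotal = 10) {
  stopifnot(minCoreports >= 0, minTotal >= 0)
  j <- .aeColumn(rm, ae)
  X <- exposures(rm)
  y <- events(rm)[, j]
  nTotal <- Matrix::colSums(X)
  nCo <- as.numeric(Matrix::crossprod(X, y))
  keep <- nCo > minCoreports & nTotal > minTotal
  if (!any(keep))
    stop(structure(class = c("pvsignal_no_eligible_drugs", "error", "condition"),
                   list(message = "no drug passes the eligibility thresholds",
                        call = sys.call())))
  ReportMatrix(X[, keep, drop = FALSE], events(rm), reportIds = reportIds(rm))
}

#' Collapse a group of adverse-event columns into one composite outcome
#'
#' A report is counted as presenting the composite event if it carries any
#' member code (logical OR), so each report contributes at most once to the
#' composite margin.  Member columns are removed; the composite is appended.
#'
#' @param rm a [ReportMatrix-class].
#' @param members AE codes forming the group.
#' @param groupId name for the composite column.
#' @return a [ReportMatrix-class].
#' @export
collapseAeGroup <- function(rm, members, groupId = "composite") {
  Y <- events(rm)
  if (!all(members %in% colnames(Y)))
    stop("unknown AE code(s): ", paste(setdiff(members, colnames(Y)), collapse = ", "))
  comp <- as.numeric(Matrix::rowSums(Y[, members, drop = FALSE]) > 0)
  keep <- setdiff(colnames(Y), members)
  Ynew <- cbind(Y[, keep, drop = FALSE],
                Matrix::Matrix(comp, ncol = 1, sparse = TRUE,
                               dimnames = list(rownames(Y), groupId)))
  ReportMatrix(exposures(rm), Ynew, reportIds = reportIds(rm))
}

#' Observed and expected co-report counts for one (drug, AE) pair
#'
#' The expected count under independence of drug and event reporting is
#' `e = N_i * N_j / N`, the classical disproportionality baseline.
#'
#' @param rm a [ReportMatrix-class].
#' @param drug,ae column code or index.
#' @return data frame with one row: observed co-report count `n`, drug
#'   margin `N_i`, event margin `N_j`, database size `N`, expected count `e`.
#' @examples
#' ## N_i = 100, N_j = 50, N = 1000 gives e = 5
#' @export
pairCounts <- function(rm, drug, ae) {
  i <- .drugColumn(rm, drug)
  j <- .aeColumn(rm, ae)
  x <- exposures(rm)[, i]
  y <- events(rm)[, j]
  N <- nReports(rm)
  if (N == 0L) stop("empty database")
  data.frame(drug = drugIds(rm)[i], ae = aeIds(rm)[j],
             n = sum(x * y), N_i = sum(x), N_j = sum(y), N = N,
             e = sum(x) * sum(y) / N)
}
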