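#' Accessors for pvsignal classes
#'
#' Small accessor generics: `exposures()` and `events()` return the sparse
#' indicator matrices of a [ReportMatrix-class]; `drugIds()`, `aeIds()` and
#' `reportIds()` the vocabularies; `nReports()`, `nDrugs()`, `nEvents()` the
#' dimensions; `psScores()`, `psMethod()` and `covariatesUsed()` the content
#' of a [PropensityScore-class]; `selectedCovariates()` the covariates kept
#' by a [CislResult-class] at a given quantile.
#'
#' @param object a pvsignal object.
#' @param ... passed to methods.
#' @return the corresponding slot content (see above).
#' @name accessors
#' @aliases exposures events drugIds aeIds reportIds nReports nDrugs nEvents
#'   psScores psMethod covariatesUsed selectedCovariates
NULL

#' @rdname accessors
#' @export
setGeneric("exposures", function(object) standardGeneric("exposures"))
#' @rdname accessors
#' @export
setGeneric("events", function(object) standardGeneric("events"))
#' @rdname accessors
#' @export
setGeneric("drugIds", function(object) standardGeneric("drugIds"))
#' @rdname accessors
#' @export
setGeneric("aeIds", function(object) standardGeneric("aeIds"))
#' @rdname accessors
#' @export
setGeneric("reportIds", function(object) standardGeneric("reportIds"))
#' @rdname accessors
#' @export
setGeneric("nReports", function(object) standardGeneric("nReports"))
#' @rdname accessors
#' @export
setGeneric("nDrugs", function(object) standardGeneric("nDrugs"))
#' @rdname accessors
#' @export
setGeneric("nEvents", function(object) standardGeneric("nEvents"))
#' @rdname accessors
#' @export
setGeneric("psScores", function(object) standardGeneric("psScores"))
#' @rdname accessors
#' @export
setGeneric("psMethod", function(object) standardGeneric("psMethod"))
#' @rdname accessors
#' @export
setGeneric("covariatesUsed", function(object) standardGeneric("covariatesUsed"))
#' @rdname accessors
#' @export
setGeneric("selectedCovariates", function(object, ...) standardGeneric("selectedCovariates"))

#' @rdname accessors
setMethod("exposures", "ReportMatrix", function(object) object@exposures)
#' @rdname accessors
setMethod("events", "ReportMatrix", function(object) object@events)
#' @rdname accessors
setMethod("drugIds", "ReportMatrix", function(object) colnames(object@exposures))
#' @rdname accessors
setMethod("aeIds", "ReportMatrix", function(object) colnames(object@events))
#' @rdname accessors
setMethod("reportIds", "ReportMatrix", function(object) rownames(object@exposures))
#' @rdname accessors
setMethod("nReports", "ReportMatrix", function(object) nrow(object@exposures))
#' @rdname accessors
setMethod("nDrugs", "ReportMatrix", function(object) ncol(object@exposures))
#' @rdname accessors
setMethod("nEvents", "ReportMatrix", function(object) ncol(object@events))

#' @rdname accessors
setMethod("psScores", "PropensityScore", function(object) object@scores)
#' @rdname accessors
setMethod("psMethod", "PropensityScore", function(object) object@method)
#' @rdname accessors
setMethod("covariatesUsed", "PropensityScore", function(object) object@covariatesUsed)

setMethod("show", "ReportMatrix", function(object) {
  cat("ReportMatrix:", nReports(object), "reports,",
      nDrugs(object), "drugs,", nEvents(object), "adverse events\n")
  cat("  exposure density:",
      signif(length(object@exposures@x) / prod(dim(object@exposures)), 3),
      " event density:",
      signif(length(object@events@x) / prod(dim(object@events)), 3), "\n")
})

setMethod("show", "LassoPath", function(object) {
  sizes <- Matrix::colSums(object@beta != 0)
  cat("LassoPath:", length(object@lambda), "penalties, lambda in [",
      signif(min(object@lambda), 3), ",", signif(max(object@lambda), 3),
      "], active-set sizes", min(sizes), "-", max(sizes), "\n")
})

setMethod("show", "CislResult", function(object) {
  cat("CislResult:", nrow(object@piHat), "covariates x", ncol(object@piHat),
      "subsamples; E =", object@E,
      "; constraint =", object@signConstraint, "\n")
  cat("  selected at q=0.05:", length(selectedCovariates(object, 0.05)),
      " at q=0.10:", length(selectedCovariates(object, 0.10)), "\n")
})

setMethod("show", "PropensityScore", function(object) {
  cat("PropensityScore for", object@drug, "(", object@method, ")\n")
  cat("  ", length(object@scores), "reports; mean score",
      signif(mean(object@scores), 4), ";",
      if (object@method == "GTB") "all co-reported drugs"
      else paste(length(object@covariatesUsed), "covariates"),
      if (object@aeDependent) "; AE-dependent" else "", "\n")
})

setMethod("show", "SimulatedDatabase", function(object) {
  cat("SimulatedDatabase:", nReports(object@rm), "reports,",
      nDrugs(object@rm), "drugs;",
      sum(object@truth$label == "true_signal"), "true signals,",
      sum(object@truth$label == "confounded_null"), "confounded nulls\n")
})
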