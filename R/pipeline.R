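## End-to-end orchestration: simulate/load -> filter -> detect -> evaluate.

.psStrategies <- c(adjust = "adjust", mw = "mw", iptw = "iptw")

#' Parse a method name into a detector specification
#'
#' Recognized names: `"univ"`, `"bic-lasso"`, `"cisl-5"`, `"cisl-10"` and
#' the PS grid `"adjustPS-X"`, `"mwPS-X"`, `"iptwPS-X"` with `X` one of
#' `BIC`, `CISL`, `hdPS`, `GTB`.
#'
#' @param name method name string.
#' @return list with `kind` and, for PS methods, `strategy` and `psMethod`.
#' @export
parseMethodName <- function(name) {
  if (name %in% c("univ", "bic-lasso", "cisl-5", "cisl-10"))
    return(list(kind = name))
  m <- regmatches(name, regexec("^(adjust|mw|iptw)PS-(BIC|CISL|hdPS|GTB)$", name))[[1]]
  if (!length(m))
    stop("unknown method name: '", name, "'; see ?parseMethodName")
  list(kind = "ps", strategy = m[2], psMethod = m[3])
}

#' Run the full signal-detection pipeline
#'
#' Applies the eligibility filter to the database, runs every requested
#' detector against the target AE (sharing one PS estimation pass per
#' AE-independent PS method across the adjust/iptw/mw strategies), and, if
#' a reference set is available, scores each signal table.
#'
#' @param rm a [ReportMatrix-class], or a [SimulatedDatabase-class] (whose
#'   truth then provides the reference set unless `reference` is given).
#' @param ae target AE column; defaults to the first event column.
#' @param methods character vector of method names (see
#'   [parseMethodName()]).
#' @param fdrLevel FDR threshold for the test-based detectors.
#' @param minCoreports,minTotal eligibility thresholds
#'   ([filterEligibleDrugs()]).
#' @param reference optional reference data frame.
#' @param seed base seed for the stochastic components (CISL subsampling,
#'   GTB).
#' @param cislB subsamples for CISL-based detectors and PS estimation.
#' @param outDir optional directory; when given, one signal TSV per method
#'   plus `performance.tsv` and a plain-text run manifest are written.
#' @param verbose print per-method progress.
#' @return list with `signals` (named list of signal tables),
#'   `performance` (combined data frame, `NULL` without a reference),
#'   `eligible` (the filtered [ReportMatrix-class]) and `manifest`.
#' @export
runPipeline <- function(rm, ae = NULL,
                        methods = c("univ", "bic-lasso", "cisl-10", "mwPS-BIC"),
                        fdrLevel = 0.05, minCoreports = 3, minTotal = 10,
                        reference = NULL, seed = 1L, cislB = 100,
                        outDir = NULL, verbose = FALSE) {
  if (is(rm, "SimulatedDatabase")) {
    if (is.null(reference)) reference <- referenceFromTruth(rm)
    rm <- rm@rm
  }
  stopifnot(is(rm, "ReportMatrix"))
  if (is.null(ae)) ae <- aeIds(rm)[1]
  specs <- lapply(methods, parseMethodName)

  elig <- filterEligibleDrugs(rm, ae, minCoreports, minTotal)
  caches <- new.env(parent = emptyenv())
  signals <- list()
  for (k in seq_along(specs)) {
    sp <- specs[[k]]
    if (verbose) message("running ", methods[k], " ...")
    signals[[methods[k]]] <- switch(sp$kind,
      univ = univariateDetector(elig, ae, fdrLevel),
      `bic-lasso` = bicLassoDetector(elig, ae),
      `cisl-5` = cislDetector(elig, ae, quantile = 0.05, B = cislB, seed = seed),
      `cisl-10` = cislDetector(elig, ae, quantile = 0.10, B = cislB, seed = seed),
      ps = {
        cacheName <- paste0("ps_", sp$psMethod)
        if (is.null(caches[[cacheName]]))
          caches[[cacheName]] <- new.env(parent = emptyenv())
        extra <- switch(sp$psMethod,
                        CISL = list(B = cislB, seed = seed),
                        GTB = list(seed = seed), list())
        do.call(psDetector,
                c(list(elig, ae, psMethod = sp$psMethod,
                       strategy = sp$strategy, fdrLevel = fdrLevel,
                       psCache = caches[[cacheName]]), extra))
      })
  }

  performance <- NULL
  if (!is.null(reference)) {
    performance <- do.call(rbind, lapply(signals, evaluateSignals, ref = reference))
    rownames(performance) <- NULL
  }
  manifest <- c(
    sprintf("pvsignal run: %d reports, %d eligible of %d drugs, AE = %s",
            nReports(elig), nDrugs(elig), nDrugs(rm),
            if (is.character(ae)) ae else aeIds(rm)[ae]),
    sprintf("methods: %s", paste(methods, collapse = ", ")),
    sprintf("fdrLevel = %g; minCoreports = %g; minTotal = %g; seed = %d; cislB = %d",
            fdrLevel, minCoreports, minTotal, as.integer(seed), as.integer(cislB)))

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(signals))
      writeSignalTable(signals[[nm]], file.path(outDir, paste0("signals_", nm, ".tsv")))
    if (!is.null(performance)) {
      perf <- performance
      perf[c("ppv", "sensitivity", "specificity", "fdp")] <-
        round(perf[c("ppv", "sensitivity", "specificity", "fdp")], 2)
      utils::write.table(perf, file.path(outDir, "performance.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    writeLines(manifest, file.path(outDir, "manifest.txt"))
  }
  list(signals = signals, performance = performance, eligible = elig,
       manifest = manifest)
}
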