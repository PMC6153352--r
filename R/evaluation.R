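## Scoring signal tables against a reference set: performance metrics,
## ranked-detection curves, observed-vs-expected counts.

.refLabels <- function(signals, ref) {
  key <- paste(signals$drug, signals$ae, sep = "\r")
  refKey <- paste(ref$drug, ref$ae, sep = "\r")
  lab <- ref$label[match(key, refKey)]
  lab[is.na(lab)] <- "unknown"
  lab
}

#' Score a signal table against a reference set
#'
#' Declared signals whose (drug, AE) pair is a positive control count as
#' true positives, negative controls as false positives; pairs of unknown
#' status contribute only to the number of generated signals.  Reported
#' percentages: PPV = 100 tp / known, FDP = 100 fp / known (so PPV + FDP =
#' 100 exactly), sensitivity = 100 tp / n_positive, specificity =
#' 100 (n_negative - fp) / n_negative.  With zero known-status signals PPV
#' and FDP are `NA`.
#'
#' @param signals a signal table (any detector).
#' @param ref reference data frame (`drug`, `ae`, `label`), e.g. from
#'   [readReferenceSet()] or [referenceFromTruth()].
#' @return one-row data frame: `method`, `n_generated`, `n_known`, `tp`,
#'   `fp`, `ppv`, `sensitivity`, `specificity`, `fdp` (percentages at full
#'   precision; round for display).
#' @export
evaluateSignals <- function(signals, ref) {
  ref <- validateReferenceSet(ref)
  nPos <- sum(ref$label == "positive")
  nNeg <- sum(ref$label == "negative")
  if (nPos < 1 || nNeg < 1)
    stop("reference set needs at least one positive and one negative control")
  if (!length(intersect(signals$drug, ref$drug)))
    stop("reference set and signal table share no drug codes")
  dec <- signals[signals$signal, , drop = FALSE]
  lab <- .refLabels(dec, ref)
  tp <- sum(lab == "positive")
  fp <- sum(lab == "negative")
  known <- tp + fp
  data.frame(
    method = if (nrow(signals)) signals$method[1] else NA_character_,
    n_generated = nrow(dec), n_known = known, tp = tp, fp = fp,
    ppv = if (known) 100 * tp / known else NA_real_,
    sensitivity = 100 * tp / nPos,
    specificity = 100 * (nNeg - fp) / nNeg,
    fdp = if (known) 100 * fp / known else NA_real_)
}

#' Cumulative ranked-detection curve
#'
#' Orders declared signals by a ranking score in ascending order (adjusted
#' p-value when available, otherwise the raw p-value; selection-only tables
#' such as CISL fall back to the estimate in descending order, with a
#' warning).  Ties are broken by descending estimate then drug code for
#' reproducibility.  Returns cumulative true/false-positive counts at
#' every rank.
#'
#' @param signals a signal table.
#' @param ref reference data frame.
#' @return data frame with columns `rank`, `drug`, `ae`, `score`,
#'   `cum_tp`, `cum_fp`; `cum_tp` and `cum_fp` are non-decreasing.
#' @export
rankedDetectionCurve <- function(signals, ref) {
  ref <- validateReferenceSet(ref)
  dec <- signals[signals$signal, , drop = FALSE]
  if (!nrow(dec))
    return(data.frame(rank = integer(), drug = character(), ae = character(),
                      score = numeric(), cum_tp = integer(), cum_fp = integer()))
  score <- if (any(!is.na(dec$p_fdr))) dec$p_fdr
           else if (any(!is.na(dec$p))) dec$p
           else {
             warning("no p-values in signal table; ranking by estimate only")
             -dec$estimate
           }
  ord <- order(score, -dec$estimate, dec$drug)
  dec <- dec[ord, , drop = FALSE]
  lab <- .refLabels(dec, ref)
  data.frame(rank = seq_len(nrow(dec)), drug = dec$drug, ae = dec$ae,
             score = score[ord],
             cum_tp = cumsum(lab == "positive"),
             cum_fp = cumsum(lab == "negative"))
}

#' Observed vs expected counts of declared signals
#'
#' Joins the co-report counts of [pairCounts()] onto the declared signals:
#' `n` observed reports involving the pair, `e = N_i N_j / N` expected
#' under independence, and the observed risk ratio `n / e`.
#'
#' @param signals a signal table.
#' @param rm the [ReportMatrix-class] the signals were computed from.
#' @return data frame with one row per declared signal.
#' @export
observedExpectedTable <- function(signals, rm) {
  dec <- signals[signals$signal, , drop = FALSE]
  if (!nrow(dec))
    return(data.frame(drug = character(), ae = character(), n = numeric(),
                      e = numeric(), ratio = numeric()))
  out <- do.call(rbind, lapply(seq_len(nrow(dec)), function(k)
    pairCounts(rm, dec$drug[k], dec$ae[k])))
  out$ratio <- out$n / out$e
  out[c("drug", "ae", "n", "e", "ratio")]
}

#' Overlap of top-ranked signal sets across detectors
#'
#' Exact set intersections of the first `k` declared signals (by the
#' ranking of [rankedDetectionCurve()]) of several detectors.
#'
#' @param signalsList named list of signal tables.
#' @param ref reference data frame (used only for ranking order).
#' @param k number of top signals per detector (default: smallest declared
#'   count).
#' @return named list: per-detector top-k pair keys, plus `common`, the
#'   intersection across all detectors.
#' @export
signalOverlap <- function(signalsList, ref, k = NULL) {
  tops <- lapply(signalsList, function(s) {
    cv <- rankedDetectionCurve(s, ref)
    paste(cv$drug, cv$ae, sep = " / ")
  })
  if (is.null(k)) k <- min(lengths(tops))
  tops <- lapply(tops, utils::head, k)
  c(tops, list(common = Reduce(intersect, tops)))
}
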