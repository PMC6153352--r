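## One-sided multiple testing: Benjamini-Hochberg adjustment and the
## signal decision rule.

#' FDR-adjust one-sided p-values
#'
#' Benjamini-Hochberg step-up adjusted p-values (monotonicity enforced)
#' applied to the one-sided p-values of the association tests.  `NA`
#' entries (failed fits) pass through as `NA` and are excluded from the
#' number of tests `m`.
#'
#' @param p numeric vector of p-values in \[0, 1\], `NA` allowed.
#' @return adjusted p-values, same length and order as `p`.
#' @examples
#' fdrAdjust(c(0.01, 0.02, 0.03))  # 0.03 0.03 0.03
#' @export
fdrAdjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0,1]")
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Declare signals at an FDR level
#'
#' Flags as signals the rows whose FDR-adjusted p-value is at most
#' `fdrLevel` (the Benjamini-Hochberg rejection rule).  Rows with `NA`
#' adjusted p-values are never signals; their count is reported in the
#' summary message.
#'
#' @param table a signal table (data frame with columns `p_fdr` at least).
#' @param fdrLevel target false discovery rate in (0, 1\]; default 0.05.
#' @param quiet suppress the summary message.
#' @return the table with its `signal` column set.
#' @export
declareSignals <- function(table, fdrLevel = 0.05, quiet = TRUE) {
  stopifnot(fdrLevel > 0, fdrLevel <= 1)
  table$signal <- !is.na(table$p_fdr) & table$p_fdr <= fdrLevel
  if (!quiet)
    message(sum(table$signal), " signal(s) at FDR ", fdrLevel, "; ",
            sum(is.na(table$p_fdr)), " pair(s) with failed fits excluded")
  table
}

## Canonical signal-table construction from association-test rows.
.signalTable <- function(rows, method, fdrLevel = 0.05, adjust = TRUE) {
  tbl <- do.call(rbind, rows)
  tbl$method <- method
  tbl$p_fdr <- if (adjust) fdrAdjust(tbl$p) else NA_real_
  tbl <- tbl[order(tbl$drug, tbl$ae), ]
  rownames(tbl) <- NULL
  if (adjust) tbl <- declareSignals(tbl, fdrLevel) else tbl$signal <- FALSE
  tbl[c("drug", "ae", "method", "strategy", "estimate", "se", "z",
        "p", "p_fdr", "signal", "note")]
}

#' Write a signal table
#'
#' Tab-separated with header
#' `drug ae method strategy estimate p p_fdr signal` and deterministic
#' (drug, ae, method) row order.
#'
#' @param table a signal table.
#' @param path output file.
#' @export
writeSignalTable <- function(table, path) {
  out <- table[order(table$drug, table$ae, table$method),
               c("drug", "ae", "method", "strategy", "estimate", "p",
                 "p_fdr", "signal")]
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
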