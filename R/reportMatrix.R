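## Constructors and I/O for ReportMatrix and reference sets.

.asBinarySparse <- function(m) {
  m <- as(as(as(m, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (length(m@x)) {
    if (any(!m@x %in% c(0, 1))) stop("matrix entries must be 0/1")
    m <- Matrix::drop0(m)
  }
  m
}

#' Assemble a ReportMatrix from sparse components
#'
#' @param X,Y binary matrices (dense or sparse) of drug exposures and
#'   adverse events, one row per report; column names are the vocabularies.
#' @param reportIds optional report identifiers (defaults to existing row
#'   names or `R1..RN`).
#' @return a [ReportMatrix-class].
#' @export
ReportMatrix <- function(X, Y, reportIds = NULL) {
  X <- .asBinarySparse(X)
  Y <- .asBinarySparse(Y)
  if (is.null(reportIds))
    reportIds <- if (!is.null(rownames(X))) rownames(X) else paste0("R", seq_len(nrow(X)))
  rownames(X) <- rownames(Y) <- reportIds
  new("ReportMatrix", exposures = X, events = Y)
}

#' Build a ReportMatrix from long-format (report, code, kind) triples
#'
#' The canonical interchange form: one row per reported drug or adverse
#' event.  Duplicated triples collapse to a single indicator; rows and
#' columns are ordered by sorted report id and sorted code.
#'
#' @param records data frame with columns `report_id`, `code`, `kind`
#'   (`"drug"` or `"ae"`).
#' @return a [ReportMatrix-class].
#' @examples
#' recs <- data.frame(report_id = c("r1", "r1", "r2"),
#'                    code = c("A", "e1", "A"),
#'                    kind = c("drug", "ae", "drug"))
#' buildReportMatrix(recs)
#' @export
buildReportMatrix <- function(records) {
  need <- c("report_id", "code", "kind")
  if (!all(need %in% names(records)))
    stop("records must have columns report_id, code, kind")
  records <- as.data.frame(records)[need]
  records[] <- lapply(records, as.character)
  if (any(!nzchar(records$code)) || anyNA(records$code))
    stop("codes must be non-empty strings")
  bad <- which(!records$kind %in% c("drug", "ae"))
  if (length(bad))
    stop("unknown kind '", records$kind[bad[1]], "' in record row ", bad[1])
  if (!any(records$kind == "drug") || !any(records$kind == "ae"))
    stop("need at least one drug and one AE record")

  reps <- sort(unique(records$report_id))
  onePart <- function(kind) {
    part <- unique(records[records$kind == kind, c("report_id", "code")])
    codes <- sort(unique(part$code))
    Matrix::sparseMatrix(
      i = match(part$report_id, reps), j = match(part$code, codes),
      x = 1, dims = c(length(reps), length(codes)),
      dimnames = list(reps, codes))
  }
  ReportMatrix(onePart("drug"), onePart("ae"), reportIds = reps)
}

#' Read / write report databases
#'
#' Two on-disk dialects are supported.  The long CSV dialect is a single
#' UTF-8 file with header `report_id,code,kind` and one triple per line.
#' The sparse dialect is a directory holding MatrixMarket coordinate files
#' `X.mtx` (exposures) and `Y.mtx` (events) plus the label files
#' `drugs.txt`, `aes.txt` and `reports.txt` (one code per line, file order =
#' matrix order).
#'
#' @param path CSV file (`*LongCsv`) or directory (`*SparseDir`).
#' @param rm a [ReportMatrix-class] to write.
#' @return readers return a [ReportMatrix-class]; writers return `path`
#'   invisibly.
#' @name report-io
NULL

#' @rdname report-io
#' @export
readLongCsv <- function(path) {
  buildReportMatrix(utils::read.csv(path, colClasses = "character"))
}

#' @rdname report-io
#' @export
writeLongCsv <- function(rm, path) {
  X <- exposures(rm); Y <- events(rm)
  longOf <- function(m, kind) {
    s <- Matrix::summary(m)
    data.frame(report_id = rownames(m)[s$i], code = colnames(m)[s$j], kind = kind)
  }
  out <- rbind(longOf(X, "drug"), longOf(Y, "ae"))
  out <- out[order(out$report_id, out$kind, out$code), ]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname report-io
#' @export
readSparseDir <- function(path) {
  rd <- function(f) readLines(file.path(path, f))
  X <- as(Matrix::readMM(file.path(path, "X.mtx")), "CsparseMatrix")
  Y <- as(Matrix::readMM(file.path(path, "Y.mtx")), "CsparseMatrix")
  reps <- rd("reports.txt")
  dimnames(X) <- list(reps, rd("drugs.txt"))
  dimnames(Y) <- list(reps, rd("aes.txt"))
  ReportMatrix(X, Y, reportIds = reps)
}

#' @rdname report-io
#' @export
writeSparseDir <- function(rm, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(exposures(rm), file.path(path, "X.mtx"))
  Matrix::writeMM(events(rm), file.path(path, "Y.mtx"))
  writeLines(drugIds(rm), file.path(path, "drugs.txt"))
  writeLines(aeIds(rm), file.path(path, "aes.txt"))
  writeLines(reportIds(rm), file.path(path, "reports.txt"))
  invisible(path)
}

#' Read / write a reference signal set
#'
#' Tab-separated file with columns `drug`, `ae`, `label`; labels are
#' `positive`, `negative` or `unknown`.  Pairs not listed are implicitly of
#' unknown status.
#'
#' @param path TSV file path.
#' @param ref data frame with columns `drug`, `ae`, `label`.
#' @return `readReferenceSet` returns the validated data frame.
#' @name reference-io
NULL

#' @rdname reference-io
#' @export
readReferenceSet <- function(path) {
  ref <- utils::read.delim(path, colClasses = "character")
  validateReferenceSet(ref)
}

#' @rdname reference-io
#' @export
writeReferenceSet <- function(ref, path) {
  utils::write.table(validateReferenceSet(ref), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname reference-io
#' @export
validateReferenceSet <- function(ref) {
  if (!all(c("drug", "ae", "label") %in% names(ref)))
    stop("reference set needs columns drug, ae, label")
  if (!all(ref$label %in% c("positive", "negative", "unknown")))
    stop("reference labels must be positive/negative/unknown")
  if (anyDuplicated(ref[c("drug", "ae")]))
    stop("duplicated (drug, ae) pair in reference set")
  as.data.frame(ref)
}
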