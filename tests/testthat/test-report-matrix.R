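test_that("long-format triples build the expected indicator matrices", {
  recs <- data.frame(report_id = c("r1", "r1", "r2"),
                     code = c("A", "e1", "A"),
                     kind = c("drug", "ae", "drug"))
  rm <- buildReportMatrix(recs)
  expect_equal(as.matrix(exposures(rm)), matrix(c(1, 1), 2, 1,
               dimnames = list(c("r1", "r2"), "A")))
  expect_equal(as.matrix(events(rm)), matrix(c(1, 0), 2, 1,
               dimnames = list(c("r1", "r2"), "e1")))

  ## duplicated triples are idempotent
  rm2 <- buildReportMatrix(rbind(recs, recs[1, ]))
  expect_identical(as.matrix(exposures(rm2)), as.matrix(exposures(rm)))

  ## random triples agree with brute-force set membership
  recs <- randomRecords(10, seed = 42)
  rm3 <- buildReportMatrix(recs)
  for (r in reportIds(rm3)) {
    for (g in drugIds(rm3))
      expect_equal(exposures(rm3)[r, g],
                   as.numeric(any(recs$report_id == r & recs$code == g &
                                  recs$kind == "drug")))
    for (e in aeIds(rm3))
      expect_equal(events(rm3)[r, e],
                   as.numeric(any(recs$report_id == r & recs$code == e &
                                  recs$kind == "ae")))
  }
})

test_that("malformed records are rejected with a pointer to the row", {
  recs <- data.frame(report_id = c("r1", "r2"), code = c("A", "e1"),
                     kind = c("drug", "event"))
  expect_error(buildReportMatrix(recs), "unknown kind 'event'.*row 2")
  expect_error(buildReportMatrix(data.frame(report_id = "r1", code = "A",
                                            kind = "drug")),
               "at least one drug and one AE")
})

test_that("databases round-trip through both on-disk dialects", {
  rm <- buildReportMatrix(randomRecords(14, seed = 3))
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLongCsv(rm, csv)
  back <- readLongCsv(csv)
  expect_equal(as.matrix(exposures(back)), as.matrix(exposures(rm)))
  expect_equal(as.matrix(events(back)), as.matrix(events(rm)))

  dir <- withr::local_tempdir()
  writeSparseDir(rm, dir)
  back2 <- readSparseDir(dir)
  expect_equal(as.matrix(exposures(back2)), as.matrix(exposures(rm)))
  expect_equal(as.matrix(events(back2)), as.matrix(events(rm)))

  ref <- data.frame(drug = c("A", "B"), ae = "e1",
                    label = c("positive", "negative"))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeReferenceSet(ref, tsv)
  expect_equal(readReferenceSet(tsv), ref)
  expect_error(validateReferenceSet(data.frame(drug = "A", ae = "e",
                                               label = "maybe")),
               "positive/negative/unknown")
})

test_that("eligibility filter applies strict thresholds in both margins", {
  ## drug E3 has exactly 3 co-reports (excluded), E4 has 4 co-reports and
  ## 11 total (retained)
  n <- 40
  y <- rep(c(1, 0), c(10, 30))
  X <- cbind(E3 = rep(c(1, 0, 1, 0), c(3, 7, 9, 21)),
             E4 = rep(c(1, 0, 1, 0), c(4, 6, 7, 23)))
  rm <- ReportMatrix(X, matrix(y, ncol = 1, dimnames = list(NULL, "AE")))
  kept <- filterEligibleDrugs(rm, "AE")
  expect_identical(drugIds(kept), "E4")
  expect_equal(sum(exposures(rm)[, "E4"]), 11)

  ## nothing eligible is an explicit condition, not a crash
  expect_error(filterEligibleDrugs(rm, "AE", minCoreports = 100),
               class = "pvsignal_no_eligible_drugs")
})

test_that("eligibility filter matches a brute-force scan and is monotone", {
  set.seed(8)
  X <- matrix(rbinom(300 * 50, 1, 0.08), 300, 50,
              dimnames = list(NULL, sprintf("D%02d", 1:50)))
  y <- rbinom(300, 1, 0.3)
  rm <- ReportMatrix(X, matrix(y, ncol = 1, dimnames = list(NULL, "AE")))
  kept <- tryCatch(drugIds(filterEligibleDrugs(rm, "AE", 3, 10)),
                   error = function(e) character())
  brute <- colnames(X)[vapply(seq_len(50), function(i) {
    co <- sum(X[, i] == 1 & y == 1)
    sum(X[, i]) > 10 && co > 3
  }, logical(1))]
  expect_identical(kept, brute)

  ## raising either threshold never adds a drug
  for (th in list(c(4, 10), c(3, 15), c(6, 20))) {
    kept2 <- tryCatch(drugIds(filterEligibleDrugs(rm, "AE", th[1], th[2])),
                      error = function(e) character())
    expect_true(all(kept2 %in% kept))
  }
})

test_that("pair counts match the independence formula and brute force", {
  ## engineered margins: N_i = 100, N_j = 50, N = 1000 -> e = 5
  set.seed(5)
  x <- sample(rep(c(1, 0), c(100, 900)))
  y <- sample(rep(c(1, 0), c(50, 950)))
  rm <- ReportMatrix(cbind(D = x, F2 = 0:1),
                     matrix(y, ncol = 1, dimnames = list(NULL, "AE")))
  pc <- pairCounts(rm, "D", "AE")
  expect_equal(pc$e, 5.0)
  expect_equal(pc$N_i, 100)
  expect_equal(pc$N_j, 50)

  ## degenerate full overlap: n = N_i = N_j = N and e = N
  rmAll <- ReportMatrix(matrix(1, 6, 1, dimnames = list(NULL, "D")),
                        matrix(1, 6, 1, dimnames = list(NULL, "AE")))
  pcAll <- pairCounts(rmAll, "D", "AE")
  expect_equal(unlist(pcAll[c("n", "N_i", "N_j", "N", "e")]),
               c(n = 6, N_i = 6, N_j = 6, N = 6, e = 6))

  ## random matrix vs explicit row iteration; n <= min(N_i, N_j) always
  set.seed(11)
  X <- matrix(rbinom(200 * 5, 1, 0.2), 200, 5,
              dimnames = list(NULL, paste0("D", 1:5)))
  Y <- matrix(rbinom(200 * 2, 1, 0.3), 200, 2,
              dimnames = list(NULL, paste0("A", 1:2)))
  rm2 <- ReportMatrix(X, Y)
  for (g in colnames(X)) for (e in colnames(Y)) {
    pc <- pairCounts(rm2, g, e)
    nBrute <- 0
    for (r in seq_len(200)) nBrute <- nBrute + (X[r, g] == 1 && Y[r, e] == 1)
    expect_equal(pc$n, nBrute)
    expect_equal(pc$e, sum(X[, g]) * sum(Y[, e]) / 200)
    expect_lte(pc$n, min(pc$N_i, pc$N_j))
    expect_lte(min(pc$N_i, pc$N_j), pc$N)
  }
})

test_that("AE group collapse counts each report once", {
  Y <- cbind(a1 = c(1, 1, 0, 0), a2 = c(1, 0, 0, 0), other = c(0, 0, 1, 0))
  rm <- ReportMatrix(matrix(c(1, 0, 1, 0), ncol = 1,
                            dimnames = list(NULL, "D")), Y)
  out <- collapseAeGroup(rm, c("a1", "a2"), "grp")
  expect_identical(aeIds(out), c("other", "grp"))
  ## report 1 carries both member codes but contributes once
  expect_equal(as.numeric(events(out)[, "grp"]), c(1, 1, 0, 0))
  expect_error(collapseAeGroup(rm, "missing"), "unknown AE")
})
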