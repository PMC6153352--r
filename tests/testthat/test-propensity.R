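indepSim <- function(seed, n = 4000, I = 15) {
  simulateReports(simConfig(nReports = n, nDrugs = I, nBlocks = 2,
                            nTrueSignals = 0, nConfoundedNulls = 0,
                            drugPrevalenceRange = c(0.1, 0.3), seed = seed))
}

## exposure driven by three known drugs on top of noise columns
drivenExposure <- function(seed, n = 4000, I = 12) {
  set.seed(seed)
  X <- matrix(rbinom(n * I, 1, 0.25), n, I,
              dimnames = list(NULL, sprintf("D%02d", 1:I)))
  drivers <- c("D01", "D02", "D03")
  x <- rbinom(n, 1, plogis(-2.2 + 1.6 * rowSums(X[, drivers])))
  Xall <- cbind(TARGET = x, X)
  rm <- ReportMatrix(Xall, matrix(rbinom(n, 1, 0.1), ncol = 1,
                                  dimnames = list(NULL, "AE")))
  list(rm = rm, drivers = drivers)
}

test_that("with no exposure predictors the PS collapses to the prevalence", {
  db <- indepSim(1)
  g <- drugIds(db@rm)[1]
  ps <- psBic(db@rm, g)
  prev <- mean(exposures(db@rm)[, g])
  expect_length(covariatesUsed(ps), 0)
  expect_equal(mean(psScores(ps)), prev, tolerance = 0.01)
  expect_lt(sd(psScores(ps)), 1e-8)
  expect_false(ps@aeDependent)
})

test_that("BIC and CISL propensity models find the exposure drivers", {
  bicHits <- cislHits <- 0L
  for (sd in 1:5) {
    d <- drivenExposure(sd)
    if (all(d$drivers %in% covariatesUsed(psBic(d$rm, "TARGET"))))
      bicHits <- bicHits + 1L
    ps <- psCisl(d$rm, "TARGET", B = 30, seed = sd)
    if (all(d$drivers %in% covariatesUsed(ps))) cislHits <- cislHits + 1L
  }
  expect_gte(bicHits, 4L)
  expect_gte(cislHits, 4L)
})

test_that("PS scores are the inverse-logit of the refit linear predictor", {
  d <- drivenExposure(7)
  ps <- psBic(d$rm, "TARGET")
  sel <- covariatesUsed(ps)
  ## recompute by hand on five reports from the refit coefficients
  co <- coef(glm(reformulate(sprintf("`%s`", sel), "x"),
                 data = data.frame(x = as.numeric(exposures(d$rm)[, "TARGET"]),
                                   as.matrix(exposures(d$rm)[, sel])),
                 family = binomial()))
  for (r in 1:5) {
    eta <- co[1] + sum(co[-1] * exposures(d$rm)[r, sel])
    expect_equal(psScores(ps)[r], unname(plogis(eta)), tolerance = 1e-5)
  }
})

test_that("degenerate exposures are refused", {
  rm <- ReportMatrix(cbind(A = rep(1, 20), B = rbinom(20, 1, 0.5)),
                     matrix(rbinom(20, 1, 0.3), ncol = 1,
                            dimnames = list(NULL, "AE")))
  expect_error(psBic(rm, "A"), "degenerate exposure")
})

test_that("an empty CISL selection falls back to an intercept-only PS", {
  ## companion drugs that are never reported cannot enter any lasso model,
  ## so the selection is empty by construction
  set.seed(3)
  n <- 500
  X <- cbind(TARGET = rbinom(n, 1, 0.3), Z1 = 0, Z2 = 0, Z3 = 0)
  rm <- ReportMatrix(X, matrix(rbinom(n, 1, 0.2), ncol = 1,
                               dimnames = list(NULL, "AE")))
  expect_message(ps <- psCisl(rm, "TARGET", B = 20, seed = 2),
                 "intercept-only")
  expect_length(covariatesUsed(ps), 0)
  expect_equal(mean(psScores(ps)), mean(X[, "TARGET"]), tolerance = 0.01)
  expect_lt(sd(psScores(ps)), 1e-8)
})

test_that("hdPS scores vanish for balanced or outcome-unrelated candidates", {
  ## candidate BAL has identical prevalence among exposed and unexposed;
  ## candidate NUL has an outcome table with equal risks in both arms
  x <- rep(c(1, 0), each = 20)
  bal <- rep(c(1, 0, 1, 0), each = 10)
  nul <- rep(c(1, 0), times = 20)
  ## y has period 4 so both nul arms see exactly half events (rr = 1 even
  ## after the 0.1 cell correction, since a = c and b = d)
  y <- rep(c(1, 1, 0, 0), times = 10)
  rm <- ReportMatrix(cbind(EXP = x, BAL = bal, NUL = nul),
                     matrix(y, ncol = 1, dimnames = list(NULL, "AE")))
  rk <- hdpsRank(rm, "EXP", "AE")
  expect_equal(rk$score[rk$candidate == "BAL"], 0, tolerance = 1e-12)
  nulRow <- rk[rk$candidate == "NUL", ]
  expect_equal(nulRow$rr, 1, tolerance = 1e-12)
  expect_equal(nulRow$score, 0, tolerance = 1e-12)
})

test_that("hdPS top-k ranking equals exhaustive scoring of all candidates", {
  set.seed(17)
  n <- 800
  X <- cbind(EXP = rbinom(n, 1, 0.3),
             matrix(rbinom(n * 30, 1, 0.2), n, 30,
                    dimnames = list(NULL, sprintf("C%02d", 1:30))))
  y <- rbinom(n, 1, plogis(-2 + X[, "C01"] + 0.5 * X[, "EXP"]))
  rm <- ReportMatrix(X, matrix(y, ncol = 1, dimnames = list(NULL, "AE")))
  rk <- hdpsRank(rm, "EXP", "AE")
  ## brute force: per candidate, 2x2 tables computed by explicit subsetting
  brute <- sapply(sprintf("C%02d", 1:30), function(cand) {
    cvec <- X[, cand]; xv <- X[, "EXP"]
    pc1 <- mean(cvec[xv == 1]); pc0 <- mean(cvec[xv == 0])
    a <- sum(cvec == 1 & y == 1); b <- sum(cvec == 1 & y == 0)
    cc <- sum(cvec == 0 & y == 1); d <- sum(cvec == 0 & y == 0)
    rr <- ((a + 0.1) / (a + b + 0.2)) / ((cc + 0.1) / (cc + d + 0.2))
    abs(log10((pc1 * (rr - 1) + 1) / (pc0 * (rr - 1) + 1)))
  })
  bruteTop <- names(sort(brute, decreasing = TRUE))[1:20]
  expect_setequal(head(rk$candidate, 20), bruteTop)
  expect_equal(rk$score, unname(sort(brute, decreasing = TRUE)),
               tolerance = 1e-12)
  ## the full hdPS estimator flags itself as AE-dependent
  ps <- psHdps(rm, "EXP", "AE", nTop = 5)
  expect_true(ps@aeDependent)
  expect_length(covariatesUsed(ps), 5)
  expect_false("EXP" %in% covariatesUsed(ps))
})

test_that("hdPS is AE-dependent while the other estimators are not", {
  set.seed(23)
  n <- 2000
  X <- cbind(EXP = rbinom(n, 1, 0.3),
             matrix(rbinom(n * 8, 1, 0.25), n, 8,
                    dimnames = list(NULL, sprintf("C%d", 1:8))))
  Y <- cbind(AE1 = rbinom(n, 1, plogis(-2 + X[, "C1"])),
             AE2 = rbinom(n, 1, plogis(-2 + X[, "C2"])))
  rm <- ReportMatrix(X, Y)
  ## BIC and GTB scores never see the outcome, so recomputation under a
  ## different AE context is bitwise identical
  expect_identical(psScores(psBic(rm, "EXP")), psScores(psBic(rm, "EXP")))
  expect_identical(psScores(psGtb(rm, "EXP", seed = 4)),
                   psScores(psGtb(rm, "EXP", seed = 4)))
  ## the hdPS confounder ranking changes with the outcome
  r1 <- hdpsRank(rm, "EXP", "AE1")
  r2 <- hdpsRank(rm, "EXP", "AE2")
  expect_false(identical(r1$score[order(r1$candidate)],
                         r2$score[order(r2$candidate)]))
  expect_true(psHdps(rm, "EXP", "AE1", nTop = 3)@aeDependent)
})

test_that("boosted-tree scores respond to signal and stay reproducible", {
  ## single perfectly predictive covariate: scores separate the groups
  set.seed(6)
  n <- 1000
  z <- rbinom(n, 1, 0.5)
  X <- cbind(TARGET = z, DRIVER = z, NOISE = rbinom(n, 1, 0.5))
  rm <- ReportMatrix(X, matrix(rbinom(n, 1, 0.2), ncol = 1,
                               dimnames = list(NULL, "AE")))
  ps <- psGtb(rm, "TARGET", nRounds = 30, seed = 1)
  expect_gt(min(psScores(ps)[z == 1]), max(psScores(ps)[z == 0]))
  expect_identical(psScores(ps), psScores(psGtb(rm, "TARGET", nRounds = 30,
                                                seed = 1)))
})

test_that("every estimator is calibrated in the large", {
  db <- indepSim(9, n = 10000, I = 10)
  g <- drugIds(db@rm)[1]
  prev <- mean(exposures(db@rm)[, g])
  for (ps in list(psBic(db@rm, g),
                  suppressMessages(psCisl(db@rm, g, B = 20, seed = 1)),
                  psHdps(db@rm, g, "AE1", nTop = 5),
                  psGtb(db@rm, g, nRounds = 50, seed = 1)))
    expect_equal(mean(psScores(ps)), prev, tolerance = 0.02)
  ## scores are clamped away from the boundaries for weighting
  expect_true(all(psScores(psGtb(db@rm, g, seed = 1)) >= 1e-6))
})
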