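## Independent oracles and small fixture builders used across the suite.

## Brute-force Benjamini-Hochberg step-up adjustment: for each p-value the
## minimum over the tail ranks of m * p_(j) / j, capped at 1.  Deliberately
## a double loop over the sorted values, independent of p.adjust.
bhOracle <- function(p) {
  m <- length(p)
  if (!m) return(numeric(0))
  ord <- order(p)
  ps <- p[ord]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (j in i:m) best <- min(best, m * ps[j] / j)
    adj[i] <- min(1, best)
  }
  out <- numeric(m)
  out[ord] <- adj
  out
}

## Scalar L1-penalized logistic regression (one covariate + unpenalized
## intercept) on the averaged-likelihood scale used by the path engine:
## minimise -(1/N) loglik + lambda |beta|.  Proximal Newton with a
## soft-threshold update, independent of glmnet.
scalarLassoOracle <- function(y, x, lambda, maxIter = 200, tol = 1e-10) {
  n <- length(y)
  b0 <- stats::qlogis(mean(y)); b1 <- 0
  for (it in seq_len(maxIter)) {
    eta <- b0 + b1 * x
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    b0new <- sum(w * (z - b1 * x)) / sum(w)
    num <- sum(w * x * (z - b0new)) / n
    den <- sum(w * x^2) / n
    b1new <- sign(num) * max(0, abs(num) - lambda) / den
    if (abs(b0new - b0) + abs(b1new - b1) < tol) {
      b0 <- b0new; b1 <- b1new
      break
    }
    b0 <- b0new; b1 <- b1new
  }
  c(intercept = b0, beta = b1)
}

## Direct 2x2 indicator fixture: a reports with (x=1,y=1), b with (1,0),
## c with (0,1), d with (0,0), plus a second filler drug so matrices keep
## two columns.
rm2x2 <- function(a, b, c, d, drug = "DRG", ae = "AE") {
  x <- rep(c(1, 1, 0, 0), c(a, b, c, d))
  y <- rep(c(1, 0, 1, 0), c(a, b, c, d))
  n <- length(x)
  set.seed(99)
  X <- cbind(x, rbinom(n, 1, 0.5))
  colnames(X) <- c(drug, "FILLER")
  Y <- matrix(y, ncol = 1, dimnames = list(NULL, ae))
  ReportMatrix(X, Y)
}

## Small random long-format record set with a known seed.
randomRecords <- function(n = 10, seed = 1) {
  set.seed(seed)
  data.frame(
    report_id = sample(paste0("r", 1:4), n, replace = TRUE),
    code = sample(c("A", "B", "e1", "e2"), n, replace = TRUE),
    kind = NA_character_) |>
    within(kind <- ifelse(code %in% c("A", "B"), "drug", "ae"))
}

## Convenience: small simulated database with the package defaults except
## for size, for detector-level tests.
smallSim <- function(seed, nReports = 4000, nDrugs = 40, nTrue = 10,
                     nConf = 10, ...) {
  simulateReports(simConfig(nReports = nReports, nDrugs = nDrugs,
                            nTrueSignals = nTrue, nConfoundedNulls = nConf,
                            seed = seed, ...))
}

flaggedOf <- function(tbl) tbl$drug[tbl$signal]

labelled <- function(db, lab) db@truth$drug[db@truth$label == lab]

## Builds a signal table realizing given counts against a reference set
## with nPos positive and nNeg negative control pairs for one AE.
mockStudy <- function(tp, fp, nGen, nPos = 114, nNeg = 90) {
  ref <- data.frame(
    drug = c(sprintf("P%03d", seq_len(nPos)), sprintf("N%03d", seq_len(nNeg))),
    ae = "AE",
    label = rep(c("positive", "negative"), c(nPos, nNeg)))
  nUnk <- nGen - tp - fp
  drugs <- c(sprintf("P%03d", seq_len(tp)), sprintf("N%03d", seq_len(fp)),
             sprintf("U%03d", seq_len(nUnk)))
  sig <- data.frame(drug = drugs, ae = "AE", method = "mock",
                    strategy = "mock", estimate = seq(2, 1, length.out = nGen),
                    se = 0.1, z = 1, p = seq(0.001, 0.04, length.out = nGen),
                    p_fdr = seq(0.002, 0.05, length.out = nGen),
                    signal = TRUE, note = "")
  list(sig = sig, ref = ref)
}
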