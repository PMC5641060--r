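# Direct evaluation of the two-group log-rank statistic: at each event
# time, observed minus expected events in group 1 with the usual
# hypergeometric variance.
logrankOracle <- function(time, event, group) {
  ts <- sort(unique(time[event]))
  U <- 0; V <- 0
  for (t in ts) {
    at <- time >= t
    n <- sum(at); n1 <- sum(at & group == 1)
    d <- sum(event & time == t); d1 <- sum(event & time == t & group == 1)
    U <- U + d1 - d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  U^2 / V
}

mkClinical <- function(time, event, ids = NULL) {
  if (is.null(ids)) ids <- paste0("s", seq_along(time))
  data.frame(sample_id = ids, time = time, event = event,
             stringsAsFactors = FALSE)
}

test_that("univariate Cox recovers a planted hazard coefficient", {
  set.seed(61)
  ok <- 0
  for (i in 1:50) {
    n <- 300
    z <- rnorm(n)
    t <- rexp(n, rate = 5e-4 * exp(0.8 * z))
    cl <- mkClinical(pmin(t, 1500) + 1e-3, t <= 1500)
    fit <- univariateCox(setNames(z, cl$sample_id), cl)
    if (abs(fit$beta - 0.8) <= 0.2) ok <- ok + 1
  }
  expect_gte(ok / 50, 0.9)
})

test_that("univariate Cox guards and degenerate inputs behave", {
  set.seed(62)
  cl <- mkClinical(rexp(50, 1e-3) + 1, rep(TRUE, 50))
  constant <- setNames(rep(2, 50), cl$sample_id)
  fit <- univariateCox(constant, cl)
  expect_equal(fit$beta, 0)
  expect_error(univariateCox(setNames(rnorm(5), cl$sample_id[1:5]),
                             cl[1:5, ]), ">= 10")
  noEv <- mkClinical(rexp(20, 1e-3) + 1, rep(FALSE, 20))
  expect_error(univariateCox(setNames(rnorm(20), noEv$sample_id), noEv),
               ">= 3")
})

test_that("log-rank statistic matches the hand-computable oracle", {
  time <- c(1, 2, 3, 4, 5, 6)
  event <- c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE)
  group <- c(1, 0, 1, 0, 1, 0)
  sd0 <- survival::survdiff(survival::Surv(time, event) ~ group)
  expect_equal(unname(sd0$chisq), logrankOracle(time, event, group),
               tolerance = 1e-10)
  # larger randomized fixture
  set.seed(63)
  time2 <- rexp(40, 0.01); event2 <- runif(40) < 0.7
  group2 <- rep(0:1, 20)
  sd2 <- survival::survdiff(survival::Surv(time2, event2) ~ group2)
  expect_equal(unname(sd2$chisq),
               logrankOracle(time2, event2, group2), tolerance = 1e-8)
})

test_that("triple risk models split at the median and test by log-rank", {
  set.seed(64)
  n <- 200
  ids <- paste0("s", 1:n)
  zl <- rnorm(n); zm <- rnorm(n); zp <- rnorm(n)
  lp <- 0.7 * zl - 0.7 * zm + 0.7 * zp
  t <- rexp(n, rate = 5e-4 * exp(lp))
  cl <- mkClinical(pmin(t, 1500) + 1e-3, t <= 1500, ids)
  vecs <- list(L = setNames(zl, ids), m1 = setNames(zm, ids),
               P = setNames(zp, ids))
  rm <- tripleRisk("L", "m1", "P", vecs, cl)
  expect_s4_class(rm, "RiskModel")
  expect_equal(sign(unname(riskBetas(rm))), c(1, -1, 1))
  expect_lt(logrankP(rm), 0.05)
  # group sizes differ by at most one and the cut is the median
  expect_lte(abs(sum(riskGroups(rm) == "high") -
                 sum(riskGroups(rm) == "low")), 1)
  expect_equal(rm@cut, median(riskScores(rm)))
  # risk score commutes with node order
  rm2 <- tripleRisk("P", "m1", "L", vecs, cl)
  expect_equal(sort(riskScores(rm2)), sort(riskScores(rm)),
               tolerance = 1e-12)
  expect_equal(logrankP(rm2), logrankP(rm), tolerance = 1e-12)
})

test_that("constant risk vectors are flagged degenerate, missing nodes error", {
  set.seed(65)
  n <- 60
  ids <- paste0("s", 1:n)
  cl <- mkClinical(rexp(n, 1e-3) + 1, runif(n) < 0.5, ids)
  const <- list(L = setNames(rep(1, n), ids),
                m1 = setNames(rep(2, n), ids),
                P = setNames(rep(3, n), ids))
  rm <- tripleRisk("L", "m1", "P", const, cl)
  expect_true(rm@degenerate)
  expect_true(is.na(logrankP(rm)))
  expect_error(tripleRisk("L", "m1", "missing", const, cl),
               "missing")
})

test_that("same-data risk scores are optimistic but bounded under the null", {
  # the betas are estimated on the same cohort the split is tested on,
  # so the null log-rank rate exceeds the nominal 5% (the well-known
  # optimism of in-sample risk scores); it must still stay far from
  # certainty
  set.seed(66)
  n <- 150
  sig <- 0
  for (i in 1:40) {
    ids <- paste0("s", 1:n)
    t <- rexp(n, rate = 5e-4)
    cl <- mkClinical(pmin(t, 1500) + 1e-3, t <= 1500, ids)
    vecs <- list(L = setNames(rnorm(n), ids),
                 m1 = setNames(rnorm(n), ids),
                 P = setNames(rnorm(n), ids))
    rm <- tripleRisk("L", "m1", "P", vecs, cl)
    if (!is.na(logrankP(rm)) && logrankP(rm) < 0.05) sig <- sig + 1
  }
  expect_lte(sig / 40, 0.4)
})

test_that("drug nomination follows the up-miRNA / up-partners rule", {
  module <- data.frame(
    lncrna_id = c("L1", "L2"), pcg_id = c("P1", "P2"),
    surviving_mirnas = c("m1,m2", "m3"),
    lnc_direction = c("up", "down"), pcg_direction = c("up", "up"),
    stringsAsFactors = FALSE)
  drugs <- data.frame(
    source_id = c("dA", "dB", "dC", "dD"),
    target_id = c("m1", "m2", "m3", "m_out"),
    effect = c("up", "down", "up", "up"),
    stringsAsFactors = FALSE)
  out <- drugCandidates(module, drugs)
  expect_false("m_out" %in% out$mirna_id)  # outside every module
  expect_equal(out$rationale[out$drug == "dA"],
               "suppresses_overexpressed_partners")
  expect_equal(out$rationale[out$drug == "dB"], "other")  # down effect
  expect_equal(out$rationale[out$drug == "dC"], "other")  # lncRNA down
  expect_equal(nrow(drugCandidates(module, drugs[0, ])), 0)
})
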