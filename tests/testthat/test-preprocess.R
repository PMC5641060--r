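test_that("upper-quartile normalization hits the target and is scale invariant", {
  m <- omFrom(matrix(c(1, 2, 3, 4, 2, 4, 6, 8), 4, 2))
  out <- upperQuartileNormalize(m, target = 1000)
  # oracle: independent sort-and-interpolate percentile
  # (h = (n-1)p + 1 between closest ranks)
  q75 <- function(x) {
    x <- sort(x); h <- (length(x) - 1) * 0.75 + 1
    lo <- floor(h)
    x[lo] + (h - lo) * (x[lo + 1] - x[lo])
  }
  expect_equal(omicsValues(out)[, 1],
               omicsValues(m)[, 1] * 1000 / q75(c(1, 2, 3, 4)))
  # doubling a sample changes nothing after normalization
  m2 <- omFrom(matrix(c(2, 4, 6, 8, 2, 4, 6, 8), 4, 2))
  expect_equal(omicsValues(upperQuartileNormalize(m2, 1000)),
               omicsValues(out), ignore_attr = FALSE)
  # a sample already at the target is unchanged
  v <- c(1, 2, 3, 4) * 1000 / q75(c(1, 2, 3, 4))
  m3 <- omFrom(matrix(v, 4, 1))
  expect_equal(unname(omicsValues(upperQuartileNormalize(m3, 1000))[, 1]),
               v)
  # zeros stay zero; all-zero sample errors with its name
  m4 <- omFrom(matrix(c(0, 1, 2, 3, 0, 0, 0, 0), 4, 2))
  expect_error(upperQuartileNormalize(m4, 1000), "s2")
})

test_that("missing-value filter uses a strict 30% boundary", {
  v <- matrix(1, 3, 100)
  v[1, 1:31] <- NA  # 31% missing: removed
  v[2, 1:30] <- NA  # exactly 30%: retained
  m <- omFrom(v)
  out <- filterMissingGenes(m, 0.3)
  expect_equal(rownames(out), c("g2", "g3"))
  expect_equal(sum(is.na(omicsValues(out)["g2", ])), 30)
  full <- omFrom(matrix(1:12, 3, 4))
  expect_equal(dim(filterMissingGenes(full)), dim(full))
})

test_that("log transform applies the pseudocount convention", {
  m <- omFrom(matrix(c(0, 2), 1, 2))
  expect_equal(omicsValues(logTransform(m, 2))[1, ], c(s1 = 1, s2 = 2))
  expect_equal(omicsValues(logTransform(m, 0.05))[1, 1],
               log2(0.05), ignore_attr = TRUE)   # = -4.321928...
  neg <- omFrom(matrix(c(-1, 2), 1, 2))
  expect_error(logTransform(neg, 2), "negative")
})

test_that("weakly expressed lncRNAs are dropped by median/90th-percentile rules", {
  v <- rbind(rep(0, 10),                   # all zero: drop (median 0)
             rep(5, 10),                   # constant 5: keep
             c(rep(0, 6), rep(1, 4)),      # median 0: drop
             rep(0.05, 10))                # q90 <= 0.1: drop
  m <- omFrom(v)
  expect_equal(rownames(filterLowLncrna(m)), "g2")
})

test_that("benjaminiHochberg matches the hand step-up oracle", {
  expect_equal(benjaminiHochberg(c(0.01, 0.02, 0.03)),
               c(0.03, 0.03, 0.03))
  expect_equal(benjaminiHochberg(0.2), 0.2)
  expect_equal(benjaminiHochberg(c(1, 1)), c(1, 1))
  set.seed(42)
  for (i in 1:25) {
    p <- runif(sample(1:50, 1))
    expect_equal(benjaminiHochberg(p), bhOracle(p))
  }
  expect_error(benjaminiHochberg(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("SAM statistic is zero for equal means and respects invariances", {
  set.seed(9)
  v <- matrix(rnorm(40 * 200, mean = 6), nrow = 40)
  logM <- omFrom(v, nTumor = 100)
  linM <- omFrom(2^v, nTumor = 100)
  res <- samDifferentialExpression(logM, linM, nPerm = 100, seed = 1)
  # equal-mean gene: plant exact equality of class means
  v2 <- v
  v2[1, ] <- 5
  v2[1, 1:100] <- v2[1, 101:200] <- rnorm(100)
  r2 <- samDifferentialExpression(omFrom(v2, 100), omFrom(2^v2, 100),
                                  nPerm = 100, seed = 1)
  expect_equal(r2$statistic[1], 0, tolerance = 1e-12)
  expect_false(r2$de[1])
  # shift invariance: adding a constant to one gene leaves d unchanged
  v3 <- v
  v3[2, ] <- v3[2, ] + 7
  r3 <- samDifferentialExpression(omFrom(v3, 100), omFrom(2^v3, 100),
                                  nPerm = 100, seed = 1)
  expect_equal(r3$statistic[2], res$statistic[2], tolerance = 1e-9)
  # antisymmetry under class-label swap
  swapped <- omFrom(v[, c(101:200, 1:100)], nTumor = 100)
  linSwap <- omFrom(2^v[, c(101:200, 1:100)], nTumor = 100)
  rs <- samDifferentialExpression(swapped, linSwap, nPerm = 100, seed = 1)
  expect_equal(rs$statistic, -res$statistic, tolerance = 1e-9)
})

test_that("SAM recovers planted 4-fold genes on the synthetic cohort", {
  co <- defaultCohort()
  pcgLin <- filterMissingGenes(
    upperQuartileNormalize(co$matrices$pcg_expr, 1000), 0.3)
  pcgLog <- logTransform(pcgLin, 2)
  res <- samDifferentialExpression(pcgLog, pcgLin, nPerm = 200, seed = 1)
  planted <- c(co$truth$de_pcgs_up, co$truth$de_pcgs_down)
  called <- res$gene_id[res$de]
  expect_gte(length(intersect(called, planted)) / length(planted), 0.95)
  expect_lte(length(setdiff(called, planted)) / max(1, length(called)), 0.1)
  # directions match the plant
  up <- res$gene_id[res$de & res$direction == "up"]
  expect_true(all(intersect(up, planted) %in% co$truth$de_pcgs_up))
})

test_that("SAM guards degenerate inputs", {
  v <- matrix(rnorm(40), 4, 10)
  allTumor <- omFrom(v, nTumor = 10)
  expect_error(samDifferentialExpression(allTumor, allTumor, 100),
               "tumor and normal")
  m <- omFrom(v, nTumor = 5)
  expect_warning(samDifferentialExpression(m, omFrom(2^v, 5), nPerm = 50),
                 "nPerm")
})

test_that("pearsonScreen recovers exact correlations and is symmetric", {
  set.seed(11)
  base <- rnorm(30)
  v <- rbind(a1 = base, a2 = -base + rnorm(30, sd = 1e-9))
  w <- rbind(b1 = base, b2 = rnorm(30))
  a <- omFrom(v); b <- omFrom(w)
  res <- pearsonScreen(a, b, rMin = 0.9, sign = "any")
  hit <- res[res$gene_a == "a1" & res$gene_b == "b1", ]
  expect_equal(hit$r, 1, tolerance = 1e-12)
  neg <- pearsonScreen(a, b, rMin = 0.9, sign = "negative")
  expect_true(all(neg$r < -0.9))
  # symmetry: screening (a,b) and (b,a) gives the same unordered set
  res2 <- pearsonScreen(b, a, rMin = 0.9, sign = "any")
  key1 <- sort(paste(pmin(res$gene_a, res$gene_b),
                     pmax(res$gene_a, res$gene_b)))
  key2 <- sort(paste(pmin(res2$gene_a, res2$gene_b),
                     pmax(res2$gene_a, res2$gene_b)))
  expect_equal(key1, key2)
  expect_error(pearsonScreen(omFrom(v[, 1:2]), omFrom(w[, 1:2])),
               ">= 3")
})

test_that("zero-variance genes are skipped and counted", {
  v <- rbind(g1 = rep(1, 10), g2 = rnorm(10))
  w <- rbind(h1 = rnorm(10))
  res <- pearsonScreen(omFrom(v), omFrom(w), rMin = 0, sign = "any")
  expect_equal(attr(res, "skipped"), 1)
  expect_false("g1" %in% res$gene_a)
})
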