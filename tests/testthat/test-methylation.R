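lncAnnOf <- function(co) {
  ann <- co$annotation
  ann[S4Vectors::mcols(ann)$biotype == "lncRNA"]
}

test_that("promoters extend upstream of the TSS, clipped at the chromosome start", {
  mk <- function(start, end, strand) {
    ann <- GenomicRanges::GRanges("chr1", IRanges::IRanges(start, end),
                                  strand = strand)
    S4Vectors::mcols(ann)$gene_id <- "g1"
    S4Vectors::mcols(ann)$tss <- if (strand == "-") end else start
    names(ann) <- "g1"
    ann
  }
  p <- promoterRegions(mk(5001, 6000, "+"), 2000)
  expect_equal(c(start(p), end(p)), c(3001, 5000))
  m <- promoterRegions(mk(4001, 5000, "-"), 2000)
  expect_equal(c(start(m), end(m)), c(5001, 7000))
  clip <- promoterRegions(mk(1001, 2000, "+"), 2000)
  expect_equal(start(clip), 1)
  # strand-agnostic mode always looks left of the start
  ag <- promoterRegions(mk(4001, 5000, "-"), 2000, strandAware = FALSE)
  expect_equal(c(start(ag), end(ag)), c(2001, 4000))
})

test_that("probes mapping to zero or multiple promoters are dropped", {
  proms <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(c(1000, 1500),
                                                   c(2000, 2500)))
  S4Vectors::mcols(proms)$gene_id <- c("gA", "gB")
  probes <- data.frame(probe_id = c("p1", "p2", "p3"),
                       chrom = "chr1",
                       position = c(1200, 1800, 5000))
  pm <- mapProbes(probes, proms)
  expect_equal(pm$probe_id, "p1")   # p2 is in both, p3 in none
  expect_equal(pm$gene_id, "gA")
})

test_that("gene beta imputes probe means first, then averages probes", {
  v <- rbind(p1 = c(0.2, NA, 0.8),
             p2 = c(0.4, 0.4, 0.4))
  beta <- omFrom(v, nTumor = 2, role = "beta")
  pm <- data.frame(probe_id = c("p1", "p2"), gene_id = "gX")
  gb <- geneBeta(beta, pm)
  # p1 missing cell imputed with mean(0.2, 0.8) = 0.5
  expect_equal(unname(omicsValues(gb)["gX", ]), c(0.3, 0.45, 0.6))
  expect_true(all(omicsValues(gb) >= 0 & omicsValues(gb) <= 1))
  # idempotence: a gene-level matrix re-aggregated by itself is unchanged
  gb2 <- geneBeta(gb, data.frame(probe_id = "gX", gene_id = "gX"))
  expect_equal(omicsValues(gb2)["gX", ], omicsValues(gb)["gX", ])
  # single fully observed probe passes through unchanged
  one <- geneBeta(omFrom(v["p2", , drop = FALSE], 2, "beta"),
                  data.frame(probe_id = "p2", gene_id = "gY"))
  expect_equal(unname(omicsValues(one)["gY", ]), unname(v["p2", ]))
})

test_that("Welch test matches stats::t.test gene by gene", {
  set.seed(21)
  v <- matrix(rbeta(20 * 30, 2, 5), nrow = 20)
  rownames(v) <- paste0("g", 1:20)
  gb <- omFrom(v, nTumor = 18, role = "beta")
  dm <- differentialMethylation(gb)
  for (i in c(1, 7, 20)) {
    ref <- t.test(v[i, 1:18], v[i, 19:30])
    expect_equal(dm$p[i], ref$p.value, tolerance = 1e-12)
  }
  expect_error(differentialMethylation(omFrom(v[, 1:19], 18, "beta")),
               ">= 2")
})

test_that("methylation calls combine the fold-change and FDR gates", {
  set.seed(22)
  n <- 40
  v <- matrix(rbeta(30 * n, 3, 17), nrow = 30)
  v[1, 1:30] <- rbeta(30, 10, 10)    # hyper: tumor mean ~0.5 vs ~0.15
  gb <- omFrom(v, nTumor = 30, role = "beta")
  dm <- differentialMethylation(gb, fcMin = 2, fdrMax = 0.01)
  expect_true(dm$called[1] && dm$state[1] == "hyper")
  expect_gt(dm$beta_fc[1], 2)
  expect_lt(sum(dm$called[-1]), 3)
})

test_that("planted hypermethylated lncRNAs are recovered from the cohort", {
  co <- defaultCohort()
  prom <- promoterRegions(lncAnnOf(co), 2000)
  pm <- mapProbes(co$probes, prom)
  gb <- geneBeta(co$matrices$probe_beta, pm)
  dm <- differentialMethylation(gb, 2, 0.01)
  called <- dm$gene_id[dm$called & dm$state == "hyper"]
  truth <- co$truth$hypermeth_lncrnas
  expect_gte(length(intersect(called, truth)) / length(truth), 0.9)
  expect_equal(length(setdiff(called, truth)), 0)
})

test_that("group expression comparison detects the planted low-expression set", {
  co <- defaultCohort()
  lncLog <- logTransform(co$matrices$lncrna_expr, 0.05)
  hyper <- co$truth$hypermeth_lncrnas
  rest <- setdiff(rownames(lncLog), hyper)
  cmp <- compareExpressionGroups(lncLog, hyper, rest)
  expect_lt(cmp$p, 0.05)
  expect_equal(cmp$direction, "A_lower")
  # identical sets: no signal
  same <- compareExpressionGroups(lncLog, rest, rest)
  expect_gt(same$p, 0.9)
  expect_error(compareExpressionGroups(lncLog, character(0), rest),
               "non-empty")
  expect_warning(compareExpressionGroups(lncLog, hyper[1], rest[1]),
                 "singleton")
})

test_that("methylation-expression correlation flags exact negative coupling", {
  set.seed(23)
  b <- matrix(rbeta(5 * 20, 2, 2), nrow = 5,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:20)))
  e <- 10 - 5 * b   # expr = -beta exactly (up to affine map)
  gb <- omFrom(b, 15, "beta")
  ex <- omFrom(e, 15)
  res <- methExprCorrelation(gb, ex)
  expect_true(all(res$negative))
  expect_equal(res$r, rep(-1, 5), tolerance = 1e-12)
  expect_error(methExprCorrelation(gb[, 1:2], ex[, 1:2]), ">= 3")
})

test_that("independent methylation and expression are flagged at the nominal rate", {
  set.seed(24)
  flagged <- 0; total <- 0
  for (i in 1:10) {
    b <- matrix(rbeta(40 * 30, 2, 2), nrow = 40,
                dimnames = list(paste0("g", 1:40), paste0("s", 1:30)))
    e <- matrix(rnorm(40 * 30), nrow = 40,
                dimnames = dimnames(b))
    res <- methExprCorrelation(omFrom(b, 30, "beta"), omFrom(e, 30))
    flagged <- flagged + sum(res$negative)
    total <- total + nrow(res)
  }
  # two-sided 5% split over the negative side: ~2.5%, allow < 6%
  expect_lt(flagged / total, 0.06)
})
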