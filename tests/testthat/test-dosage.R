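mkAnn <- function(starts, ends, chrom = "chr1", strand = "+",
                  biotype = "lncRNA") {
  ann <- GenomicRanges::GRanges(chrom, IRanges::IRanges(starts, ends),
                                strand = strand)
  ids <- paste0("g", seq_along(ann))
  S4Vectors::mcols(ann)$gene_id <- ids
  S4Vectors::mcols(ann)$symbol <- ids
  S4Vectors::mcols(ann)$biotype <- biotype
  S4Vectors::mcols(ann)$tss <- ifelse(strand == "-", ends, starts)
  names(ann) <- ids
  ann
}

mkFrags <- function(starts, ends, direction = "gain", chrom = "chr1") {
  fr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(starts, ends))
  S4Vectors::mcols(fr)$fragment_id <- paste0("f", seq_along(fr))
  S4Vectors::mcols(fr)$direction <- rep(direction, length.out = length(fr))
  names(fr) <- S4Vectors::mcols(fr)$fragment_id
  fr
}

test_that("fragment mapping respects interval boundaries and multiplicity", {
  # gene [101,200] vs fragment [151,300]: 50 bp overlap
  ann <- mkAnn(101, 200)
  hit <- mapToFragments(ann, mkFrags(151, 300))
  expect_equal(hit$overlap_bp, 50)
  # adjacent but non-overlapping intervals do not hit
  expect_equal(nrow(mapToFragments(ann, mkFrags(201, 300))), 0)
  # a gene spanning two fragments yields two hits
  two <- mapToFragments(mkAnn(101, 400),
                        mkFrags(c(1, 301), c(150, 500),
                                direction = c("gain", "loss")))
  expect_equal(nrow(two), 2)
  expect_setequal(two$direction, c("gain", "loss"))
  # order independence
  ann3 <- mkAnn(c(101, 301, 601), c(200, 400, 700))
  fr3 <- mkFrags(c(50, 350), c(120, 650), direction = c("gain", "loss"))
  h1 <- mapToFragments(ann3, fr3)
  h2 <- mapToFragments(rev(ann3), rev(fr3))
  expect_equal(h1, h2[order(h2$gene_id, h2$fragment_id), ],
               ignore_attr = TRUE)
})

test_that("alteration frequency counts gains/losses with a >= 20% gate", {
  v <- rbind(g1 = c(1, 1, 0, 0, -1),
             g2 = rep(0, 5),
             g3 = c(1, 0, 0, 0, 0))
  dcn <- omFrom(v, nTumor = 5, role = "discrete_cn")
  f <- alterationFrequency(dcn, 0.2)
  expect_equal(f$gain_freq, c(0.4, 0, 0.2))
  expect_equal(f$loss_freq, c(0.2, 0, 0))
  expect_equal(f$high_frequency, c(TRUE, FALSE, TRUE))  # 0.2 counts (>=)
  expect_equal(f$direction[1], "gain")
})

test_that("DSS is exactly +-1 for perfect monotone dependence", {
  set.seed(3)
  cn <- c(runif(40, -1.4, -0.4), runif(60, -0.25, 0.25))
  r <- dosageSensitivityScore(cn, 2 * cn, n = 6)
  expect_equal(r$dss, 1)
  expect_equal(r$linear_component, 1)
  expect_equal(r$monotonicity_component, 1)
  r2 <- dosageSensitivityScore(cn, -cn, n = 6)
  expect_equal(r2$dss, -1)
})

test_that("DSS is invariant under positive affine maps and flips sign", {
  set.seed(4)
  cn <- c(runif(30, 0.4, 1.4), runif(70, -0.25, 0.25))
  expr <- 0.8 * cn + rnorm(100, sd = 0.2)
  a <- dosageSensitivityScore(cn, expr)
  b <- dosageSensitivityScore(cn, 3 * expr + 10)
  expect_equal(a$dss, b$dss, tolerance = 1e-12)
  c2 <- dosageSensitivityScore(cn, -expr)
  expect_equal(c2$dss, -a$dss, tolerance = 1e-12)
})

test_that("monotonicity component matches a brute-force pair-count oracle", {
  set.seed(5)
  for (i in 1:20) {
    m <- sample(20:40, 1); n <- sample(2:7, 1)
    cn <- c(runif(ceiling(m * 0.4), 0.35, 1.5),
            runif(m - ceiling(m * 0.4), -0.29, 0.29))
    expr <- rnorm(m)
    r <- dosageSensitivityScore(cn, expr, n = n)
    # oracle: recompute bin means independently and count ordered pairs
    ord <- order(cn, as.character(seq_along(cn)))
    sizes <- c(rep(m %/% n, n - m %% n), rep(m %/% n + 1, m %% n))
    bins <- split(expr[ord], rep(seq_len(n), sizes))
    bm <- unname(vapply(bins, mean, numeric(1)))
    s <- 0
    for (k in seq_len(n - 1)) for (l in (k + 1):n)
      s <- s + sign(bm[l] - bm[k])
    expect_equal(r$monotonicity_component, s / choose(n, 2),
                 tolerance = 1e-12)
  }
})

test_that("DSS honours the alteration gate and bin preconditions", {
  cn <- c(rep(0, 85), rep(1, 15))    # 15% altered: below the > 20% gate
  r <- dosageSensitivityScore(cn, rnorm(100))
  expect_false(r$defined)
  expect_true(is.na(r$dss))
  expect_error(dosageSensitivityScore(rnorm(5), rnorm(5), n = 6),
               "exceeds")
  expect_error(dosageSensitivityScore(rnorm(10), rnorm(10), n = 1),
               ">= 2")
})

test_that("planted dosage-sensitive genes score high, null genes near zero", {
  co <- generateCohort(cohortConfig(noise_sd = 0.1,
                                    dosage_slope_range = c(0.5, 1.2),
                                    seed = 8))
  lncLog <- logTransform(co$matrices$lncrna_expr, 0.05)
  tab <- dssTable(co$matrices$copy_number, lncLog,
                  geneIds = co$truth$dss_lncrnas)
  expect_gte(mean(tab$dss), 0.9)
  fragGenes <- unique(mapToFragments(
    co$annotation[mcols(co$annotation)$biotype == "lncRNA"],
    co$fragments)$gene_id)
  nullGenes <- setdiff(fragGenes, co$truth$dss_lncrnas)
  nullTab <- dssTable(co$matrices$copy_number, lncLog,
                      geneIds = nullGenes)
  expect_lt(mean(abs(nullTab$dss)), 0.25)
})

test_that("robustness table needs two n values and reports Spearman pairs", {
  co <- defaultCohort()
  lncLog <- logTransform(co$matrices$lncrna_expr, 0.05)
  expect_error(dssRobustness(co$matrices$copy_number, lncLog,
                             nValues = 6), ">= 2")
  rb <- dssRobustness(co$matrices$copy_number, lncLog,
                      nValues = c(5, 7),
                      geneIds = co$truth$dss_lncrnas)
  expect_equal(dim(rb$correlations), c(2, 2))
  expect_equal(diag(rb$correlations), c(n5 = 1, n7 = 1))
})

test_that("DSS groups partition defined scores into k equal-width bins", {
  tab <- data.frame(gene_id = paste0("g", 1:8),
                    dss = c(0, 1, 2, 3, 4, 5, 6, 7))
  g <- assignDssGroups(tab, k = 7)
  expect_equal(unname(g), c(1, 2, 3, 4, 5, 6, 7, 7))  # max closes group k
  expect_equal(sum(table(g)), 8)
  same <- data.frame(gene_id = c("a", "b", "c", "d", "e", "f", "g"),
                     dss = rep(0.3, 7))
  expect_warning(g2 <- assignDssGroups(same, k = 7), "single group")
  expect_true(all(g2 == 1))
})
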