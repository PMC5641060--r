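#' @importFrom GenomicRanges promoters countOverlaps start<- strand<-
#' @importFrom stats wilcox.test
NULL

#' Promoter regions upstream of the TSS
#'
#' The promoter of a gene is the `length` bp immediately upstream of its
#' transcription start site: `[tss - length, tss)` on the `+` strand and
#' `(tss, tss + length]` on the `-` strand, clipped at the chromosome
#' start. Strand awareness is the default; set `strandAware = FALSE` to
#' always take the region left of the annotated start.
#'
#' @param ann GRanges gene annotation.
#' @param length promoter length in bp.
#' @param strandAware use the strand to orient "upstream".
#' @return GRanges of promoter intervals, named by gene_id, with mcols
#'   `gene_id`.
#' @export
promoterRegions <- function(ann, length = 2000, strandAware = TRUE) {
  gr <- granges(ann)
  if (!strandAware) strand(gr) <- "+"
  prom <- promoters(gr, upstream = length, downstream = 0)
  # clip at the chromosome start (seqlengths are usually unknown here)
  start(prom) <- pmax(start(prom), 1L)
  mcols(prom)$gene_id <- mcols(ann)$gene_id
  names(prom) <- mcols(ann)$gene_id
  prom
}

#' Map methylation probes to promoters
#'
#' A probe is kept iff its genomic position falls inside exactly one
#' promoter interval; probes hitting zero or more than one promoter are
#' dropped.
#'
#' @param probes data.frame(probe_id, chrom, position) with 1-based
#'   positions.
#' @param promoters GRanges from [promoterRegions()].
#' @return data.frame(probe_id, gene_id).
#' @export
mapProbes <- function(probes, promoters) {
  pr <- GRanges(probes$chrom, IRanges(probes$position, probes$position))
  hits <- findOverlaps(pr, promoters, ignore.strand = TRUE)
  nHit <- countOverlaps(pr, promoters, ignore.strand = TRUE)
  keep <- which(nHit == 1L)
  qi <- queryHits(hits); si <- subjectHits(hits)
  sel <- qi %in% keep
  data.frame(
    probe_id = probes$probe_id[qi[sel]],
    gene_id = mcols(promoters)$gene_id[si[sel]],
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Promoter methylation beta values per gene
#'
#' Missing probe values are first imputed with the probe's across-sample
#' mean; the gene-level beta of a sample is then the mean over the
#' gene's probes. Imputation-then-aggregation is idempotent. Genes with
#' no mapped probe are absent from the output.
#'
#' @param beta probe-level OmicsMatrix with role `"beta"` (rownames =
#'   probe ids).
#' @param probeMap data.frame(probe_id, gene_id) from [mapProbes()].
#' @return gene-level OmicsMatrix with role `"beta"`.
#' @export
geneBeta <- function(beta, probeMap) {
  stopifnot(omicsRole(beta) == "beta")
  v <- omicsValues(beta)
  probeMap <- probeMap[probeMap$probe_id %in% rownames(v), , drop = FALSE]
  if (!nrow(probeMap)) stop("no probe of the map is present in the matrix")
  v <- v[probeMap$probe_id, , drop = FALSE]
  # impute probe means into missing cells
  pm <- rowMeans(v, na.rm = TRUE)
  idx <- which(is.na(v), arr.ind = TRUE)
  if (nrow(idx)) v[idx] <- pm[idx[, 1]]
  agg <- rowsum(v, group = probeMap$gene_id, reorder = TRUE)
  counts <- as.vector(table(probeMap$gene_id)[rownames(agg)])
  OmicsMatrix(agg / counts, sampleClass(beta), "beta")
}

# Vectorized Welch two-sample t-test per row.
.welchRows <- function(v, isTumor) {
  n1 <- sum(isTumor); n2 <- sum(!isTumor)
  if (n1 < 2 || n2 < 2) stop("each class needs >= 2 samples")
  x1 <- v[, isTumor, drop = FALSE]; x2 <- v[, !isTumor, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(abs(t), df = df, lower.tail = FALSE)
  p[se2 == 0] <- 1  # no variance, no evidence
  list(t = t, p = p, meanTumor = m1, meanNormal = m2)
}

#' Differential promoter methylation
#'
#' Per gene: two-sided Welch t-test between tumor and normal beta
#' values, Benjamini-Hochberg correction, and a fold change defined as
#' the ratio of the tumor and normal mean beta. A gene is called
#' hypermethylated iff `beta_fc > fcMin` and `q < fdrMax`,
#' hypomethylated iff `beta_fc < 1/fcMin` and `q < fdrMax`.
#'
#' @param gb gene-level beta OmicsMatrix from [geneBeta()].
#' @param fcMin fold-change gate.
#' @param fdrMax BH FDR threshold.
#' @return data.frame(gene_id, beta_fc, t, p, q, state, called) where
#'   state is `"hyper"` iff beta_fc > 1 else `"hypo"`.
#' @export
differentialMethylation <- function(gb, fcMin = 2, fdrMax = 0.01) {
  isTumor <- sampleClass(gb) == "tumor"
  w <- .welchRows(omicsValues(gb), isTumor)
  fc <- w$meanTumor / w$meanNormal
  q <- benjaminiHochberg(w$p)
  data.frame(
    gene_id = rownames(gb),
    beta_fc = unname(fc), t = unname(w$t),
    p = unname(w$p), q = unname(q),
    state = ifelse(fc > 1, "hyper", "hypo"),
    called = unname((fc > fcMin | fc < 1 / fcMin) & q < fdrMax),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Compare mean tumor expression between two gene sets
#'
#' Summarizes each gene by its mean tumor expression and compares the
#' two sets with a two-sided Wilcoxon rank-sum test; the direction
#' reports which set has the lower median summary.
#'
#' @param expr expression OmicsMatrix.
#' @param groupA,groupB non-empty character vectors of gene ids.
#' @return list(statistic, p, direction) with direction one of
#'   `"A_lower"`, `"B_lower"`, `"none"`.
#' @export
compareExpressionGroups <- function(expr, groupA, groupB) {
  if (!length(groupA) || !length(groupB)) stop("gene sets must be non-empty")
  v <- omicsValues(subsetByClass(expr, "tumor"))
  a <- rowMeans(v[intersect(groupA, rownames(v)), , drop = FALSE], na.rm = TRUE)
  b <- rowMeans(v[intersect(groupB, rownames(v)), , drop = FALSE], na.rm = TRUE)
  if (!length(a) || !length(b))
    stop("gene sets have no member in the expression matrix")
  if (length(a) == 1 && length(b) == 1)
    warning("singleton gene sets: the rank test has essentially no power")
  wt <- suppressWarnings(wilcox.test(a, b, alternative = "two.sided"))
  direction <- if (median(a) < median(b)) "A_lower"
               else if (median(b) < median(a)) "B_lower" else "none"
  list(statistic = unname(wt$statistic), p = wt$p.value,
       direction = direction)
}

#' Methylation-expression correlation per gene
#'
#' Pearson correlation between a gene's promoter beta and its expression
#' across the samples shared by the two matrices; a gene is flagged
#' negative iff `r < 0` and the raw two-sided p-value is below `pMax`
#' (no multiplicity correction, by design).
#'
#' @param gb gene-level beta OmicsMatrix.
#' @param expr expression OmicsMatrix.
#' @param pMax raw p-value threshold.
#' @return data.frame(gene_id, r, p, negative).
#' @export
methExprCorrelation <- function(gb, expr, pMax = 0.05) {
  samples <- intersect(colnames(gb), colnames(expr))
  if (length(samples) < 3) stop("need >= 3 shared samples")
  genes <- intersect(rownames(gb), rownames(expr))
  bv <- omicsValues(gb)[genes, samples, drop = FALSE]
  ev <- omicsValues(expr)[genes, samples, drop = FALSE]
  m <- length(samples)
  r <- vapply(seq_along(genes), function(i)
    suppressWarnings(cor(bv[i, ], ev[i, ])), numeric(1))
  r[is.na(r)] <- 0
  tstat <- r * sqrt((m - 2) / pmax(1 - r^2, 1e-300))
  p <- 2 * pt(abs(tstat), df = m - 2, lower.tail = FALSE)
  data.frame(gene_id = genes, r = r, p = p,
             negative = r < 0 & p < pMax,
             stringsAsFactors = FALSE, row.names = NULL)
}
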