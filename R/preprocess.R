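#' @importFrom stats cor pt median quantile setNames
NULL

# Percentile convention used throughout the package: linear interpolation
# between closest ranks (stats::quantile type 7).
.pctl <- function(x, p) unname(quantile(x, p, type = 7, names = FALSE))

#' Upper-quartile normalization
#'
#' Scales each sample so that the 75th percentile of its nonzero values
#' equals `target`. Zeros stay zero and missing cells stay missing.
#'
#' @param m OmicsMatrix with role `"expression"` (linear scale).
#' @param target the common upper-quartile value after scaling.
#' @return a rescaled OmicsMatrix.
#' @export
upperQuartileNormalize <- function(m, target = 1000) {
  stopifnot(is(m, "OmicsMatrix"))
  if (omicsRole(m) != "expression") stop("role must be 'expression'")
  v <- omicsValues(m)
  for (j in seq_len(ncol(v))) {
    nz <- v[, j]
    nz <- nz[!is.na(nz) & nz != 0]
    if (!length(nz))
      stop("all-zero sample cannot be upper-quartile normalized: ",
           colnames(v)[j])
    v[, j] <- v[, j] * (target / .pctl(nz, 0.75))
  }
  OmicsMatrix(v, sampleClass(m), "expression")
}

#' Remove genes with too many missing values
#'
#' Drops genes whose fraction of missing samples is strictly greater than
#' `maxMissingFraction` (a gene missing in exactly 30% of samples is
#' kept at the default). Remaining missing cells are left intact.
#'
#' @param m OmicsMatrix.
#' @param maxMissingFraction maximum tolerated missing fraction.
#' @return the filtered OmicsMatrix.
#' @export
filterMissingGenes <- function(m, maxMissingFraction = 0.3) {
  v <- omicsValues(m)
  frac <- rowMeans(is.na(v))
  m[frac <= maxMissingFraction, ]
}

#' Log2 transform with a pseudocount
#'
#' `v -> log2(v + pseudocount)`; the conventional pseudocounts are 2 for
#' protein-coding genes and 0.05 for lncRNAs/miRNAs.
#'
#' @param m OmicsMatrix with non-negative values.
#' @param pseudocount added before taking log2.
#' @return OmicsMatrix on the log2 scale.
#' @export
logTransform <- function(m, pseudocount) {
  v <- omicsValues(m)
  if (any(v < 0, na.rm = TRUE)) stop("negative values cannot be log-transformed")
  OmicsMatrix(log2(v + pseudocount), sampleClass(m), omicsRole(m))
}

#' Drop weakly expressed lncRNAs
#'
#' A gene is removed iff its median is 0 or its 90th percentile is <=
#' `q90Max`, evaluated on the linear scale.
#'
#' @param m linear-scale OmicsMatrix.
#' @param q90Max 90th-percentile floor.
#' @return the filtered OmicsMatrix.
#' @export
filterLowLncrna <- function(m, q90Max = 0.1) {
  v <- omicsValues(m)
  med <- apply(v, 1L, function(x) .pctl(x[!is.na(x)], 0.5))
  q90 <- apply(v, 1L, function(x) .pctl(x[!is.na(x)], 0.9))
  m[!(med == 0 | q90 <= q90Max), ]
}

#' Benjamini-Hochberg step-up FDR
#'
#' Standard BH adjusted p-values (`q_(i) = min_{j>=i} p_(j) m / j` on the
#' sorted vector, mapped back to input order).
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return numeric vector of q-values, same order as `p`.
#' @export
benjaminiHochberg <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

# Pooled-SD two-class d statistic machinery shared by SAM.
.classStats <- function(v, isTumor) {
  n1 <- sum(isTumor); n2 <- sum(!isTumor)
  m1 <- rowMeans(v[, isTumor, drop = FALSE])
  m2 <- rowMeans(v[, !isTumor, drop = FALSE])
  ss1 <- rowSums((v[, isTumor, drop = FALSE] - m1)^2)
  ss2 <- rowSums((v[, !isTumor, drop = FALSE] - m2)^2)
  s <- sqrt((1 / n1 + 1 / n2) * (ss1 + ss2) / (n1 + n2 - 2))
  list(diff = m1 - m2, s = s)
}

#' SAM-style permutation differential expression
#'
#' Computes, per gene, the moderated statistic
#' `d = (mean_tumor - mean_normal) / (s + s0)` with pooled standard
#' deviation `s` and exchangeability constant `s0` (the median of all
#' per-gene pooled SDs), derives two-sided p-values from the
#' pooled-across-genes permutation null of the class labels, applies
#' Benjamini-Hochberg, and calls a gene differentially expressed iff
#' `q < fdrMax` and its linear fold change (ratio of linear-scale class
#' means, tumor/normal) exceeds `fcMin` or falls below `1/fcMin`.
#'
#' @param logM log-scale OmicsMatrix (statistic and permutations).
#' @param linearM linear-scale OmicsMatrix on the same genes/samples
#'   (fold changes).
#' @param nPerm number of label permutations (>= 100 recommended).
#' @param fcMin linear fold-change gate.
#' @param fdrMax BH FDR threshold.
#' @param seed RNG seed for the permutations.
#' @return data.frame(gene_id, statistic, fold_change, p, q, direction,
#'   de) with direction `"up"`/`"down"` from the fold change.
#' @export
samDifferentialExpression <- function(logM, linearM, nPerm = 200,
                                      fcMin = 2, fdrMax = 0.05,
                                      seed = 1) {
  stopifnot(identical(rownames(logM), rownames(linearM)),
            identical(colnames(logM), colnames(linearM)))
  isTumor <- sampleClass(logM) == "tumor"
  if (!any(isTumor) || !all(c(TRUE, FALSE) %in% unique(isTumor)))
    stop("both tumor and normal samples are required")
  if (sum(isTumor) < 2 || sum(!isTumor) < 2)
    stop("need >= 2 samples per class")
  if (nPerm < 100) warning("nPerm < 100: permutation p-values will be coarse")

  v <- omicsValues(logM)
  st <- .classStats(v, isTumor)
  s0 <- median(st$s)
  d <- st$diff / (st$s + s0)

  # pooled permutation null of |d|
  old <- .setSeed(seed)
  on.exit(.restoreSeed(old), add = TRUE)
  nullAbs <- vector("list", nPerm)
  for (b in seq_len(nPerm)) {
    perm <- sample(isTumor)
    stp <- .classStats(v, perm)
    nullAbs[[b]] <- abs(stp$diff / (stp$s + s0))
  }
  nullAbs <- sort(unlist(nullAbs))
  nNull <- length(nullAbs)
  # p = (1 + #{|d*| >= |d|}) / (1 + B*G)
  geq <- nNull - findInterval(abs(d) - 1e-12, nullAbs)
  p <- (1 + geq) / (1 + nNull)
  q <- benjaminiHochberg(p)

  lv <- omicsValues(linearM)
  fc <- rowMeans(lv[, isTumor, drop = FALSE], na.rm = TRUE) /
        rowMeans(lv[, !isTumor, drop = FALSE], na.rm = TRUE)
  res <- data.frame(
    gene_id = rownames(v),
    statistic = unname(d),
    fold_change = unname(fc),
    p = unname(p), q = unname(q),
    direction = ifelse(fc > 1, "up", "down"),
    de = unname(q < fdrMax & (fc > fcMin | fc < 1 / fcMin)),
    stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  res
}

#' Pearson correlation screen between two expression matrices
#'
#' Scores every cross pair (one gene from `a`, one from `b`) with the
#' Pearson correlation over the shared ordered sample set, computes
#' two-sided p-values from the t distribution with `m - 2` df, applies
#' Benjamini-Hochberg over all tested pairs and retains pairs by sign:
#' `positive` keeps `r > rMin`, `negative` keeps `r < -rMin`, `any`
#' keeps `|r| > rMin`, each additionally requiring `q < fdrMax`.
#' Zero-variance genes are skipped (their pair count is reported in the
#' `skipped` attribute).
#'
#' @param a,b OmicsMatrix objects over an identical ordered sample set.
#' @param rMin correlation threshold (strict inequality).
#' @param fdrMax BH FDR threshold.
#' @param sign which correlation sign to retain.
#' @return data.frame(gene_a, gene_b, r, p, q); attribute `skipped` =
#'   number of pairs dropped for zero variance.
#' @export
pearsonScreen <- function(a, b, rMin = 0.5, fdrMax = 0.05,
                          sign = c("positive", "negative", "any")) {
  sign <- match.arg(sign)
  if (!identical(colnames(a), colnames(b)))
    stop("matrices must share an identical ordered sample set")
  nS <- ncol(a)
  if (nS < 3) stop("need >= 3 shared samples")
  va <- omicsValues(a); vb <- omicsValues(b)
  sdA <- apply(va, 1L, stats::sd); sdB <- apply(vb, 1L, stats::sd)
  okA <- sdA > 0; okB <- sdB > 0
  skipped <- sum(!okA) * nrow(vb) + sum(okA) * sum(!okB)
  va <- va[okA, , drop = FALSE]; vb <- vb[okB, , drop = FALSE]
  if (!nrow(va) || !nrow(vb)) {
    out <- data.frame(gene_a = character(), gene_b = character(),
                      r = numeric(), p = numeric(), q = numeric())
    attr(out, "skipped") <- skipped
    return(out)
  }
  r <- cor(t(va), t(vb))
  r[r > 1] <- 1; r[r < -1] <- -1
  tstat <- r * sqrt((nS - 2) / pmax(1 - r^2, 1e-300))
  p <- 2 * pt(abs(tstat), df = nS - 2, lower.tail = FALSE)
  df <- data.frame(
    gene_a = rep(rownames(va), times = ncol(r)),
    gene_b = rep(colnames(r), each = nrow(r)),
    r = as.vector(r), p = as.vector(p),
    stringsAsFactors = FALSE
  )
  # one edge per unordered pair; self pairs are not edges
  df <- df[df$gene_a != df$gene_b, , drop = FALSE]
  key <- ifelse(df$gene_a < df$gene_b,
                paste(df$gene_a, df$gene_b), paste(df$gene_b, df$gene_a))
  df <- df[!duplicated(key), , drop = FALSE]
  df$q <- benjaminiHochberg(df$p)
  keep <- switch(sign,
    positive = df$r > rMin,
    negative = df$r < -rMin,
    any = abs(df$r) > rMin)
  out <- df[keep & df$q < fdrMax, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

# Seed handling: set a local RNG state and restore the caller's.
.setSeed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  old
}
.restoreSeed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
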