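#' @importFrom GenomicRanges findOverlaps pintersect granges
#' @importFrom IRanges width
#' @importFrom S4Vectors queryHits subjectHits
NULL

#' Map genes to recurrent focal copy-number fragments
#'
#' A gene hits a fragment iff their intervals overlap by at least 1 bp.
#' Gains and losses are reported per hit; a gene spanning several
#' fragments yields several hits. The hit set is independent of the input
#' ordering.
#'
#' @param ann GRanges gene annotation (see [readAnnotation()]).
#' @param fragments GRanges focal fragments with mcols `fragment_id`,
#'   `direction` (see [readFragments()]).
#' @return data.frame(gene_id, fragment_id, direction, overlap_bp).
#' @export
mapToFragments <- function(ann, fragments) {
  fragChroms <- unique(as.character(seqnames(fragments)))
  annChroms <- unique(as.character(seqnames(ann)))
  if (!all(fragChroms %in% annChroms))
    warning("fragment chromosome(s) absent from the annotation: ",
            paste(setdiff(fragChroms, annChroms), collapse = ", "))
  hits <- findOverlaps(ann, fragments, minoverlap = 1L,
                       ignore.strand = TRUE)
  qi <- queryHits(hits); si <- subjectHits(hits)
  ov <- width(pintersect(granges(ann[qi]), granges(fragments[si]),
                         ignore.strand = TRUE))
  out <- data.frame(
    gene_id = mcols(ann)$gene_id[qi],
    fragment_id = mcols(fragments)$fragment_id[si],
    direction = mcols(fragments)$direction[si],
    overlap_bp = ov,
    stringsAsFactors = FALSE
  )
  out[order(out$gene_id, out$fragment_id), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Per-gene copy-number alteration frequency
#'
#' Computed over tumor samples of a discrete copy-number matrix:
#' `gain_freq` is the fraction of tumor samples with a value > 0,
#' `loss_freq` with a value < 0. A gene is flagged high-frequency iff the
#' larger of the two is at least `minFraction` (>=, "at least 20%"); the
#' dominant direction is the larger frequency, with ties resolved to
#' gain.
#'
#' @param dcn OmicsMatrix with role `"discrete_cn"`.
#' @param minFraction high-frequency threshold.
#' @return data.frame(gene_id, gain_freq, loss_freq, high_frequency,
#'   direction).
#' @export
alterationFrequency <- function(dcn, minFraction = 0.2) {
  stopifnot(is(dcn, "OmicsMatrix"))
  if (omicsRole(dcn) != "discrete_cn") stop("role must be 'discrete_cn'")
  v <- omicsValues(subsetByClass(dcn, "tumor"))
  gain <- rowMeans(v > 0, na.rm = TRUE)
  loss <- rowMeans(v < 0, na.rm = TRUE)
  data.frame(
    gene_id = rownames(v),
    gain_freq = unname(gain),
    loss_freq = unname(loss),
    high_frequency = unname(pmax(gain, loss) >= minFraction),
    direction = ifelse(gain >= loss, "gain", "loss"),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

# Concordance of n bin means: (#concordant - #discordant) / C(n, 2),
# a pair (k < l) concordant iff m_l > m_k, discordant iff m_l < m_k.
.binConcordance <- function(binMeans) {
  n <- length(binMeans)
  conc <- 0L; disc <- 0L
  for (k in seq_len(n - 1L)) for (l in (k + 1L):n) {
    if (binMeans[l] > binMeans[k]) conc <- conc + 1L
    else if (binMeans[l] < binMeans[k]) disc <- disc + 1L
  }
  (conc - disc) / choose(n, 2)
}

# Equal-size bins of m samples into n bins; the last (m mod n) bins get
# one extra sample each, so no bin is empty.
.binSizes <- function(m, n) {
  base <- m %/% n; rem <- m %% n
  c(rep(base, n - rem), rep(base + 1L, rem))
}

#' Copy-number dosage sensitivity score (DSS)
#'
#' Quantifies how strongly a gene's expression tracks its copy number
#' across tumor samples by combining two components, each in \[-1, 1\]:
#'
#' * **linear**: the Pearson correlation `r(cn, expr)` over all samples;
#' * **monotonicity**: samples are sorted by copy number (stable sort,
#'   ties broken by sample name), split into `n` equal-size bins (the
#'   last `m mod n` bins receive one extra sample), and the per-bin mean
#'   expressions `m_1..m_n` are scored by pair concordance:
#'   `(#concordant - #discordant) / C(n, 2)` where a pair `(k < l)` is
#'   concordant iff `m_l > m_k`.
#'
#' `dss = w * linear + (1 - w) * monotonicity`. The score is only
#' defined for genes altered in more than `minAlteredFraction` of
#' samples, where a sample counts as altered iff its continuous copy
#' number falls outside `normalWindow`; otherwise a flagged record with
#' `defined = FALSE` is returned.
#'
#' @param cn named numeric, continuous copy number per tumor sample.
#' @param expr named numeric, expression over the same samples.
#' @param n number of monotonicity bins (>= 2, <= number of samples).
#' @param normalWindow copy-number interval treated as unaltered.
#' @param w weight of the linear component.
#' @param minAlteredFraction alteration gate (strict >).
#' @return one-row data.frame(dss, n_param, altered_fraction,
#'   n_used_samples, linear_component, monotonicity_component, defined).
#' @export
dosageSensitivityScore <- function(cn, expr, n = 6,
                                   normalWindow = c(-0.3, 0.3), w = 0.5,
                                   minAlteredFraction = 0.2) {
  if (length(cn) != length(expr)) stop("cn and expr must be paired")
  if (n < 2) stop("n must be >= 2")
  if (n > length(cn)) stop("n exceeds the number of samples")
  altered <- mean(cn < normalWindow[1] | cn > normalWindow[2])
  if (altered <= minAlteredFraction) {
    return(data.frame(dss = NA_real_, n_param = n,
                      altered_fraction = altered,
                      n_used_samples = length(cn),
                      linear_component = NA_real_,
                      monotonicity_component = NA_real_,
                      defined = FALSE))
  }
  lin <- suppressWarnings(cor(cn, expr))
  if (is.na(lin)) lin <- 0   # zero-variance expression
  ids <- if (!is.null(names(cn))) names(cn) else as.character(seq_along(cn))
  ord <- order(cn, ids)
  sizes <- .binSizes(length(cn), n)
  bin <- rep(seq_len(n), times = sizes)
  binMeans <- tapply(expr[ord], bin, mean)
  mono <- .binConcordance(as.numeric(binMeans))
  data.frame(dss = w * lin + (1 - w) * mono, n_param = n,
             altered_fraction = altered, n_used_samples = length(cn),
             linear_component = lin, monotonicity_component = mono,
             defined = TRUE)
}

#' DSS for every gene of paired copy-number / expression matrices
#'
#' Applies [dosageSensitivityScore()] gene-wise over the tumor samples
#' shared by a continuous copy-number matrix and an expression matrix.
#'
#' @param cnM OmicsMatrix with role `"copy_number"`.
#' @param exprM expression OmicsMatrix (log scale recommended).
#' @param geneIds genes to score (default: genes present in both).
#' @inheritParams dosageSensitivityScore
#' @return data.frame, one row per gene (gene_id + the
#'   [dosageSensitivityScore()] columns).
#' @export
dssTable <- function(cnM, exprM, geneIds = NULL, n = 6,
                     normalWindow = c(-0.3, 0.3), w = 0.5,
                     minAlteredFraction = 0.2) {
  cnT <- subsetByClass(cnM, "tumor")
  exT <- subsetByClass(exprM, "tumor")
  samples <- intersect(colnames(cnT), colnames(exT))
  if (length(samples) < n) stop("fewer shared tumor samples than bins")
  if (is.null(geneIds)) geneIds <- intersect(rownames(cnT), rownames(exT))
  cnV <- omicsValues(cnT)[, samples, drop = FALSE]
  exV <- omicsValues(exT)[, samples, drop = FALSE]
  rows <- lapply(geneIds, function(g)
    dosageSensitivityScore(cnV[g, ], exV[g, ], n = n,
                           normalWindow = normalWindow, w = w,
                           minAlteredFraction = minAlteredFraction))
  out <- do.call(rbind, rows)
  out <- cbind(gene_id = geneIds, out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Robustness of the DSS to the monotonicity parameter n
#'
#' Recomputes the DSS vector at each value of `nValues` and returns the
#' matrix of pairwise Spearman rank correlations over the genes whose
#' score is defined at every n.
#'
#' @inheritParams dssTable
#' @param nValues integer vector of bin counts (>= 2 values).
#' @return list(correlations = symmetric matrix, n_genes = number of
#'   commonly defined genes, dss = gene x n matrix of scores).
#' @export
dssRobustness <- function(cnM, exprM, nValues = c(5, 6, 7, 15),
                          geneIds = NULL, normalWindow = c(-0.3, 0.3),
                          w = 0.5, minAlteredFraction = 0.2) {
  if (length(nValues) < 2) stop("need >= 2 values of n")
  tabs <- lapply(nValues, function(n)
    dssTable(cnM, exprM, geneIds = geneIds, n = n,
             normalWindow = normalWindow, w = w,
             minAlteredFraction = minAlteredFraction))
  scores <- sapply(tabs, function(t) t$dss)
  rownames(scores) <- tabs[[1]]$gene_id
  colnames(scores) <- paste0("n", nValues)
  defined <- rowSums(is.na(scores)) == 0
  if (!any(defined)) stop("no gene has a defined DSS at every n")
  scores <- scores[defined, , drop = FALSE]
  rho <- cor(scores, method = "spearman")
  list(correlations = rho, n_genes = sum(defined), dss = scores)
}

#' Bin genes into k equal-width DSS groups
#'
#' The range `[min(dss), max(dss)]` is split into `k` equal-width
#' intervals, left-closed/right-open except the last, which is
#' right-closed so the maximum lands in group `k`. Labels are ordered
#' low to high. Undefined scores receive `NA`.
#'
#' @param dssTab data.frame from [dssTable()].
#' @param k number of groups.
#' @return integer vector of group labels (1..k) named by gene_id.
#' @export
assignDssGroups <- function(dssTab, k = 7) {
  x <- dssTab$dss
  ok <- !is.na(x)
  if (sum(ok) < k) stop("fewer defined scores than groups")
  lo <- min(x[ok]); hi <- max(x[ok])
  g <- rep(NA_integer_, length(x))
  if (lo == hi) {
    warning("all DSS identical: a single group is assigned")
    g[ok] <- 1L
  } else {
    width <- (hi - lo) / k
    g[ok] <- pmin(floor((x[ok] - lo) / width) + 1L, k)
  }
  setNames(g, dssTab$gene_id)
}
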