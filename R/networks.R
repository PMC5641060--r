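#' @importFrom GenomicRanges distance
NULL

#' Cis-acting lncRNA-PCG pairs
#'
#' Filters a co-expression edge list (SCNA lncRNAs x differentially
#' expressed PCGs, already screened at r > 0.5 / FDR < 0.05) down to
#' genomic neighbors: an edge is retained iff both genes are on the same
#' chromosome and the gap between their gene bodies is at most
#' `windowBp` (overlapping bodies count as distance 0). Edges whose
#' genes are absent from the annotation are skipped with a warning.
#'
#' @param coexpr data.frame(gene_a = lncRNA, gene_b = PCG, r, p, q) from
#'   [pearsonScreen()].
#' @param ann GRanges gene annotation.
#' @param windowBp neighborhood window in bp.
#' @return data.frame(lncrna_id, pcg_id, distance_bp, r, p, q).
#' @export
cisPairs <- function(coexpr, ann, windowBp = 300000) {
  if (!nrow(coexpr))
    return(data.frame(lncrna_id = character(), pcg_id = character(),
                      distance_bp = integer(), r = numeric(),
                      p = numeric(), q = numeric()))
  known <- coexpr$gene_a %in% names(ann) & coexpr$gene_b %in% names(ann)
  if (any(!known))
    warning(sum(!known), " edge(s) skipped: gene absent from annotation")
  ce <- coexpr[known, , drop = FALSE]
  d <- distance(granges(ann[ce$gene_a]), granges(ann[ce$gene_b]),
                ignore.strand = TRUE)
  keep <- !is.na(d) & d <= windowBp
  out <- data.frame(
    lncrna_id = ce$gene_a[keep], pcg_id = ce$gene_b[keep],
    distance_bp = as.integer(d[keep]),
    r = ce$r[keep], p = ce$p[keep], q = ce$q[keep],
    stringsAsFactors = FALSE, row.names = NULL
  )
  out
}

#' TF-lncRNA co-expression links
#'
#' [pearsonScreen()] with positive sign at the stricter transcription
#' factor threshold (`r > 0.6`, strict inequality).
#'
#' @param lncExpr,tfExpr expression OmicsMatrix objects over an
#'   identical ordered sample set.
#' @param rMin correlation threshold.
#' @param fdrMax BH FDR threshold.
#' @return data.frame(lncrna_id, tf_id, r, p, q).
#' @export
tfCoexpression <- function(lncExpr, tfExpr, rMin = 0.6, fdrMax = 0.05) {
  df <- pearsonScreen(lncExpr, tfExpr, rMin = rMin, fdrMax = fdrMax,
                      sign = "positive")
  out <- data.frame(lncrna_id = df$gene_a, tf_id = df$gene_b,
                    r = df$r, p = df$p, q = df$q,
                    stringsAsFactors = FALSE, row.names = NULL)
  out
}

#' Trans-acting lncRNA-TF-PCG triples
#'
#' For every co-expressed (lncRNA, TF) link, tests whether the lncRNA's
#' co-expressed PCGs overlap the TF's target genes more than expected by
#' chance, using the upper-tail hypergeometric probability `P(K >= k)`
#' with universe `N` (all eligible differentially expressed PCGs),
#' `M = |lncRNA co-expressed PCGs in the universe|`,
#' `L = |TF targets in the universe|` and `k` the overlap. P-values are
#' BH-corrected across all tested links; each significant link emits one
#' triple per overlap gene.
#'
#' @param lncCoexprPcgs named list: lncRNA id -> character vector of
#'   co-expressed PCG ids.
#' @param tfTargets named list: TF id -> character vector of target gene
#'   ids.
#' @param tfLinks data.frame(lncrna_id, tf_id, r, ...) from
#'   [tfCoexpression()].
#' @param universe character vector of eligible PCG ids.
#' @param fdrMax BH FDR threshold.
#' @return data.frame(lncrna_id, tf_id, pcg_id, tf_lnc_r, overlap_k,
#'   lnc_coexpr_M, tf_targets_L, universe_N, p, q).
#' @export
transTriples <- function(lncCoexprPcgs, tfTargets, tfLinks, universe,
                         fdrMax = 0.05) {
  if (!length(universe)) stop("empty universe")
  if (!nrow(tfLinks)) return(.emptyTriples())
  N <- length(universe)
  tests <- lapply(seq_len(nrow(tfLinks)), function(i) {
    lnc <- tfLinks$lncrna_id[i]; tf <- tfLinks$tf_id[i]
    Mset <- intersect(lncCoexprPcgs[[lnc]], universe)
    Lset <- intersect(tfTargets[[tf]], universe)
    ov <- intersect(Mset, Lset)
    list(lnc = lnc, tf = tf, r = tfLinks$r[i],
         M = length(Mset), L = length(Lset), k = length(ov), overlap = ov)
  })
  p <- vapply(tests, function(t)
    hypergeomTailP(t$k, N = N, M = t$M, L = t$L), numeric(1))
  q <- benjaminiHochberg(p)
  rows <- list()
  for (i in seq_along(tests)) {
    t <- tests[[i]]
    if (q[i] < fdrMax && t$k > 0) {
      rows[[length(rows) + 1L]] <- data.frame(
        lncrna_id = t$lnc, tf_id = t$tf, pcg_id = t$overlap,
        tf_lnc_r = t$r, overlap_k = t$k, lnc_coexpr_M = t$M,
        tf_targets_L = t$L, universe_N = N, p = p[i], q = q[i],
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) return(.emptyTriples())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.emptyTriples <- function() {
  data.frame(lncrna_id = character(), tf_id = character(),
             pcg_id = character(), tf_lnc_r = numeric(),
             overlap_k = integer(), lnc_coexpr_M = integer(),
             tf_targets_L = integer(), universe_N = integer(),
             p = numeric(), q = numeric())
}
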