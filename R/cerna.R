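#' Upper-tail hypergeometric probability, log-space
#'
#' `P(K >= k)` when drawing `M` balls without replacement from an urn of
#' `N` balls of which `L` are white and `K` counts the white draws:
#' `sum_{i=k}^{min(M,L)} C(L,i) C(N-L, M-i) / C(N,M)`, evaluated with
#' log-binomials for stability. `k <= 0` gives 1 by convention (empty
#' complement sum).
#'
#' @param k observed overlap (integer).
#' @param N universe size.
#' @param M size of the first set.
#' @param L size of the second set.
#' @return probability in \[0, 1\].
#' @export
hypergeomTailP <- function(k, N, M, L) {
  if (M > N || L > N || M < 0 || L < 0)
    stop("require 0 <= M, L <= N")
  if (k > min(M, L)) stop("overlap k cannot exceed min(M, L)")
  if (k <= 0) return(1)
  i <- k:min(M, L)
  p <- sum(exp(lchoose(L, i) + lchoose(N - L, M - i) - lchoose(N, M)))
  min(max(p, 0), 1)
}

#' Shared-miRNA significance of a candidate ceRNA pair
#'
#' The probability of observing at least `x` shared miRNAs between a
#' lncRNA with `M` interacting miRNAs and a PCG with `L` interacting
#' miRNAs out of a universe of `N` miRNAs:
#' `P = 1 - sum_{i=0}^{x-1} C(L,i) C(N-L, M-i) / C(N,M)`.
#' Symmetric in the roles of M and L; `x = 0` gives `P = 1`.
#'
#' @param N total number of miRNAs interacting with any lncRNA or PCG in
#'   the run.
#' @param M number of miRNAs interacting with the lncRNA.
#' @param L number of miRNAs interacting with the PCG.
#' @param x number of shared miRNAs.
#' @return probability in \[0, 1\].
#' @export
sharedMirnaPvalue <- function(N, M, L, x) {
  if (x < 0 || x > min(M, L)) stop("require 0 <= x <= min(M, L)")
  hypergeomTailP(x, N = N, M = M, L = L)
}

#' Filter candidate ceRNA pairs by shared negatively-correlated miRNAs
#'
#' For each co-expressed lncRNA-PCG pair, collects the miRNAs listed in
#' the interaction tables for both partners, tests every required
#' miRNA-gene Pearson correlation over tumor samples, BH-corrects across
#' all tests performed in this step, and keeps a shared miRNA iff it is
#' negatively correlated (`r < 0`, `q < fdrMax`) with both partners.
#' Pairs retaining at least one such miRNA proceed; shared-miRNA counts
#' (x, M, L) from the interaction table are attached for the
#' hypergeometric test. miRNAs present in the interaction table but
#' absent from the expression matrix are skipped and counted.
#'
#' @param pairs data.frame(gene_a = lncRNA, gene_b = PCG, r, ...) from
#'   [pearsonScreen()] (already r > 0.5, FDR < 0.05).
#' @param lncExpr,pcgExpr,mirExpr expression OmicsMatrix objects sharing
#'   an identical ordered sample set.
#' @param mirLnc data.frame(source_id = miRNA, target_id = lncRNA).
#' @param mirPcg data.frame(source_id = miRNA, target_id = PCG).
#' @param fdrMax BH FDR threshold for the miRNA correlations.
#' @return data.frame(lncrna_id, pcg_id, pair_r, x, M, L,
#'   shared_mirnas, surviving_mirnas); attribute `skipped_mirnas` counts
#'   interaction-table miRNAs without expression.
#' @export
negativeMirnaFilter <- function(pairs, lncExpr, pcgExpr, mirExpr,
                                mirLnc, mirPcg, fdrMax = 0.05) {
  empty <- data.frame(lncrna_id = character(), pcg_id = character(),
                      pair_r = numeric(), x = integer(), M = integer(),
                      L = integer(), shared_mirnas = character(),
                      surviving_mirnas = character())
  if (!nrow(pairs)) { attr(empty, "skipped_mirnas") <- 0L; return(empty) }
  stopifnot(identical(colnames(lncExpr), colnames(mirExpr)),
            identical(colnames(pcgExpr), colnames(mirExpr)))
  mirsOf <- function(tab, gene) unique(tab$source_id[tab$target_id == gene])
  exprMir <- rownames(mirExpr)
  skipped <- length(setdiff(unique(c(mirLnc$source_id, mirPcg$source_id)),
                            exprMir))

  cand <- lapply(seq_len(nrow(pairs)), function(i) {
    lnc <- pairs$gene_a[i]; pcg <- pairs$gene_b[i]
    mL <- mirsOf(mirLnc, lnc); mP <- mirsOf(mirPcg, pcg)
    shared <- intersect(mL, mP)
    list(lnc = lnc, pcg = pcg, r = pairs$r[i],
         M = length(mL), L = length(mP), shared = shared,
         testable = intersect(shared, exprMir))
  })
  cand <- Filter(function(c) length(c$shared) > 0, cand)
  if (!length(cand)) { attr(empty, "skipped_mirnas") <- skipped; return(empty) }

  # one correlation test per needed (miRNA, gene) combination
  tests <- unique(do.call(rbind, lapply(cand, function(c) {
    if (!length(c$testable)) return(NULL)
    rbind(data.frame(mir = c$testable, gene = c$lnc, mat = "lnc",
                     stringsAsFactors = FALSE),
          data.frame(mir = c$testable, gene = c$pcg, mat = "pcg",
                     stringsAsFactors = FALSE))
  })))
  if (is.null(tests) || !nrow(tests)) {
    attr(empty, "skipped_mirnas") <- skipped
    return(empty)
  }
  mv <- omicsValues(mirExpr); lv <- omicsValues(lncExpr)
  pv <- omicsValues(pcgExpr)
  m <- ncol(mv)
  rs <- numeric(nrow(tests)); ps <- numeric(nrow(tests))
  for (i in seq_len(nrow(tests))) {
    g <- if (tests$mat[i] == "lnc") lv[tests$gene[i], ] else pv[tests$gene[i], ]
    r <- suppressWarnings(cor(mv[tests$mir[i], ], g))
    if (is.na(r)) r <- 0
    tt <- r * sqrt((m - 2) / pmax(1 - r^2, 1e-300))
    rs[i] <- r
    ps[i] <- 2 * pt(abs(tt), df = m - 2, lower.tail = FALSE)
  }
  qs <- benjaminiHochberg(ps)
  key <- paste(tests$mir, tests$gene, tests$mat)
  pass <- setNames(rs < 0 & qs < fdrMax, key)

  rows <- lapply(cand, function(c) {
    ok <- c$testable[
      pass[paste(c$testable, c$lnc, "lnc")] &
      pass[paste(c$testable, c$pcg, "pcg")]
    ]
    ok <- ok[!is.na(ok)]
    if (!length(ok)) return(NULL)
    data.frame(lncrna_id = c$lnc, pcg_id = c$pcg, pair_r = c$r,
               x = length(c$shared), M = c$M, L = c$L,
               shared_mirnas = paste(sort(c$shared), collapse = ","),
               surviving_mirnas = paste(sort(ok), collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows) else empty
  rownames(out) <- NULL
  attr(out, "skipped_mirnas") <- skipped
  out
}

#' Build the ceRNA network from filtered candidates
#'
#' Applies the shared-miRNA hypergeometric test to every candidate pair
#' (x, M, L from the interaction tables; universe `N` = miRNAs
#' interacting with any lncRNA or PCG present in the run), BH-corrects
#' across candidates, and retains pairs with both `p < pMax` and
#' `q < fdrMax`. The retained edge set does not depend on candidate
#' order.
#'
#' @param candidates data.frame from [negativeMirnaFilter()].
#' @param N miRNA universe size.
#' @param pMax raw p-value threshold.
#' @param fdrMax BH FDR threshold.
#' @return data.frame(lncrna_id, pcg_id, x, M, L, N, pair_r,
#'   shared_mirnas, surviving_mirnas, p, q), retained edges only, sorted
#'   by (lncrna_id, pcg_id); `degree` attribute = per-node edge counts.
#' @export
buildCernaNetwork <- function(candidates, N, pMax = 0.05,
                              fdrMax = 0.05) {
  if (!nrow(candidates)) {
    warning("no ceRNA candidates: empty network")
    out <- data.frame(lncrna_id = character(), pcg_id = character(),
                      x = integer(), M = integer(), L = integer(),
                      N = integer(), pair_r = numeric(),
                      shared_mirnas = character(),
                      surviving_mirnas = character(),
                      p = numeric(), q = numeric())
    attr(out, "degree") <- integer(0)
    return(out)
  }
  ord <- order(candidates$lncrna_id, candidates$pcg_id)
  cd <- candidates[ord, , drop = FALSE]
  p <- vapply(seq_len(nrow(cd)), function(i)
    sharedMirnaPvalue(N, cd$M[i], cd$L[i], cd$x[i]), numeric(1))
  q <- benjaminiHochberg(p)
  keep <- p < pMax & q < fdrMax
  out <- data.frame(
    lncrna_id = cd$lncrna_id[keep], pcg_id = cd$pcg_id[keep],
    x = cd$x[keep], M = cd$M[keep], L = cd$L[keep], N = N,
    pair_r = cd$pair_r[keep],
    shared_mirnas = cd$shared_mirnas[keep],
    surviving_mirnas = cd$surviving_mirnas[keep],
    p = p[keep], q = q[keep],
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "degree") <- table(c(out$lncrna_id, out$pcg_id))
  out
}

#' miRNA universe size for the ceRNA test
#'
#' Number of distinct miRNAs with at least one interaction to a lncRNA
#' or PCG present in the run.
#'
#' @param mirLnc,mirPcg interaction data.frames (source_id = miRNA).
#' @param lncIds,pcgIds gene ids present in the run (NULL = all).
#' @return integer universe size.
#' @export
mirnaUniverseSize <- function(mirLnc, mirPcg, lncIds = NULL,
                              pcgIds = NULL) {
  a <- mirLnc; b <- mirPcg
  if (!is.null(lncIds)) a <- a[a$target_id %in% lncIds, , drop = FALSE]
  if (!is.null(pcgIds)) b <- b[b$target_id %in% pcgIds, , drop = FALSE]
  length(unique(c(a$source_id, b$source_id)))
}
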