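#' Hypergeometric GO over-representation of a gene set
#'
#' Tests each term with at least one hit in the set and at least
#' `minTermSize` annotated genes in the universe, using the upper-tail
#' hypergeometric probability `P(K >= k)` with universe size `N_u`, set
#' size `K`, term size `L_t` and hit count `k`; BH correction across
#' tested terms.
#'
#' @param geneSet character vector of gene ids (subset of `universe`).
#' @param goTable data.frame(gene_id, term_id, term_name).
#' @param universe character vector of background gene ids.
#' @param fdrMax BH FDR threshold for the `significant` flag.
#' @param minTermSize smallest term tested.
#' @return data.frame(term_id, term_name, k, K, L_t, N_u, p, q,
#'   significant), all tested terms.
#' @export
goEnrichment <- function(geneSet, goTable, universe, fdrMax = 0.05,
                         minTermSize = 3) {
  if (!length(universe)) stop("empty universe")
  empty <- data.frame(term_id = character(), term_name = character(),
                      k = integer(), K = integer(), L_t = integer(),
                      N_u = integer(), p = numeric(), q = numeric(),
                      significant = logical())
  geneSet <- intersect(unique(geneSet), universe)
  if (!length(geneSet)) return(empty)
  go <- goTable[goTable$gene_id %in% universe, , drop = FALSE]
  if (!nrow(go)) return(empty)
  termGenes <- split(go$gene_id, go$term_id)
  termNames <- go$term_name[!duplicated(go$term_id)]
  names(termNames) <- go$term_id[!duplicated(go$term_id)]
  Nu <- length(universe); K <- length(geneSet)
  rows <- lapply(names(termGenes), function(term) {
    tg <- unique(termGenes[[term]])
    Lt <- length(tg)
    k <- length(intersect(geneSet, tg))
    if (k < 1 || Lt < minTermSize) return(NULL)
    data.frame(term_id = term, term_name = unname(termNames[term]),
               k = k, K = K, L_t = Lt, N_u = Nu,
               p = hypergeomTailP(k, N = Nu, M = K, L = Lt),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$term_id), , drop = FALSE]
  out$q <- benjaminiHochberg(out$p)
  out$significant <- out$q < fdrMax
  rownames(out) <- NULL
  out
}

#' Functional profiles of DSS groups
#'
#' For each dosage-sensitivity group, the union of PCGs co-expressed
#' with the group's lncRNAs is enriched against the GO table; the
#' summary matrix reports `-log10(q)` per (group, term) for all terms
#' significant in at least one group. Groups with no co-expressed PCG
#' are skipped.
#'
#' @param groups named integer vector from [assignDssGroups()]
#'   (lncRNA id -> group label).
#' @param coexpr data.frame(gene_a = lncRNA, gene_b = PCG, ...).
#' @param goTable data.frame(gene_id, term_id, term_name).
#' @param universe background PCG ids.
#' @param fdrMax BH FDR threshold.
#' @return list(profiles = groups x terms matrix of -log10(q),
#'   tables = per-group enrichment data.frames, skipped = labels of
#'   empty groups).
#' @export
dssGroupProfiles <- function(groups, coexpr, goTable, universe,
                             fdrMax = 0.05) {
  labs <- sort(unique(groups[!is.na(groups)]))
  tables <- list(); skipped <- integer(0)
  for (g in labs) {
    lncs <- names(groups)[!is.na(groups) & groups == g]
    pcgs <- unique(coexpr$gene_b[coexpr$gene_a %in% lncs])
    pcgs <- intersect(pcgs, universe)
    if (!length(pcgs)) { skipped <- c(skipped, g); next }
    tables[[as.character(g)]] <-
      goEnrichment(pcgs, goTable, universe, fdrMax = fdrMax)
  }
  sigTerms <- sort(unique(unlist(lapply(tables, function(t)
    t$term_id[t$significant]))))
  prof <- matrix(0, nrow = length(tables), ncol = length(sigTerms),
                 dimnames = list(names(tables), sigTerms))
  for (gn in names(tables)) {
    t <- tables[[gn]]
    hit <- t$term_id %in% sigTerms
    prof[gn, t$term_id[hit]] <- -log10(pmax(t$q[hit], 1e-300))
  }
  list(profiles = prof, tables = tables, skipped = skipped)
}

#' lncRNA-function bipartite network
#'
#' Per lncRNA, enriches its regulatory target set (union of cis targets
#' and trans targets) against the GO table; an edge lncRNA-term is
#' emitted iff `q < fdrMax`. Node annotation carries the lncRNA's DSS
#' when supplied.
#'
#' @param lncTargets named list: lncRNA id -> character vector of target
#'   gene ids.
#' @param goTable data.frame(gene_id, term_id, term_name).
#' @param universe background gene ids.
#' @param dss optional named numeric of DSS values per lncRNA.
#' @param fdrMax BH FDR threshold.
#' @return data.frame(lncrna_id, term_id, term_name, p, q, dss).
#' @export
lncrnaFunctionNetwork <- function(lncTargets, goTable, universe,
                                  dss = NULL, fdrMax = 0.05) {
  rows <- lapply(names(lncTargets), function(lnc) {
    tg <- lncTargets[[lnc]]
    if (!length(tg)) return(NULL)
    enr <- goEnrichment(tg, goTable, universe, fdrMax = fdrMax)
    enr <- enr[enr$significant, , drop = FALSE]
    if (!nrow(enr)) return(NULL)
    data.frame(lncrna_id = lnc, term_id = enr$term_id,
               term_name = enr$term_name, p = enr$p, q = enr$q,
               dss = if (!is.null(dss) && lnc %in% names(dss))
                       unname(dss[lnc]) else NA_real_,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(lncrna_id = character(), term_id = character(),
                      term_name = character(), p = numeric(),
                      q = numeric(), dss = numeric()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
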