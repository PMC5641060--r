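#' Pipeline parameters with the study's default thresholds
#'
#' Every tunable threshold of the pipeline, overridable by name:
#' copy-number normal window \[-0.3, 0.3\], high-frequency and DSS
#' alteration gates 0.2, DE fold change 2 / FDR 0.05, methylation fold
#' change 2 / FDR 0.01, lncRNA-PCG co-expression r 0.5, TF co-expression
#' r 0.6, cis window 300 kb, ceRNA p and FDR 0.05, GO FDR 0.05,
#' survival p 0.05, DSS bins n = 6 (robustness sweep 5, 6, 7, 15) with
#' linear weight w = 0.5, 7 DSS groups.
#'
#' @param ... overrides by name.
#' @return a named list of class `PipelineParams`.
#' @export
pipelineParams <- function(...) {
  par <- list(
    uq_target = 1000, max_missing_fraction = 0.3,
    pcg_pseudocount = 2, lncrna_pseudocount = 0.05,
    mirna_pseudocount = 0.05,
    normal_window = c(-0.3, 0.3),
    high_freq_min = 0.2, dss_min_altered = 0.2,
    dss_n = 6, dss_n_robustness = c(5, 6, 7, 15), dss_w = 0.5,
    dss_groups = 7,
    de_fc = 2, de_fdr = 0.05, sam_nperm = 200,
    meth_fc = 2, meth_fdr = 0.01, meth_corr_p = 0.05,
    promoter_bp = 2000,
    coexpr_r = 0.5, coexpr_fdr = 0.05,
    tf_r = 0.6, tf_fdr = 0.05,
    cis_window = 300000,
    trans_fdr = 0.05,
    cerna_p = 0.05, cerna_fdr = 0.05, mirna_corr_fdr = 0.05,
    go_fdr = 0.05, go_min_term = 3,
    survival_p = 0.05
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(par))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  par[names(over)] <- over
  class(par) <- "PipelineParams"
  par
}

.ALL_STAGES <- c("preprocess", "dss", "de", "meth", "coexpr", "cis",
                 "trans", "cerna", "enrich", "prognosis", "drugs")

#' Run the full SCNA-lncRNA analysis pipeline
#'
#' Executes the stages in order on a cohort (an in-memory
#' `SyntheticCohort` from [generateCohort()] or a directory written by
#' [writeCohort()]): preprocessing (upper-quartile normalization,
#' missing/low-expression filters, log2), fragment mapping and dosage
#' sensitivity scoring, SAM differential expression (PCGs and lncRNAs),
#' promoter methylation analysis, lncRNA-PCG co-expression, cis pairs,
#' trans triples, ceRNA network, DSS-group enrichment and the
#' lncRNA-function network, prognostic risk models of the ceRNA
#' modules, and drug nomination. Each stage's tables are written to
#' `outDir` before the next stage begins; a run manifest with stage
#' record counts, input checksums and the seed is written as JSON.
#' Correlation screens and risk models use tumor samples.
#'
#' @param cohort `SyntheticCohort` or a cohort directory path.
#' @param outDir output directory for the stage TSVs and manifest.
#' @param params a [pipelineParams()].
#' @param stages subset of stages to run (upstream results must already
#'   be present in the returned object when skipping; the default runs
#'   everything).
#' @param seed seed for the permutation tests.
#' @return invisibly, a list with one element per stage plus `manifest`.
#' @export
runPipeline <- function(cohort, outDir, params = pipelineParams(),
                        stages = .ALL_STAGES, seed = 1) {
  t0 <- Sys.time()
  inputChecksums <- NULL
  if (is.character(cohort)) {
    if (!dir.exists(cohort)) stop("cohort directory not found: ", cohort)
    need <- file.path(cohort, "clinical.tsv")
    if ("prognosis" %in% stages && !file.exists(need))
      stop("prognosis stage enabled but clinical file missing: ", need)
    files <- sort(list.files(cohort, full.names = TRUE))
    inputChecksums <- as.list(tools::md5sum(files))
    names(inputChecksums) <- basename(files)
    cohort <- readCohort(cohort)
  }
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  fp <- function(f) file.path(outDir, f)
  stages <- match.arg(stages, .ALL_STAGES, several.ok = TRUE)
  res <- list()
  counts <- list()
  p <- params
  ann <- cohort$annotation
  mats <- cohort$matrices

  ## preprocess ---------------------------------------------------------
  if ("preprocess" %in% stages) {
    pcgLin <- filterMissingGenes(
      upperQuartileNormalize(mats$pcg_expr, p$uq_target),
      p$max_missing_fraction)
    tfLin <- upperQuartileNormalize(mats$tf_expr, p$uq_target)
    lncLin <- filterLowLncrna(mats$lncrna_expr)
    mirLin <- mats$mirna_expr
    pre <- list(
      pcg_lin = pcgLin, lnc_lin = lncLin,
      pcg_log = logTransform(pcgLin, p$pcg_pseudocount),
      lnc_log = logTransform(lncLin, p$lncrna_pseudocount),
      tf_log = logTransform(tfLin, p$pcg_pseudocount),
      mir_log = logTransform(mirLin, p$mirna_pseudocount),
      mir_lin = mirLin
    )
    res$preprocess <- pre
    counts$preprocess <- c(pcgs_kept = nrow(pre$pcg_log),
                           lncrnas_kept = nrow(pre$lnc_log))
    writeMatrix(pre$pcg_log, fp("pcg_log2.tsv"))
    writeMatrix(pre$lnc_log, fp("lncrna_log2.tsv"))
  }
  pre <- res$preprocess

  ## dss ----------------------------------------------------------------
  if ("dss" %in% stages) {
    lncAnn <- ann[mcols(ann)$biotype == "lncRNA"]
    hits <- mapToFragments(lncAnn, cohort$fragments)
    freq <- alterationFrequency(mats$discrete_cn, p$high_freq_min)
    scnaLnc <- intersect(freq$gene_id[freq$high_frequency],
                         rownames(pre$lnc_log))
    dss <- dssTable(mats$copy_number, pre$lnc_log, geneIds = scnaLnc,
                    n = p$dss_n, normalWindow = p$normal_window,
                    w = p$dss_w, minAlteredFraction = p$dss_min_altered)
    groups <- assignDssGroups(dss, k = p$dss_groups)
    res$dss <- list(fragment_hits = hits, alteration_freq = freq,
                    scna_lncrnas = scnaLnc, table = dss,
                    groups = groups)
    counts$dss <- c(fragment_hits = nrow(hits),
                    scna_lncrnas = length(scnaLnc),
                    defined_dss = sum(dss$defined))
    writeEdges(hits, fp("fragment_hits.tsv"))
    writeEdges(dss, fp("dss.tsv"))
  }

  ## de -----------------------------------------------------------------
  if ("de" %in% stages) {
    dePcg <- samDifferentialExpression(pre$pcg_log, pre$pcg_lin,
                                       nPerm = p$sam_nperm,
                                       fcMin = p$de_fc,
                                       fdrMax = p$de_fdr, seed = seed)
    deLnc <- samDifferentialExpression(pre$lnc_log, pre$lnc_lin,
                                       nPerm = p$sam_nperm,
                                       fcMin = p$de_fc,
                                       fdrMax = p$de_fdr,
                                       seed = seed + 1)
    res$de <- list(pcg = dePcg, lncrna = deLnc)
    counts$de <- c(de_pcgs = sum(dePcg$de), de_lncrnas = sum(deLnc$de))
    writeEdges(dePcg, fp("de_pcg.tsv"))
    writeEdges(deLnc, fp("de_lncrna.tsv"))
  }

  ## meth ---------------------------------------------------------------
  if ("meth" %in% stages) {
    lncAnn <- ann[mcols(ann)$biotype == "lncRNA"]
    prom <- promoterRegions(lncAnn, p$promoter_bp)
    pmap <- mapProbes(cohort$probes, prom)
    gb <- geneBeta(mats$probe_beta, pmap)
    dm <- differentialMethylation(gb, fcMin = p$meth_fc,
                                  fdrMax = p$meth_fdr)
    hyper <- dm$gene_id[dm$called & dm$state == "hyper"]
    expressed <- intersect(hyper, rownames(pre$lnc_log))
    cmp <- if (length(expressed) &&
               length(setdiff(rownames(pre$lnc_log), expressed)))
      compareExpressionGroups(pre$lnc_log, expressed,
                              setdiff(rownames(pre$lnc_log), expressed))
    else NULL
    corr <- methExprCorrelation(gb[intersect(rownames(gb),
                                             rownames(pre$lnc_log)), ],
                                pre$lnc_log, pMax = p$meth_corr_p)
    res$meth <- list(probe_map = pmap, gene_beta = gb, dm = dm,
                     hyper = hyper, expression_comparison = cmp,
                     correlation = corr)
    counts$meth <- c(mapped_probes = nrow(pmap),
                     hyper = sum(dm$called & dm$state == "hyper"),
                     hypo = sum(dm$called & dm$state == "hypo"),
                     negative_corr = sum(corr$negative))
    writeEdges(dm, fp("differential_methylation.tsv"))
    writeEdges(corr, fp("meth_expr_correlation.tsv"))
  }

  ## coexpr -------------------------------------------------------------
  if ("coexpr" %in% stages) {
    scna <- res$dss$scna_lncrnas
    deP <- res$de$pcg$gene_id[res$de$pcg$de]
    lncT <- subsetByClass(pre$lnc_log[scna, ], "tumor")
    pcgT <- subsetByClass(pre$pcg_log[deP, ], "tumor")
    coex <- pearsonScreen(lncT, pcgT, rMin = p$coexpr_r,
                          fdrMax = p$coexpr_fdr, sign = "positive")
    res$coexpr <- coex
    counts$coexpr <- c(pairs = nrow(coex))
    writeEdges(coex, fp("coexpression.tsv"))
  }

  ## cis ----------------------------------------------------------------
  if ("cis" %in% stages) {
    cis <- cisPairs(res$coexpr, ann, windowBp = p$cis_window)
    res$cis <- cis
    counts$cis <- c(pairs = nrow(cis))
    writeEdges(cis, fp("cis_pairs.tsv"))
  }

  ## trans --------------------------------------------------------------
  if ("trans" %in% stages) {
    scna <- res$dss$scna_lncrnas
    deP <- res$de$pcg$gene_id[res$de$pcg$de]
    lncT <- subsetByClass(pre$lnc_log[scna, ], "tumor")
    tfT <- subsetByClass(pre$tf_log, "tumor")
    links <- tfCoexpression(lncT, tfT, rMin = p$tf_r, fdrMax = p$tf_fdr)
    coex <- res$coexpr
    lncSets <- split(coex$gene_b, coex$gene_a)
    tg <- cohort$interactions$tf_gene
    tfSets <- split(tg$target_id, tg$source_id)
    triples <- if (length(deP))
      transTriples(lncSets, tfSets, links, universe = deP,
                   fdrMax = p$trans_fdr)
    else .emptyTriples()
    res$trans <- list(tf_links = links, triples = triples)
    counts$trans <- c(tf_links = nrow(links), triples = nrow(triples))
    writeEdges(triples, fp("trans_triples.tsv"))
  }

  ## cerna --------------------------------------------------------------
  if ("cerna" %in% stages) {
    coex <- res$coexpr
    lncT <- subsetByClass(pre$lnc_log, "tumor")
    pcgT <- subsetByClass(pre$pcg_log, "tumor")
    mirT <- subsetByClass(pre$mir_log, "tumor")
    cands <- negativeMirnaFilter(coex, lncT, pcgT, mirT,
                                 cohort$interactions$mir_lnc,
                                 cohort$interactions$mir_pcg,
                                 fdrMax = p$mirna_corr_fdr)
    N <- mirnaUniverseSize(cohort$interactions$mir_lnc,
                           cohort$interactions$mir_pcg,
                           lncIds = rownames(pre$lnc_log),
                           pcgIds = rownames(pre$pcg_log))
    net <- if (nrow(cands)) buildCernaNetwork(cands, N,
                                              pMax = p$cerna_p,
                                              fdrMax = p$cerna_fdr)
           else suppressWarnings(buildCernaNetwork(cands, max(N, 1L)))
    # DE directions of the partners, for drug nomination
    dirOf <- function(tab, g) {
      i <- match(g, tab$gene_id)
      ifelse(is.na(i), NA_character_, tab$direction[i])
    }
    if (nrow(net)) {
      net$lnc_direction <- dirOf(res$de$lncrna, net$lncrna_id)
      net$pcg_direction <- dirOf(res$de$pcg, net$pcg_id)
    }
    res$cerna <- net
    counts$cerna <- c(candidates = nrow(cands), edges = nrow(net))
    writeEdges(net, fp("cerna_network.tsv"))
  }

  ## enrich -------------------------------------------------------------
  if ("enrich" %in% stages) {
    universe <- rownames(pre$pcg_log)
    prof <- dssGroupProfiles(res$dss$groups, res$coexpr,
                             cohort$go_table, universe,
                             fdrMax = p$go_fdr)
    targets <- c(split(res$cis$pcg_id, res$cis$lncrna_id),
                 split(res$trans$triples$pcg_id,
                       res$trans$triples$lncrna_id))
    if (length(targets)) {
      targets <- tapply(unlist(targets, use.names = FALSE),
                        rep(names(targets), lengths(targets)),
                        function(x) unique(x), simplify = FALSE)
    }
    dssVec <- setNames(res$dss$table$dss, res$dss$table$gene_id)
    fnet <- lncrnaFunctionNetwork(as.list(targets), cohort$go_table,
                                  universe, dss = dssVec,
                                  fdrMax = p$go_fdr)
    res$enrich <- list(group_profiles = prof, function_network = fnet)
    counts$enrich <- c(
      profiled_groups = length(prof$tables),
      significant_terms = ncol(prof$profiles),
      function_edges = nrow(fnet))
    writeEdges(fnet, fp("function_network.tsv"))
  }

  ## prognosis ----------------------------------------------------------
  if ("prognosis" %in% stages) {
    net <- res$cerna
    clinical <- cohort$clinical
    exprOf <- function(g) {
      for (m in list(pre$lnc_log, pre$pcg_log, pre$mir_log)) {
        if (g %in% rownames(m))
          return(omicsValues(subsetByClass(m, "tumor"))[g, ])
      }
      stop("node missing expression: ", g)
    }
    models <- list()
    if (nrow(net)) {
      for (i in seq_len(nrow(net))) {
        mirs <- strsplit(net$surviving_mirnas[i], ",")[[1]]
        models[[paste(net$lncrna_id[i], net$pcg_id[i], sep = "~")]] <-
          tripleRisk(net$lncrna_id[i], mirs, net$pcg_id[i], exprOf,
                     clinical)
      }
    }
    pvals <- vapply(models, logrankP, numeric(1))
    summaryTab <- data.frame(
      triple = names(models),
      logrank_p = unname(pvals),
      logrank_q = if (length(pvals)) benjaminiHochberg(pvals) else numeric(0),
      significant = unname(!is.na(pvals) & pvals < p$survival_p),
      stringsAsFactors = FALSE)
    res$prognosis <- list(models = models, summary = summaryTab)
    counts$prognosis <- c(triples_tested = length(models),
                          significant = sum(summaryTab$significant))
    writeEdges(summaryTab, fp("prognosis.tsv"))
    if (length(models)) {
      best <- models[[which.min(pvals)]]
      if (!best@degenerate)
        writeEdges(kmCoordinates(best, clinical), fp("km_best.tsv"))
    }
  }

  ## drugs --------------------------------------------------------------
  if ("drugs" %in% stages) {
    drugs <- drugCandidates(res$cerna, cohort$interactions$drug_mirna)
    res$drugs <- drugs
    counts$drugs <- c(rows = nrow(drugs),
                      candidates = sum(drugs$rationale ==
                                       "suppresses_overexpressed_partners"))
    writeEdges(drugs, fp("drug_candidates.tsv"))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("lncSCNA")),
    seed = seed,
    params = unclass(params),
    stage_counts = lapply(counts, as.list),
    input_checksums = inputChecksums,
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(manifest, fp("run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}
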