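#' Configuration of the synthetic tumor cohort
#'
#' Returns the default study conditions of the generator, optionally
#' overridden. Sizes are a desk-scale rendering of a TCGA-style tumor
#' cohort: 100 tumor and 30 normal samples; 80 lncRNAs, 150
#' protein-coding genes (6 of them transcription factors) and 30
#' miRNAs; 10 focal fragments (5 gains, 5 losses) each hosting 4
#' lncRNAs.
#'
#' Planted signals (all recorded in the ground-truth manifest):
#' * `n_planted_dss` dosage-sensitive lncRNAs whose log2 expression
#'   follows `mu + s * cn` with slope `s` drawn uniformly from
#'   `dosage_slope_range`;
#' * `n_planted_de` differentially expressed PCGs (and 10 DE lncRNAs)
#'   with 4-fold tumor shifts, split between up and down;
#' * `n_planted_cerna` lncRNA-PCG ceRNA pairs sharing
#'   `mirnas_per_triple` miRNAs through a latent factor (partners load
#'   +1, shared miRNAs load -0.9), giving pair r > 0.5 and negative
#'   miRNA correlations at the default noise;
#' * `n_planted_hypermeth` promoter-hypermethylated lncRNAs (tumor mean
#'   beta > 2x normal) whose expression is negatively coupled to beta;
#' * cis pairs: `n_planted_cis` dosage-sensitive lncRNAs each get a DE
#'   PCG neighbor 50 kb away sharing the copy-number signal;
#' * one trans triple: a fragment lncRNA and a TF share a latent factor
#'   with 8 DE target PCGs listed in the TF-target table;
#' * survival hazards `exp(sum coef * z)` on the first ceRNA triple
#'   with coefficients (+0.7 lncRNA, -0.7 each miRNA, +0.7 PCG),
#'   exponential event times and administrative censoring at
#'   `censor_time` days (roughly 40-60% events).
#'
#' Expression noise is Gaussian on the log2 scale (`noise_sd`); matrices
#' are emitted on the linear scale so the pipeline's own pseudocount /
#' log2 transforms are exercised. One RNG stream is derived from the
#' master seed per data layer, so regenerating one layer never perturbs
#' another.
#'
#' @param ... overrides of the defaults, by name.
#' @return a list of class `CohortConfig`.
#' @export
cohortConfig <- function(...) {
  cfg <- list(
    n_tumor = 100L, n_normal = 30L,
    n_lncrna = 80L, n_pcg = 150L, n_tf = 6L, n_mirna = 30L,
    n_fragments = 10L, lncrna_per_fragment = 4L,
    fragment_bp = 500000L, alteration_fraction = 0.5,
    cn_background = 0.25, cn_alt_min = 0.4, cn_alt_max = 1.4,
    dosage_slope_range = c(0.15, 1.2),
    noise_sd = 0.3, base_expr = 6,
    n_planted_dss = 30L, n_planted_de = 30L, n_planted_de_lnc = 10L,
    de_log2fc = 2,
    n_planted_cerna = 5L, mirnas_per_triple = 4L,
    n_planted_cis = 5L, cis_offset_bp = 50000L,
    n_trans_targets = 8L, n_tf_extra_targets = 4L,
    n_planted_hypermeth = 8L, meth_coupling = 2,
    n_probes_per_gene = 2L,
    n_go_terms = 20L,
    hazard_coefs = c(lncrna = 0.7, mirna = -0.7, pcg = 0.7),
    base_hazard = 5e-4, censor_time = 1000,
    n_background_interactions = 60L,
    seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  class(cfg) <- "CohortConfig"
  .validateConfig(cfg)
  cfg
}

.validateConfig <- function(cfg) {
  counts <- c("n_tumor", "n_normal", "n_lncrna", "n_pcg", "n_tf",
              "n_mirna", "n_fragments")
  for (f in counts) if (cfg[[f]] < 1) stop(f, " must be positive")
  if (cfg$alteration_fraction <= 0 || cfg$alteration_fraction > 1)
    stop("alteration_fraction must be in (0, 1]")
  nFrag <- cfg$n_fragments * cfg$lncrna_per_fragment
  if (cfg$n_planted_dss + cfg$n_planted_cerna + 1L > nFrag)
    stop("fragments cannot host all planted fragment lncRNAs")
  if (nFrag + cfg$n_planted_hypermeth > cfg$n_lncrna)
    stop("n_lncrna too small for the planted layout")
  if (cfg$n_planted_cis > cfg$n_planted_dss)
    stop("planted cis pairs require as many dosage-sensitive lncRNAs")
  if (cfg$n_planted_cerna * cfg$mirnas_per_triple > cfg$n_mirna)
    stop("planted ceRNA triples need more miRNAs than exist")
  if (cfg$n_trans_targets + cfg$n_tf_extra_targets + cfg$n_planted_cis +
      cfg$n_planted_cerna > cfg$n_planted_de)
    stop("n_planted_de too small to cover cis/trans/ceRNA partners")
  if (cfg$n_planted_de > cfg$n_pcg) stop("n_planted_de exceeds n_pcg")
  invisible(TRUE)
}

# Independent RNG stream per data layer, derived from the master seed.
.layerSeed <- function(seed, layer) {
  offs <- c(genome = 101L, cn = 202L, expression = 303L,
            methylation = 404L, interactions = 505L, survival = 606L,
            go = 707L)
  (as.integer(seed) * 1009L + offs[[layer]]) %% .Machine$integer.max
}

#' Generate a complete synthetic cohort with planted ground truth
#'
#' Emits a gene annotation (GRanges), focal fragments, continuous and
#' discrete copy number, linear-scale expression matrices (lncRNA, PCG,
#' miRNA), probe-level promoter methylation, interaction tables
#' (miRNA-lncRNA, miRNA-PCG, TF-gene, drug-miRNA), a GO annotation
#' table, a clinical survival table, and a ground-truth manifest naming
#' every planted element. Identical config and seed give bit-identical
#' output.
#'
#' @param config a [cohortConfig()].
#' @return a list of class `SyntheticCohort`; see Details of
#'   [cohortConfig()] for the planted structure, and `$truth` for the
#'   manifest.
#' @export
generateCohort <- function(config = cohortConfig()) {
  stopifnot(inherits(config, "CohortConfig"))
  cfg <- config
  samples <- c(sprintf("T%03d", seq_len(cfg$n_tumor)),
               sprintf("N%03d", seq_len(cfg$n_normal)))
  sclass <- setNames(rep(c("tumor", "normal"),
                         c(cfg$n_tumor, cfg$n_normal)), samples)
  isTumor <- sclass == "tumor"

  ## ---- genome layer: fragments and gene placement -------------------
  callerSeed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(.restoreSeed(callerSeed), add = TRUE)
  set.seed(.layerSeed(cfg$seed, "genome"))

  nFragLnc <- cfg$n_fragments * cfg$lncrna_per_fragment
  lncIds <- sprintf("LNC%03d", seq_len(cfg$n_lncrna))
  pcgIds <- sprintf("PCG%03d", seq_len(cfg$n_pcg))
  tfIds <- sprintf("TF%02d", seq_len(cfg$n_tf))
  mirIds <- sprintf("MIR%03d", seq_len(cfg$n_mirna))

  # fragments tiled along chr1, 2 Mb apart
  fragStart <- (seq_len(cfg$n_fragments) - 1L) * 2000000L + 1000001L
  fragments <- GRanges("chr1",
                       IRanges(fragStart, fragStart + cfg$fragment_bp - 1L))
  mcols(fragments)$fragment_id <- sprintf("FRAG%02d", seq_len(cfg$n_fragments))
  mcols(fragments)$direction <- rep(c("gain", "loss"),
                                    length.out = cfg$n_fragments)
  names(fragments) <- mcols(fragments)$fragment_id

  # fragment lncRNAs: planted dosage-sensitive first, then ceRNA, trans,
  # remaining flat
  fragLnc <- lncIds[seq_len(nFragLnc)]
  dssLnc <- fragLnc[seq_len(cfg$n_planted_dss)]
  cisLnc <- dssLnc[seq_len(cfg$n_planted_cis)]
  cernaLnc <- fragLnc[cfg$n_planted_dss + seq_len(cfg$n_planted_cerna)]
  transLnc <- if (cfg$n_trans_targets > 0)
    fragLnc[cfg$n_planted_dss + cfg$n_planted_cerna + 1L] else character(0)
  offFragLnc <- setdiff(lncIds, fragLnc)
  hypermethLnc <- offFragLnc[seq_len(cfg$n_planted_hypermeth)]

  fragOfLnc <- rep(seq_len(cfg$n_fragments), each = cfg$lncrna_per_fragment)
  slotInFrag <- rep(seq_len(cfg$lncrna_per_fragment),
                    times = cfg$n_fragments)
  lncChrom <- c(rep("chr1", nFragLnc),
                rep("chr2", cfg$n_lncrna - nFragLnc))
  lncStart <- integer(cfg$n_lncrna)
  lncStart[seq_len(nFragLnc)] <-
    fragStart[fragOfLnc] + (slotInFrag - 1L) * 100000L + 10000L
  lncStart[(nFragLnc + 1L):cfg$n_lncrna] <-
    (seq_len(cfg$n_lncrna - nFragLnc) - 1L) * 800000L + 100001L
  lncEnd <- lncStart + 9999L
  lncStrand <- rep(c("+", "-"), length.out = cfg$n_lncrna)

  # PCGs: cis partners adjacent to their lncRNA, everything else on
  # chr3 spaced 800 kb so no accidental cis pair can form
  cisPcg <- pcgIds[seq_len(cfg$n_planted_cis)]
  pcgChrom <- rep("chr3", cfg$n_pcg)
  pcgStart <- (seq_len(cfg$n_pcg) - 1L) * 800000L + 100001L
  cisIdx <- seq_len(cfg$n_planted_cis)
  pcgChrom[cisIdx] <- "chr1"
  pcgStart[cisIdx] <- lncEnd[match(cisLnc, lncIds)] + cfg$cis_offset_bp
  pcgEnd <- pcgStart + 19999L
  pcgStrand <- rep(c("+", "-"), length.out = cfg$n_pcg)

  tfStart <- (seq_len(cfg$n_tf) - 1L) * 500000L + 100001L
  mirStart <- (seq_len(cfg$n_mirna) - 1L) * 200000L + 100001L

  ann <- GRanges(
    c(lncChrom, pcgChrom, rep("chr4", cfg$n_tf), rep("chr5", cfg$n_mirna)),
    IRanges(c(lncStart, pcgStart, tfStart, mirStart),
            c(lncEnd, pcgEnd, tfStart + 9999L, mirStart + 99L)),
    strand = c(lncStrand, pcgStrand,
               rep("+", cfg$n_tf), rep("+", cfg$n_mirna))
  )
  gid <- c(lncIds, pcgIds, tfIds, mirIds)
  mcols(ann)$gene_id <- gid
  mcols(ann)$symbol <- gid
  mcols(ann)$biotype <- rep(c("lncRNA", "PCG", "TF", "miRNA"),
                            c(cfg$n_lncrna, cfg$n_pcg, cfg$n_tf,
                              cfg$n_mirna))
  mcols(ann)$tss <- ifelse(as.character(strand(ann)) == "-",
                           end(ann), start(ann))
  names(ann) <- gid

  ## ---- copy-number layer --------------------------------------------
  set.seed(.layerSeed(cfg$seed, "cn"))

  nS <- length(samples)
  cn <- matrix(runif(cfg$n_lncrna * nS, -cfg$cn_background,
                     cfg$cn_background),
               nrow = cfg$n_lncrna,
               dimnames = list(lncIds, samples))
  nAlt <- round(cfg$alteration_fraction * cfg$n_tumor)
  alteredSamples <- vector("list", cfg$n_fragments)
  tumorIdx <- which(isTumor)
  for (f in seq_len(cfg$n_fragments)) {
    alt <- sort(sample(tumorIdx, nAlt))
    alteredSamples[[f]] <- samples[alt]
    sgn <- if (mcols(fragments)$direction[f] == "gain") 1 else -1
    genes <- fragLnc[fragOfLnc == f]
    for (g in genes)
      cn[g, alt] <- sgn * runif(nAlt, cfg$cn_alt_min, cfg$cn_alt_max)
  }
  dcn <- matrix(0L, nrow = nrow(cn), ncol = ncol(cn),
                dimnames = dimnames(cn))
  dcn[cn > 0.3] <- 1L; dcn[cn > 1.3] <- 2L
  dcn[cn < -0.3] <- -1L; dcn[cn < -1.3] <- -2L

  ## ---- expression layer ---------------------------------------------
  set.seed(.layerSeed(cfg$seed, "expression"))

  slopes <- setNames(runif(cfg$n_planted_dss, cfg$dosage_slope_range[1],
                           cfg$dosage_slope_range[2]), dssLnc)
  # latent factors: one per ceRNA triple, one for the trans module
  fTriple <- matrix(rnorm(cfg$n_planted_cerna * nS),
                    nrow = cfg$n_planted_cerna, ncol = nS,
                    dimnames = if (cfg$n_planted_cerna > 0)
                      list(NULL, samples) else NULL)
  gTrans <- rnorm(nS)

  noise <- function(n) rnorm(n, sd = cfg$noise_sd)
  mu <- cfg$base_expr

  lncLog <- matrix(mu + noise(cfg$n_lncrna * nS), nrow = cfg$n_lncrna,
                   dimnames = list(lncIds, samples))
  for (g in dssLnc) lncLog[g, ] <- mu + slopes[g] * cn[g, ] + noise(nS)
  for (i in seq_len(cfg$n_planted_cerna))
    lncLog[cernaLnc[i], ] <- mu + fTriple[i, ] + noise(nS)
  for (g in transLnc) lncLog[g, ] <- mu + gTrans + noise(nS)

  # DE lncRNAs: ceRNA lncRNAs up-shifted (4-fold), plus pure down genes
  nDeLnc <- cfg$n_planted_de_lnc
  deLncUp <- cernaLnc
  deLncDown <- offFragLnc[cfg$n_planted_hypermeth +
                          seq_len(max(0L, nDeLnc - length(deLncUp)))]
  for (g in deLncUp) lncLog[g, isTumor] <- lncLog[g, isTumor] + cfg$de_log2fc
  for (g in deLncDown) lncLog[g, isTumor] <- lncLog[g, isTumor] - cfg$de_log2fc

  # PCG layout inside the planted-DE set:
  #   [cis partners | trans targets | ceRNA partners | pure DE]
  dePcg <- pcgIds[seq_len(cfg$n_planted_de)]
  transTargets <- pcgIds[cfg$n_planted_cis + seq_len(cfg$n_trans_targets)]
  cernaPcg <- pcgIds[cfg$n_planted_cis + cfg$n_trans_targets +
                     seq_len(cfg$n_planted_cerna)]
  pureDe <- setdiff(dePcg, c(cisPcg, transTargets, cernaPcg))

  pcgLog <- matrix(mu + noise(cfg$n_pcg * nS), nrow = cfg$n_pcg,
                   dimnames = list(pcgIds, samples))
  # cis partners track the lncRNA's expression (cis regulation), so the
  # pair is co-expressed whatever dosage slope the lncRNA drew
  for (i in seq_len(cfg$n_planted_cis)) {
    lnc <- cisLnc[i]
    pcgLog[cisPcg[i], ] <- mu + 0.8 * (lncLog[lnc, ] - mu) + noise(nS)
  }
  for (g in transTargets) pcgLog[g, ] <- mu + 0.8 * gTrans + noise(nS)
  for (i in seq_len(cfg$n_planted_cerna))
    pcgLog[cernaPcg[i], ] <- mu + fTriple[i, ] + noise(nS)
  # tumor shifts: all DE PCGs move; half of the pure set moves down
  deUpPcg <- c(cisPcg, transTargets, cernaPcg,
               pureDe[seq_len(ceiling(length(pureDe) / 2))])
  deDownPcg <- setdiff(pureDe, deUpPcg)
  for (g in deUpPcg) pcgLog[g, isTumor] <- pcgLog[g, isTumor] + cfg$de_log2fc
  for (g in deDownPcg) pcgLog[g, isTumor] <- pcgLog[g, isTumor] - cfg$de_log2fc

  tfLog <- matrix(mu + noise(cfg$n_tf * nS), nrow = cfg$n_tf,
                  dimnames = list(tfIds, samples))
  tfLog[1, ] <- mu + gTrans + noise(nS)

  # shared miRNAs load negatively on their triple's factor
  tripleMirs <- split(mirIds[seq_len(cfg$n_planted_cerna *
                                     cfg$mirnas_per_triple)],
                      rep(seq_len(cfg$n_planted_cerna),
                          each = cfg$mirnas_per_triple))
  mirLog <- matrix(mu + noise(cfg$n_mirna * nS), nrow = cfg$n_mirna,
                   dimnames = list(mirIds, samples))
  for (i in seq_len(cfg$n_planted_cerna))
    for (g in tripleMirs[[i]])
      mirLog[g, ] <- mu - 0.9 * fTriple[i, ] + noise(nS)

  ## ---- methylation layer --------------------------------------------
  set.seed(.layerSeed(cfg$seed, "methylation"))

  probeRows <- list()
  betaRows <- list()
  for (g in lncIds) {
    tss <- mcols(ann)$tss[match(g, gid)]
    chrom <- as.character(seqnames(ann))[match(g, gid)]
    str <- as.character(strand(ann))[match(g, gid)]
    # positions inside the 2 kb upstream promoter
    offs <- round(seq(200, 1800, length.out = cfg$n_probes_per_gene))
    pos <- if (str == "-") tss + offs else tss - offs
    hyper <- g %in% hypermethLnc
    for (pi in seq_len(cfg$n_probes_per_gene)) {
      pid <- sprintf("cg_%s_%d", g, pi)
      probeRows[[pid]] <- data.frame(probe_id = pid, chrom = chrom,
                                     position = pos[pi],
                                     stringsAsFactors = FALSE)
      bNorm <- rbeta(cfg$n_normal, 3, 17)           # mean 0.15
      bTum <- if (hyper) rbeta(cfg$n_tumor, 10, 10) # mean 0.50
              else rbeta(cfg$n_tumor, 3, 17)
      betaRows[[pid]] <- c(bTum, bNorm)
    }
  }
  probes <- do.call(rbind, probeRows); rownames(probes) <- NULL
  beta <- do.call(rbind, betaRows)
  colnames(beta) <- samples

  # couple expression of hypermethylated lncRNAs negatively to their
  # mean promoter beta
  for (g in hypermethLnc) {
    pids <- sprintf("cg_%s_%d", g, seq_len(cfg$n_probes_per_gene))
    gb <- colMeans(beta[pids, , drop = FALSE])
    lncLog[g, ] <- mu - cfg$meth_coupling * gb + noise(nS)
  }

  ## ---- interaction layer --------------------------------------------
  set.seed(.layerSeed(cfg$seed, "interactions"))

  mirLnc <- do.call(rbind, lapply(seq_len(cfg$n_planted_cerna),
    function(i) data.frame(source_id = tripleMirs[[i]],
                           target_id = cernaLnc[i],
                           stringsAsFactors = FALSE)))
  mirPcg <- do.call(rbind, lapply(seq_len(cfg$n_planted_cerna),
    function(i) data.frame(source_id = tripleMirs[[i]],
                           target_id = cernaPcg[i],
                           stringsAsFactors = FALSE)))
  nBg <- cfg$n_background_interactions
  bgLnc <- data.frame(source_id = sample(mirIds, nBg, replace = TRUE),
                      target_id = sample(lncIds, nBg, replace = TRUE),
                      stringsAsFactors = FALSE)
  bgPcg <- data.frame(source_id = sample(mirIds, nBg, replace = TRUE),
                      target_id = sample(pcgIds, nBg, replace = TRUE),
                      stringsAsFactors = FALSE)
  mirLnc <- unique(rbind(mirLnc, bgLnc))
  mirPcg <- unique(rbind(mirPcg, bgPcg))
  rownames(mirLnc) <- rownames(mirPcg) <- NULL

  tf1Targets <- c(transTargets,
                  pureDe[seq_len(min(cfg$n_tf_extra_targets,
                                     length(pureDe)))])
  tfTargets <- if (length(tf1Targets))
    data.frame(source_id = tfIds[1], target_id = tf1Targets,
               stringsAsFactors = FALSE)
  else data.frame(source_id = character(0), target_id = character(0),
                  stringsAsFactors = FALSE)
  for (t in tfIds[-1]) {
    tfTargets <- rbind(tfTargets,
      data.frame(source_id = t,
                 target_id = sample(pcgIds, 10),
                 stringsAsFactors = FALSE))
  }
  rownames(tfTargets) <- NULL

  drugTable <- if (cfg$n_planted_cerna > 0) data.frame(
    source_id = c(rep("drug_up", cfg$mirnas_per_triple),
                  rep("drug_down", cfg$mirnas_per_triple),
                  "drug_offmodule"),
    target_id = c(tripleMirs[[1]], tripleMirs[[1]],
                  mirIds[cfg$n_mirna]),
    effect = c(rep("up", cfg$mirnas_per_triple),
               rep("down", cfg$mirnas_per_triple), "up"),
    stringsAsFactors = FALSE)
  else data.frame(source_id = "drug_offmodule",
                  target_id = mirIds[cfg$n_mirna], effect = "up",
                  stringsAsFactors = FALSE)

  ## ---- GO layer ------------------------------------------------------
  set.seed(.layerSeed(cfg$seed, "go"))
  terms <- sprintf("GO:%07d", seq_len(cfg$n_go_terms))
  goRows <- lapply(pcgIds, function(g) {
    k <- sample(1:3, 1)
    data.frame(gene_id = g, term_id = sample(terms, k),
               stringsAsFactors = FALSE)
  })
  goTable <- do.call(rbind, goRows)
  goTable$term_name <- sub("GO:", "process_", goTable$term_id)
  rownames(goTable) <- NULL

  ## ---- survival layer ------------------------------------------------
  set.seed(.layerSeed(cfg$seed, "survival"))
  zs <- function(x) (x - mean(x)) / sd(x)
  tum <- samples[isTumor]
  if (cfg$n_planted_cerna > 0) {
    progLnc <- cernaLnc[1]; progPcg <- cernaPcg[1]
    progMirs <- tripleMirs[[1]]
    lp <- cfg$hazard_coefs[["lncrna"]] * zs(lncLog[progLnc, tum]) +
          cfg$hazard_coefs[["pcg"]] * zs(pcgLog[progPcg, tum])
    for (g in progMirs)
      lp <- lp + cfg$hazard_coefs[["mirna"]] * zs(mirLog[g, tum])
  } else {
    progLnc <- character(0); progPcg <- character(0)
    progMirs <- character(0)
    lp <- rep(0, length(tum))
  }
  rate <- cfg$base_hazard * exp(lp)
  tEvent <- rexp(length(tum), rate = rate)
  time <- pmin(tEvent, cfg$censor_time)
  clinical <- data.frame(sample_id = tum,
                         time = round(time, 3) + 1e-3,
                         event = tEvent <= cfg$censor_time,
                         stringsAsFactors = FALSE)

  ## ---- assemble ------------------------------------------------------
  lin <- function(logm) 2^logm
  matrices <- list(
    lncrna_expr = OmicsMatrix(lin(lncLog), sclass, "expression"),
    pcg_expr = OmicsMatrix(lin(pcgLog), sclass, "expression"),
    tf_expr = OmicsMatrix(lin(tfLog), sclass, "expression"),
    mirna_expr = OmicsMatrix(lin(mirLog), sclass, "expression"),
    copy_number = OmicsMatrix(cn, sclass, "copy_number"),
    discrete_cn = OmicsMatrix(dcn, sclass, "discrete_cn"),
    probe_beta = OmicsMatrix(beta, sclass, "beta")
  )
  truth <- list(
    dss_lncrnas = dssLnc,
    dss_slopes = slopes,
    de_genes = c(setNames(rep("up", length(deUpPcg)), deUpPcg),
                 setNames(rep("down", length(deDownPcg)), deDownPcg),
                 setNames(rep("up", length(deLncUp)), deLncUp),
                 setNames(rep("down", length(deLncDown)), deLncDown)),
    de_pcgs_up = deUpPcg, de_pcgs_down = deDownPcg,
    de_lncrnas_up = deLncUp, de_lncrnas_down = deLncDown,
    cerna_triples = lapply(seq_len(cfg$n_planted_cerna), function(i)
      list(lncrna = cernaLnc[i], pcg = cernaPcg[i],
           mirnas = tripleMirs[[i]])),
    hypermeth_lncrnas = hypermethLnc,
    cis_pairs = data.frame(lncrna_id = cisLnc, pcg_id = cisPcg,
                           stringsAsFactors = FALSE),
    trans_triple = if (length(transLnc))
      list(lncrna = transLnc, tf = tfIds[1], targets = transTargets)
      else NULL,
    prognostic_triple = if (length(progLnc))
      list(lncrna = progLnc, mirnas = progMirs, pcg = progPcg,
           coef_signs = c(lncrna = 1, mirna = -1, pcg = 1))
      else NULL,
    altered_samples = setNames(alteredSamples,
                               mcols(fragments)$fragment_id)
  )
  structure(list(config = cfg, annotation = ann, fragments = fragments,
                 matrices = matrices, probes = probes,
                 interactions = list(mir_lnc = mirLnc, mir_pcg = mirPcg,
                                     tf_gene = tfTargets,
                                     drug_mirna = drugTable),
                 go_table = goTable, clinical = clinical, truth = truth),
            class = "SyntheticCohort")
}

#' Write a synthetic cohort to disk
#'
#' Emits every layer in the package's standard text formats (GTF
#' annotation, fragment/matrix/interaction/clinical TSVs), the config as
#' YAML and the ground-truth manifest as JSON. Reading the files back
#' through the core readers reproduces the in-memory objects.
#'
#' @param cohort a `SyntheticCohort` from [generateCohort()].
#' @param outDir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
writeCohort <- function(cohort, outDir) {
  stopifnot(inherits(cohort, "SyntheticCohort"))
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  fp <- function(f) file.path(outDir, f)
  writeAnnotation(cohort$annotation, fp("annotation.gtf"), "GTF")
  writeFragments(cohort$fragments, fp("fragments.tsv"))
  mats <- cohort$matrices
  for (nm in names(mats)) writeMatrix(mats[[nm]], fp(paste0(nm, ".tsv")))
  write.table(cohort$probes, fp("probes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  ints <- cohort$interactions
  writeInteractions(ints$mir_lnc, fp("mirna_lncrna.tsv"))
  writeInteractions(ints$mir_pcg, fp("mirna_pcg.tsv"))
  writeInteractions(ints$tf_gene, fp("tf_gene.tsv"))
  writeInteractions(ints$drug_mirna, fp("drug_mirna.tsv"))
  write.table(cohort$go_table, fp("go_table.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeClinical(cohort$clinical, fp("clinical.tsv"))
  sc <- sampleClass(mats$lncrna_expr)
  write.table(data.frame(sample_id = names(sc), class = unname(sc)),
              fp("samples.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  cfg <- cohort$config
  yaml::write_yaml(unclass(cfg), fp("config.yaml"))
  jsonlite::write_json(.manifestJson(cohort$truth), fp("truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outDir)
}

.manifestJson <- function(truth) {
  list(
    dss_lncrnas = truth$dss_lncrnas,
    dss_slopes = as.list(truth$dss_slopes),
    de_pcgs_up = truth$de_pcgs_up, de_pcgs_down = truth$de_pcgs_down,
    de_lncrnas_up = truth$de_lncrnas_up,
    de_lncrnas_down = truth$de_lncrnas_down,
    cerna_triples = truth$cerna_triples,
    hypermeth_lncrnas = truth$hypermeth_lncrnas,
    cis_pairs = truth$cis_pairs,
    trans_triple = truth$trans_triple,
    prognostic_triple = truth$prognostic_triple
  )
}

#' Read a cohort directory written by [writeCohort()]
#'
#' @param dir cohort directory.
#' @return a list with the same shape as [generateCohort()] output
#'   (without `truth`/`config` unless present on disk).
#' @export
readCohort <- function(dir) {
  fp <- function(f) file.path(dir, f)
  smp <- read.delim(fp("samples.tsv"), stringsAsFactors = FALSE)
  classMap <- setNames(smp$class, smp$sample_id)
  roleOf <- c(lncrna_expr = "expression", pcg_expr = "expression",
              tf_expr = "expression", mirna_expr = "expression",
              copy_number = "copy_number", discrete_cn = "discrete_cn",
              probe_beta = "beta")
  mats <- lapply(names(roleOf), function(nm)
    readMatrix(fp(paste0(nm, ".tsv")), roleOf[[nm]], classMap))
  names(mats) <- names(roleOf)
  truth <- if (file.exists(fp("truth.json")))
    jsonlite::read_json(fp("truth.json"), simplifyVector = TRUE) else NULL
  config <- if (file.exists(fp("config.yaml")))
    yaml::read_yaml(fp("config.yaml")) else NULL
  list(
    annotation = readAnnotation(fp("annotation.gtf"), "GTF"),
    fragments = readFragments(fp("fragments.tsv")),
    matrices = mats,
    probes = read.delim(fp("probes.tsv"), stringsAsFactors = FALSE),
    interactions = list(
      mir_lnc = readInteractions(fp("mirna_lncrna.tsv"), "miRNA-lncRNA"),
      mir_pcg = readInteractions(fp("mirna_pcg.tsv"), "miRNA-mRNA"),
      tf_gene = readInteractions(fp("tf_gene.tsv"), "TF-gene"),
      drug_mirna = readInteractions(fp("drug_mirna.tsv"), "drug-miRNA")),
    go_table = readGoTable(fp("go_table.tsv")),
    clinical = readClinical(fp("clinical.tsv")),
    truth = truth, config = config
  )
}
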