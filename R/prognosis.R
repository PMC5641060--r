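#' @importFrom survival coxph survdiff Surv
#' @importFrom stats pchisq sd
NULL

#' Univariate Cox proportional-hazards fit of one expression vector
#'
#' Standardizes the expression vector (z-score) and fits
#' `Surv(time, event) ~ z` by partial likelihood, returning the
#' coefficient and its Wald p-value. Requires at least 10 samples and 3
#' observed events; non-convergence is flagged, constant expression
#' yields beta = 0.
#'
#' @param expr named numeric, expression per sample.
#' @param clinical data.frame(sample_id, time, event); samples are
#'   matched by name.
#' @return list(beta, p, converged).
#' @export
univariateCox <- function(expr, clinical) {
  common <- intersect(names(expr), clinical$sample_id)
  if (length(common) < 10) stop("need >= 10 samples with clinical data")
  cl <- clinical[match(common, clinical$sample_id), ]
  if (sum(cl$event) < 3) stop("need >= 3 observed events")
  x <- expr[common]
  if (sd(x) == 0)
    return(list(beta = 0, p = 1, converged = TRUE))
  z <- (x - mean(x)) / sd(x)
  converged <- TRUE
  fit <- withCallingHandlers(
    coxph(Surv(cl$time, cl$event) ~ z),
    warning = function(w) {
      converged <<- FALSE
      invokeRestart("muffleWarning")
    })
  s <- summary(fit)
  list(beta = unname(stats::coef(fit)[1]),
       p = unname(s$coefficients[1, "Pr(>|z|)"]),
       converged = converged)
}

#' Prognostic risk model of a lncRNA-miRNA-PCG triple
#'
#' Fits a univariate Cox model per node (lncRNA, each miRNA, PCG) on
#' z-scored expression, sums `beta_node * z_node` into a per-sample risk
#' score, splits samples at the median risk (ties to the low-risk
#' group), and compares the groups with a log-rank test. A constant
#' risk vector is flagged degenerate and no split/test is performed.
#'
#' @param lncrna,pcg gene id of the lncRNA / PCG node.
#' @param mirnas character vector of miRNA node ids.
#' @param exprOf function(gene_id) -> named numeric expression vector
#'   over the clinical samples (see [runPipeline()] for the matrix-backed
#'   version), or a single named list of such vectors.
#' @param clinical data.frame(sample_id, time, event).
#' @return a [RiskModel-class] object.
#' @export
tripleRisk <- function(lncrna, mirnas, pcg, exprOf, clinical) {
  getv <- if (is.function(exprOf)) exprOf else function(g) {
    if (is.null(exprOf[[g]])) stop("node missing expression: ", g)
    exprOf[[g]]
  }
  nodes <- c(lncrna, mirnas, pcg)
  vecs <- lapply(nodes, function(g) {
    v <- getv(g)
    if (is.null(v)) stop("node missing expression: ", g)
    v
  })
  names(vecs) <- nodes
  common <- Reduce(intersect, c(lapply(vecs, names),
                                list(clinical$sample_id)))
  cl <- clinical[match(common, clinical$sample_id), ]
  betas <- numeric(length(nodes)); waldP <- numeric(length(nodes))
  risk <- setNames(rep(0, length(common)), common)
  for (i in seq_along(nodes)) {
    v <- vecs[[i]][common]
    fit <- univariateCox(v, cl)
    betas[i] <- fit$beta; waldP[i] <- fit$p
    z <- if (sd(v) == 0) rep(0, length(v)) else (v - mean(v)) / sd(v)
    risk <- risk + fit$beta * z
  }
  names(betas) <- names(waldP) <- nodes
  cut <- median(risk)
  if (all(risk == risk[1])) {
    return(new("RiskModel", lncrna = lncrna, mirnas = mirnas, pcg = pcg,
               betas = betas, waldP = waldP, risk = risk, cut = cut,
               group = setNames(rep(NA_character_, length(risk)), common),
               logrankChi2 = NA_real_, logrankP = NA_real_,
               degenerate = TRUE))
  }
  group <- setNames(ifelse(risk > cut, "high", "low"), common)
  sd0 <- survdiff(Surv(cl$time, cl$event) ~ group)
  p <- pchisq(sd0$chisq, df = 1, lower.tail = FALSE)
  new("RiskModel", lncrna = lncrna, mirnas = mirnas, pcg = pcg,
      betas = betas, waldP = waldP, risk = risk, cut = cut,
      group = group, logrankChi2 = unname(sd0$chisq), logrankP = p,
      degenerate = FALSE)
}

#' Kaplan-Meier coordinates of a risk split
#'
#' Step-function coordinates of the Kaplan-Meier survival estimates for
#' the high- and low-risk groups of a [RiskModel-class], suitable for
#' plotting or TSV export.
#'
#' @param model a RiskModel.
#' @param clinical data.frame(sample_id, time, event).
#' @return data.frame(group, time, surv).
#' @export
kmCoordinates <- function(model, clinical) {
  if (model@degenerate) stop("degenerate risk model has no split")
  cl <- clinical[match(names(model@group), clinical$sample_id), ]
  fit <- survival::survfit(Surv(cl$time, cl$event) ~ model@group)
  strata <- rep(sub("^model@group=", "", names(fit$strata)),
                times = fit$strata)
  data.frame(group = strata, time = fit$time, surv = fit$surv,
             stringsAsFactors = FALSE)
}

#' Nominate candidate drugs through drug-miRNA associations
#'
#' A drug is a candidate for a ceRNA module iff it up-regulates one of
#' the module's miRNAs while both the module lncRNA and PCG are
#' up-regulated in tumors (boosting the shared miRNA then plausibly
#' represses both). Drug rows targeting module miRNAs under any other
#' combination are reported with `rationale = "other"`; drugs whose
#' miRNA is outside the module are excluded.
#'
#' @param moduleEdges data.frame with columns lncrna_id, pcg_id,
#'   surviving_mirnas (comma-separated), lnc_direction, pcg_direction
#'   (`"up"`/`"down"`).
#' @param drugTable data.frame(source_id = drug, target_id = miRNA,
#'   effect = "up"/"down").
#' @return data.frame(drug, mirna_id, effect, lncrna_id, pcg_id,
#'   rationale) with rationale `"suppresses_overexpressed_partners"` or
#'   `"other"`.
#' @export
drugCandidates <- function(moduleEdges, drugTable) {
  out <- data.frame(drug = character(), mirna_id = character(),
                    effect = character(), lncrna_id = character(),
                    pcg_id = character(), rationale = character())
  if (!nrow(moduleEdges) || !nrow(drugTable)) return(out)
  rows <- list()
  for (i in seq_len(nrow(moduleEdges))) {
    mirs <- strsplit(moduleEdges$surviving_mirnas[i], ",")[[1]]
    hits <- drugTable[drugTable$target_id %in% mirs, , drop = FALSE]
    if (!nrow(hits)) next
    up <- moduleEdges$lnc_direction[i] == "up" &&
          moduleEdges$pcg_direction[i] == "up"
    rows[[length(rows) + 1L]] <- data.frame(
      drug = hits$source_id, mirna_id = hits$target_id,
      effect = hits$effect,
      lncrna_id = moduleEdges$lncrna_id[i],
      pcg_id = moduleEdges$pcg_id[i],
      rationale = ifelse(hits$effect == "up" & up,
                         "suppresses_overexpressed_partners", "other"),
      stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) return(out)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
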