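#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
NULL

.OMICS_ROLES <- c("expression", "copy_number", "discrete_cn", "beta")
.SAMPLE_CLASSES <- c("tumor", "normal")
.BIOTYPES <- c("lncRNA", "PCG", "TF", "miRNA")

#' OmicsMatrix: a role-tagged gene x sample assay
#'
#' An `OmicsMatrix` is a [SummarizedExperiment::SummarizedExperiment]
#' carrying a single numeric gene x sample assay plus a per-sample
#' tumor/normal class label (in `colData()$sampleClass`) and a `role` tag
#' identifying what the numbers are: `"expression"` (linear-scale abundance
#' unless otherwise transformed), `"copy_number"` (continuous gene-level
#' SCNA values, GISTIC style), `"discrete_cn"` (thresholded calls in
#' -2..2) or `"beta"` (methylation fractions in \[0, 1\]).
#'
#' Validity enforces the role invariants: beta values in \[0, 1\] and
#' discrete copy number in \{-2, -1, 0, 1, 2\} (missing values allowed and
#' kept distinct from zero throughout the pipeline).
#'
#' @slot role character(1), one of the four roles above.
#' @export
setClass("OmicsMatrix",
  contains = "SummarizedExperiment",
  representation(role = "character")
)

setValidity("OmicsMatrix", function(object) {
  msg <- character()
  if (length(object@role) != 1L || !object@role %in% .OMICS_ROLES)
    msg <- c(msg, sprintf("role must be one of: %s",
                          paste(.OMICS_ROLES, collapse = ", ")))
  if (!"sampleClass" %in% colnames(colData(object)))
    msg <- c(msg, "colData must contain a 'sampleClass' column")
  else {
    sc <- colData(object)$sampleClass
    if (!all(sc %in% .SAMPLE_CLASSES))
      msg <- c(msg, "sampleClass values must be 'tumor' or 'normal'")
  }
  if (length(SummarizedExperiment::assays(object)) >= 1L) {
    v <- assay(object)
    if (identical(object@role, "beta")) {
      vv <- v[!is.na(v)]
      if (length(vv) && (min(vv) < 0 || max(vv) > 1))
        msg <- c(msg, "beta values must lie in [0, 1]")
    }
    if (identical(object@role, "discrete_cn")) {
      vv <- v[!is.na(v)]
      if (length(vv) && !all(vv %in% -2:2))
        msg <- c(msg, "discrete_cn values must be in {-2,-1,0,1,2}")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct an OmicsMatrix
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids). `NA` marks missing data
#'   and is never conflated with zero.
#' @param sampleClass character vector (`"tumor"`/`"normal"`), one per
#'   column, or a named vector mapping sample id to class.
#' @param role one of `"expression"`, `"copy_number"`, `"discrete_cn"`,
#'   `"beta"`.
#' @return An [OmicsMatrix-class] object.
#' @examples
#' m <- matrix(rnorm(6), 2, 3,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
#' om <- OmicsMatrix(m, c("tumor", "tumor", "normal"), "expression")
#' omicsRole(om)
#' @export
OmicsMatrix <- function(values, sampleClass, role) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have rownames (gene ids) and colnames (sample ids)")
  if (!is.null(names(sampleClass)))
    sampleClass <- unname(sampleClass[colnames(values)])
  if (length(sampleClass) != ncol(values))
    stop("sampleClass must supply one class per sample column")
  se <- SummarizedExperiment(
    assays = list(values = values),
    colData = DataFrame(sampleClass = as.character(sampleClass),
                        row.names = colnames(values))
  )
  new("OmicsMatrix", se, role = role)
}

#' @describeIn OmicsMatrix The role tag of the assay.
#' @param x an OmicsMatrix.
#' @export
omicsRole <- function(x) x@role

#' @describeIn OmicsMatrix Per-sample tumor/normal labels, named by sample.
#' @export
sampleClass <- function(x) {
  stats::setNames(colData(x)$sampleClass, colnames(x))
}

#' @describeIn OmicsMatrix The numeric gene x sample matrix.
#' @export
omicsValues <- function(x) assay(x, "values")

#' @describeIn OmicsMatrix Subset to tumor (or normal) samples only.
#' @param class sample class to keep.
#' @export
subsetByClass <- function(x, class = c("tumor", "normal")) {
  class <- match.arg(class)
  x[, colData(x)$sampleClass == class]
}

setMethod("show", "OmicsMatrix", function(object) {
  sc <- colData(object)$sampleClass
  cat(sprintf("OmicsMatrix [%s]: %d genes x %d samples (%d tumor, %d normal)\n",
              object@role, nrow(object), ncol(object),
              sum(sc == "tumor"), sum(sc == "normal")))
  nmiss <- sum(is.na(assay(object)))
  if (nmiss > 0) cat(sprintf("  missing cells: %d\n", nmiss))
})

#' RiskModel: prognostic risk score of a ceRNA triple
#'
#' Result container for [tripleRisk()]: per-node univariate Cox
#' coefficients, the per-sample summed risk score, the median cut, the
#' high/low group assignment and the two-group log-rank test.
#'
#' @slot lncrna,pcg character(1) node ids.
#' @slot mirnas character vector of miRNA node ids.
#' @slot betas named numeric, univariate Cox coefficient per node.
#' @slot waldP named numeric, per-node Wald p-values.
#' @slot risk named numeric, per-sample risk score.
#' @slot cut numeric(1), median risk.
#' @slot group named character, "high"/"low" per sample (ties at the
#'   median go to "low").
#' @slot logrankChi2,logrankP numeric(1), log-rank test between groups.
#' @slot degenerate logical(1), TRUE when the risk vector was constant and
#'   no split/test was possible.
#' @export
setClass("RiskModel", representation(
  lncrna = "character", mirnas = "character", pcg = "character",
  betas = "numeric", waldP = "numeric",
  risk = "numeric", cut = "numeric", group = "character",
  logrankChi2 = "numeric", logrankP = "numeric", degenerate = "logical"
))

setMethod("show", "RiskModel", function(object) {
  cat(sprintf("RiskModel: %s | %s | %s\n", object@lncrna,
              paste(object@mirnas, collapse = "/"), object@pcg))
  cat("  Cox betas: ",
      paste(sprintf("%s=%.3f", names(object@betas), object@betas),
            collapse = ", "), "\n", sep = "")
  if (object@degenerate) {
    cat("  degenerate risk vector: no split performed\n")
  } else {
    cat(sprintf("  median cut %.3f; %d high / %d low; log-rank chi2 %.3f, p %.3g\n",
                object@cut, sum(object@group == "high"),
                sum(object@group == "low"),
                object@logrankChi2, object@logrankP))
  }
})

#' @describeIn RiskModel per-node Cox coefficients.
#' @param x a RiskModel.
#' @export
riskBetas <- function(x) x@betas

#' @describeIn RiskModel per-sample risk scores.
#' @export
riskScores <- function(x) x@risk

#' @describeIn RiskModel per-sample high/low group labels.
#' @export
riskGroups <- function(x) x@group

#' @describeIn RiskModel log-rank p-value of the median split.
#' @export
logrankP <- function(x) x@logrankP
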