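#' @import methods
#' @importFrom stats cor cov pchisq predict rnorm runif sd setNames var
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Cohort of subjects with ROI morphometry
#'
#' \code{MorphCohort} extends
#' \link[SummarizedExperiment]{SummarizedExperiment}: the single assay
#' \code{"morpho"} holds the ROI feature matrix (features x subjects, in
#' schema order), \code{rowData} carries the ROI schema (\code{name},
#' \code{kind}, \code{hemisphere}) and \code{colData} the per-subject
#' metadata (\code{group}, \code{age}, \code{sex}, \code{education},
#' \code{icv}, optionally \code{suvr}, \code{apoe_e4_count} and simulation
#' truth columns prefixed \code{truth_}).
#'
#' @seealso [readCohortTable()], [generateCohort()], [featureMatrix()]
#' @export
setClass("MorphCohort", contains = "SummarizedExperiment")

setValidity("MorphCohort", function(object) {
  msg <- character(0)
  a <- SummarizedExperiment::assay(object)
  cd <- SummarizedExperiment::colData(object)
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("group", "icv") %in% colnames(cd)))
    msg <- c(msg, "colData must contain 'group' and 'icv'")
  if (!all(c("name", "kind", "hemisphere") %in% colnames(rd)))
    msg <- c(msg, "rowData must carry the ROI schema (name, kind, hemisphere)")
  else if (!identical(rownames(object), as.character(rd$name)))
    msg <- c(msg, "assay row names must equal schema names, in order")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicate subject_id")
  if ("icv" %in% colnames(cd) &&
      (!all(is.finite(cd$icv)) || any(cd$icv <= 0)))
    msg <- c(msg, "icv must be finite and > 0")
  if (!all(is.finite(a)))
    msg <- c(msg, "feature values must be finite (no NA/NaN/Inf)")
  if (length(msg)) msg else TRUE
})

#' Fitted OPLS discriminant model
#'
#' Holds a single-predictive-component OPLS discriminant fit: the unit
#' predictive weight vector \code{w}, predictive loading \code{p}, scalar
#' y-loading \code{c}, ordered orthogonal weight/loading vectors, the
#' centred-y intercept, the class coding, and the preprocessing
#' (\code{ScalingParams}) estimated on the training set so that raw unseen
#' subjects can be projected with [predict()] / [computeIndex()].
#'
#' @slot weights unit predictive weight vector w.
#' @slot loadings predictive loading vector p.
#' @slot yLoading scalar y-loading c; prediction is \code{c * t + yMean}.
#' @slot orthoWeights,orthoLoadings feature x nOrth matrices of orthogonal
#'   weights w_o (unit norm) and loadings p_o.
#' @slot nOrth number of orthogonal components removed before prediction.
#' @slot yMean training mean of the coded response (the intercept).
#' @slot yCoding named character vector \code{c(control=, disease=)} mapping
#'   the 0 and 1 codes to group labels.
#' @slot scaling list with elements \code{icv} and \code{std}: the ICV
#'   adjustment and standardization parameters estimated on training rows.
#' @slot featureNames column names of the (post-preprocessing) model space.
#' @slot trainingIds subject ids used for fitting (leakage guard).
#' @slot scores training predictive scores t.
#' @slot fitted training fitted values c*t + yMean.
#' @export
setClass("OplsModel", representation(
  weights = "numeric",
  loadings = "numeric",
  yLoading = "numeric",
  orthoWeights = "matrix",
  orthoLoadings = "matrix",
  nOrth = "integer",
  yMean = "numeric",
  yCoding = "character",
  scaling = "list",
  featureNames = "character",
  trainingIds = "character",
  scores = "numeric",
  fitted = "numeric"
))

setValidity("OplsModel", function(object) {
  msg <- character(0)
  p <- length(object@weights)
  if (abs(sqrt(sum(object@weights^2)) - 1) > 1e-8)
    msg <- c(msg, "predictive weight vector must have unit norm")
  if (length(object@loadings) != p)
    msg <- c(msg, "loading length must match weight length")
  if (object@nOrth > 0) {
    if (ncol(object@orthoWeights) != object@nOrth ||
        ncol(object@orthoLoadings) != object@nOrth)
      msg <- c(msg, "orthogonal weight/loading count must equal nOrth")
    nrm <- sqrt(colSums(object@orthoWeights^2))
    if (any(abs(nrm - 1) > 1e-8))
      msg <- c(msg, "orthogonal weights must have unit norm")
  }
  if (length(msg)) msg else TRUE
})

#' Cross-validation result for an OPLS discriminant model
#'
#' @slot q2 cross-validated goodness of prediction, 1 - PRESS/SS.
#' @slot press,ss prediction error sum of squares and total sum of squares
#'   about the overall response mean.
#' @slot predictions per-subject cross-validated predicted response, each
#'   subject predicted exactly once by the fold that held it out.
#' @slot observed the coded response.
#' @slot folds fold assignment (1..k), stratified by class.
#' @slot sensitivity,specificity fractions of disease/control subjects whose
#'   cross-validated prediction falls on the correct side of 0.5.
#' @slot nOrth orthogonal component count used.
#' @export
setClass("OplsCv", representation(
  q2 = "numeric",
  press = "numeric",
  ss = "numeric",
  predictions = "numeric",
  observed = "numeric",
  folds = "integer",
  sensitivity = "numeric",
  specificity = "numeric",
  nOrth = "integer"
))

setMethod("show", "MorphCohort", function(object) {
  grp <- table(SummarizedExperiment::colData(object)$group)
  cat("MorphCohort:", ncol(object), "subjects x", nrow(object), "ROI features\n")
  cat("groups:", paste(sprintf("%s=%d", names(grp), grp), collapse = ", "), "\n")
  extras <- setdiff(colnames(SummarizedExperiment::colData(object)),
                    c("group", "icv"))
  if (length(extras))
    cat("colData:", paste(extras, collapse = ", "), "\n")
})

setMethod("show", "OplsModel", function(object) {
  cat("OplsModel:", length(object@weights), "features,",
      object@nOrth, "orthogonal component(s)\n")
  cat(sprintf("coding: %s=0, %s=1; intercept %.3f\n",
              object@yCoding[["control"]], object@yCoding[["disease"]],
              object@yMean))
  cat("trained on", length(object@trainingIds), "subjects\n")
})

setMethod("show", "OplsCv", function(object) {
  k <- length(unique(object@folds))
  cat(sprintf(
    "OplsCv: %d-fold, nOrth=%d | Q2 = %.3f, sensitivity = %.3f, specificity = %.3f\n",
    k, object@nOrth, object@q2, object@sensitivity, object@specificity))
})

#' @describeIn OplsCv-class cross-validated Q2.
#' @param x an \code{OplsCv} object.
#' @export
q2 <- function(x) {
  stopifnot(is(x, "OplsCv"))
  x@q2
}

#' @describeIn OplsCv-class per-subject cross-validated predictions.
#' @export
cvPredictions <- function(x) {
  stopifnot(is(x, "OplsCv"))
  x@predictions
}

#' @describeIn OplsCv-class fold assignment used.
#' @export
foldAssignment <- function(x) {
  stopifnot(is(x, "OplsCv"))
  x@folds
}

#' @describeIn OplsCv-class sensitivity and specificity of the
#'   cross-validated predictions at the 0.5 threshold.
#' @export
cvClassification <- function(x) {
  stopifnot(is(x, "OplsCv"))
  c(sensitivity = x@sensitivity, specificity = x@specificity)
}
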