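#' Compute severity indices for a target group
#'
#' Projects the subjects of \code{targetGroup} onto a fitted model as
#' unseen data: the ICV adjustment and standardization stored with the
#' model (estimated on its training set) are applied, the stored
#' orthogonal variation is removed, and the predictive score is mapped to
#' the coded-y scale. Target subjects must be disjoint from the model's
#' training subjects unless \code{allowTrainingOverlap} is set (useful for
#' training-set diagnostics).
#'
#' @param model an [OplsModel-class] from [trainSeverityModel()].
#' @param cohort a [MorphCohort-class].
#' @param targetGroup group label to project (e.g. \code{"SMD"}).
#' @param allowTrainingOverlap override the leakage guard.
#' @return data.frame with \code{subject_id} and \code{index} (coded-y
#'   units, ~0-1 scale, not clipped), one row per subject in cohort order;
#'   attribute \code{model} carries the model fingerprint.
#' @export
computeIndex <- function(model, cohort, targetGroup,
                         allowTrainingOverlap = FALSE) {
  stopifnot(is(model, "OplsModel"), is(cohort, "MorphCohort"))
  grp <- cohortGroups(cohort)
  sel <- which(grp %in% targetGroup)
  if (length(sel) == 0) {
    out <- data.frame(subject_id = character(0), index = numeric(0))
    attr(out, "model") <- modelFingerprint(model)
    return(out)
  }
  X <- featureMatrix(cohort)[sel, , drop = FALSE]
  overlap <- intersect(rownames(X), model@trainingIds)
  if (length(overlap) && !allowTrainingOverlap)
    stop("leakage error: target subjects overlap the model training set ",
         "(e.g. ", overlap[1], "); set allowTrainingOverlap = TRUE for ",
         "training-set diagnostics")
  idx <- predict(model, X, raw = TRUE, icvValues = icv(cohort)[sel])
  out <- data.frame(subject_id = rownames(X), index = unname(idx),
                    row.names = NULL)
  attr(out, "model") <- modelFingerprint(model)
  out
}

#' Classify severity indices into subtypes
#'
#' Subjects with index >= cutoff are called disease-like
#' (\code{"AD-like"}); the tie at exactly the cutoff goes to the
#' disease-like class. The default cutoff 0.5 is the midpoint of the 0/1
#' class coding.
#'
#' @param results data.frame from [computeIndex()] (columns
#'   \code{subject_id}, \code{index}).
#' @param cutoff classification threshold (default 0.5).
#' @param labels length-2 labels for (disease-like, control-like)
#'   subtypes.
#' @return the input with an added \code{subtype} column and a
#'   \code{cutoff} column recording the rule used.
#' @export
classifySubtypes <- function(results, cutoff = 0.5,
                             labels = c("AD-like", "HC-like")) {
  stopifnot(is.data.frame(results), "index" %in% colnames(results))
  if (!all(is.finite(results$index))) stop("indices must be finite")
  if (!is.finite(cutoff)) stop("cutoff must be finite")
  results$subtype <- ifelse(results$index >= cutoff, labels[1], labels[2])
  results$cutoff <- cutoff
  results
}

#' Write / read an index CSV (subject_id, index, subtype)
#' @param results classified index data.frame.
#' @param path CSV path.
#' @export
writeIndexTable <- function(results, path) {
  utils::write.csv(results, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeIndexTable
#' @export
readIndexTable <- function(path) {
  if (!file.exists(path)) stop("index file not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
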