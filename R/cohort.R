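#' Construct a MorphCohort from a subject-by-feature matrix
#'
#' @param features numeric matrix, subjects x features, columns in schema
#'   order (names must equal \code{schema$name}).
#' @param meta data.frame of per-subject metadata; must contain
#'   \code{subject_id}, \code{group} and \code{icv}. Extra columns are kept.
#' @param schema ROI schema (see [defaultRoiSchema()]).
#' @return a [MorphCohort-class] object.
#' @export
MorphCohort <- function(features, meta, schema = defaultRoiSchema()) {
  schema <- validateRoiSchema(schema)
  features <- as.matrix(features)
  if (!identical(colnames(features), schema$name))
    stop("feature columns must match the schema names in order")
  if (!"subject_id" %in% colnames(meta))
    stop("meta must contain a subject_id column")
  if (anyDuplicated(meta$subject_id))
    stop("duplicate subject_id: ",
         meta$subject_id[duplicated(meta$subject_id)][1])
  rownames(features) <- meta$subject_id
  cd <- S4Vectors::DataFrame(meta[colnames(meta) != "subject_id"],
                             row.names = meta$subject_id)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(morpho = t(features)),
    rowData = S4Vectors::DataFrame(schema, row.names = schema$name),
    colData = cd)
  methods::new("MorphCohort", se)
}

#' @describeIn MorphCohort subject identifiers.
#' @param x a MorphCohort.
#' @export
subjectIds <- function(x) colnames(x)

#' @describeIn MorphCohort diagnostic group labels (HC/SMD/MCI/AD by
#'   default).
#' @export
cohortGroups <- function(x) {
  as.character(SummarizedExperiment::colData(x)$group)
}

#' @describeIn MorphCohort total intracranial volume per subject (mm^3).
#' @export
icv <- function(x) {
  setNames(SummarizedExperiment::colData(x)$icv, colnames(x))
}

#' @describeIn MorphCohort the ROI schema stored with the cohort.
#' @export
roiSchema <- function(x) {
  as.data.frame(SummarizedExperiment::rowData(x))[, c("name", "kind", "hemisphere")]
}

#' Assemble an analysis-ready feature matrix
#'
#' Returns the subjects-by-features matrix for the selected diagnostic
#' groups, columns exactly in schema order, rows in cohort (input) order.
#'
#' @param cohort a [MorphCohort-class].
#' @param groups character vector of group labels to include; \code{NULL}
#'   selects every subject.
#' @return numeric matrix with subject ids as row names.
#' @export
featureMatrix <- function(cohort, groups = NULL) {
  stopifnot(is(cohort, "MorphCohort"))
  grp <- cohortGroups(cohort)
  if (is.null(groups)) {
    sel <- seq_along(grp)
  } else {
    if (length(groups) == 0) stop("empty group selection")
    missing <- setdiff(groups, unique(grp))
    if (length(missing))
      stop("group(s) not present in cohort: ",
           paste(missing, collapse = ", "))
    sel <- which(grp %in% groups)
    if (length(sel) == 0) stop("empty group selection")
  }
  t(SummarizedExperiment::assay(cohort)[, sel, drop = FALSE])
}

requiredCohortColumns <- c("subject_id", "group", "age", "sex",
                           "education", "icv")

#' Read a cohort CSV
#'
#' Expected dialect: comma-separated, UTF-8, header row, "." decimal, one
#' baseline row per subject. Required columns: \code{subject_id},
#' \code{group}, \code{age}, \code{sex}, \code{education}, \code{icv};
#' optional \code{suvr} and \code{apoe_e4_count}; then one column per
#' schema feature, matched case-sensitively by name. Extra columns are
#' preserved as metadata.
#'
#' @param path path to the CSV file.
#' @param schema ROI schema to enforce.
#' @return a [MorphCohort-class].
#' @export
readCohortTable <- function(path, schema = defaultRoiSchema()) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  schema <- validateRoiSchema(schema)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(requiredCohortColumns, colnames(df))
  if (length(miss))
    stop("cohort file is missing required column(s): ",
         paste(miss, collapse = ", "))
  miss <- setdiff(schema$name, colnames(df))
  if (length(miss))
    stop("cohort file is missing feature column(s): ",
         paste(utils::head(miss, 5), collapse = ", "))
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject_id: ",
         df$subject_id[duplicated(df$subject_id)][1])
  feat <- as.matrix(df[, schema$name, drop = FALSE])
  if (!is.numeric(feat)) {
    bad <- which(!vapply(df[, schema$name, drop = FALSE], is.numeric,
                         logical(1)))[1]
    stop("non-numeric feature value in column '", schema$name[bad], "'")
  }
  if (!all(is.finite(feat))) {
    idx <- which(!is.finite(feat), arr.ind = TRUE)[1, ]
    stop("non-finite feature value at row ", idx[1], ", column '",
         schema$name[idx[2]], "'")
  }
  meta <- df[, setdiff(colnames(df), schema$name), drop = FALSE]
  MorphCohort(feat, meta, schema)
}

#' Write a cohort CSV
#'
#' Inverse of [readCohortTable()]: metadata columns first, then the
#' feature columns in schema order.
#'
#' @param cohort a [MorphCohort-class].
#' @param path output path.
#' @export
writeCohortTable <- function(cohort, path) {
  stopifnot(is(cohort, "MorphCohort"))
  cd <- as.data.frame(SummarizedExperiment::colData(cohort))
  df <- data.frame(subject_id = colnames(cohort), cd,
                   as.data.frame(featureMatrix(cohort)),
                   check.names = FALSE)
  rownames(df) <- NULL
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a long-format follow-up table
#'
#' Columns: \code{subject_id}, \code{month}, \code{diagnosis},
#' \code{mmse}, \code{cdr_sob}, \code{vital_status}. Months must be
#' strictly increasing within subject and every subject must have a
#' baseline (month 0) row.
#'
#' @param path CSV path.
#' @return data.frame in long format.
#' @export
readFollowupTable <- function(path) {
  if (!file.exists(path)) stop("follow-up file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validateFollowupTable(df)
}

#' @rdname readFollowupTable
#' @param followup long-format follow-up data.frame.
#' @export
writeFollowupTable <- function(followup, path) {
  followup <- validateFollowupTable(followup)
  utils::write.csv(followup, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname readFollowupTable
#' @export
validateFollowupTable <- function(followup) {
  need <- c("subject_id", "month", "diagnosis", "mmse", "cdr_sob",
            "vital_status")
  miss <- setdiff(need, colnames(followup))
  if (length(miss))
    stop("follow-up table is missing column(s): ",
         paste(miss, collapse = ", "))
  bymonth <- split(followup$month, followup$subject_id)
  if (any(vapply(bymonth, function(m) any(diff(m) <= 0), logical(1))))
    stop("visit months must be strictly increasing within subject")
  if (any(vapply(bymonth, function(m) m[1] != 0, logical(1))))
    stop("every subject needs a baseline (month 0) visit")
  followup[, need]
}
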