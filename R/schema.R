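#' ROI feature schema
#'
#' The schema is an ordered catalogue of ROI measure names with their kind
#' (\code{"thickness"} in mm or \code{"volume"} in mm^3) and hemisphere
#' (\code{left}, \code{right} or \code{bilateral}). The packaged default
#' lists 68 Desikan-Killiany cortical thickness measures, the matching 68
#' cortical volumes, and 51 subcortical segmentation volumes: 187 measures
#' in total. Column order is stable and defines the feature-matrix layout.
#' Alternative schemas of any length >= 2 may be supplied; the modelling
#' code is dimension-agnostic.
#'
#' @return A data.frame with columns \code{name}, \code{kind},
#'   \code{hemisphere}, one row per feature.
#' @examples
#' sch <- defaultRoiSchema()
#' nrow(sch)            # 187
#' table(sch$kind)
#' @export
defaultRoiSchema <- function() {
  path <- system.file("extdata", "roi_schema_dk187.csv",
                      package = "dsindex", mustWork = TRUE)
  readRoiSchema(path)
}

#' Read a ROI schema file
#'
#' One feature per line, comma-separated columns
#' \code{name,kind,hemisphere}.
#'
#' @param path path to a schema CSV.
#' @return validated schema data.frame.
#' @export
readRoiSchema <- function(path) {
  if (!file.exists(path)) stop("schema file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validateRoiSchema(df)
}

#' Validate a ROI schema
#'
#' @param schema data.frame with columns \code{name}, \code{kind},
#'   \code{hemisphere}.
#' @return the schema, invisibly unchanged, or an error.
#' @export
validateRoiSchema <- function(schema) {
  need <- c("name", "kind", "hemisphere")
  miss <- setdiff(need, colnames(schema))
  if (length(miss))
    stop("schema is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(schema) < 2)
    stop("schema must list at least 2 features")
  if (anyDuplicated(schema$name))
    stop("duplicate schema feature name: ",
         schema$name[duplicated(schema$name)][1])
  bad <- setdiff(unique(schema$kind), c("thickness", "volume"))
  if (length(bad))
    stop("unknown feature kind: ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(schema$hemisphere),
                 c("left", "right", "bilateral", "none"))
  if (length(bad))
    stop("unknown hemisphere label: ", paste(bad, collapse = ", "))
  schema[, need]
}

#' Write a schema to file
#' @param schema validated schema data.frame.
#' @param path output path.
#' @export
writeRoiSchema <- function(schema, path) {
  schema <- validateRoiSchema(schema)
  utils::write.csv(schema, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# indices of volume-kind columns (the ones subject to ICV adjustment)
schemaVolumeColumns <- function(schema) {
  which(schema$kind == "volume")
}
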