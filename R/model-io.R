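#' Write an OPLS model to a versioned JSON file
#'
#' Serializes every slot (weights, loadings, orthogonal components,
#' intercept, class coding, scaling parameters, feature names, training
#' ids, a schema fingerprint) at full double precision so that
#' [readOplsModel()] round-trips exactly.
#'
#' @param model an [OplsModel-class].
#' @param path output path (conventionally \code{model.json}).
#' @export
writeOplsModel <- function(model, path) {
  stopifnot(is(model, "OplsModel"))
  obj <- list(
    format = "dsindex-opls", version = 1L,
    fingerprint = modelFingerprint(model),
    yCoding = as.list(model@yCoding),
    yMean = model@yMean,
    yLoading = model@yLoading,
    nOrth = model@nOrth,
    featureNames = model@featureNames,
    trainingIds = model@trainingIds,
    weights = unname(model@weights),
    loadings = unname(model@loadings),
    orthoWeights = asColumnList(model@orthoWeights),
    orthoLoadings = asColumnList(model@orthoLoadings),
    scores = model@scores,
    fitted = model@fitted,
    scaling = serializeScaling(model@scaling))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

asColumnList <- function(m) lapply(seq_len(ncol(m)), function(j) m[, j])

serializeScaling <- function(scaling) {
  if (length(scaling) == 0) return(NULL)
  icvp <- scaling$icv
  if (!is.null(icvp) && identical(icvp$mode, "residualize"))
    icvp <- list(mode = "residualize",
                 volumeCols = icvp$volumeCols,
                 intercept = unname(icvp$coefs["intercept", ]),
                 slope = unname(icvp$coefs["slope", ]))
  std <- scaling$std
  list(icv = icvp,
       std = list(columns = names(std$center),
                  center = unname(std$center), scale = unname(std$scale),
                  dropped = std$dropped, method = std$method))
}

#' Read an OPLS model from JSON
#'
#' @param path path written by [writeOplsModel()].
#' @return an [OplsModel-class] identical to the one written.
#' @export
readOplsModel <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "dsindex-opls"))
    stop("not a dsindex OPLS model file")
  fn <- obj$featureNames
  p <- length(fn)
  toMat <- function(x) {
    if (length(x) == 0) return(matrix(0, p, 0, dimnames = list(fn, NULL)))
    # simplifyVector turns the column list into an nOrth x p matrix
    m <- if (is.matrix(x)) t(x)
         else if (is.list(x)) do.call(cbind, x)
         else matrix(x, ncol = 1)
    rownames(m) <- fn
    m
  }
  scaling <- list()
  if (!is.null(obj$scaling)) {
    icvp <- obj$scaling$icv
    if (!is.null(icvp) && identical(icvp$mode, "residualize")) {
      coefs <- rbind(intercept = icvp$intercept, slope = icvp$slope)
      colnames(coefs) <- icvp$volumeCols
      icvp <- list(mode = "residualize", coefs = coefs,
                   volumeCols = icvp$volumeCols)
    }
    std <- obj$scaling$std
    scaling <- list(
      icv = icvp,
      std = list(center = setNames(std$center, std$columns),
                 scale = setNames(std$scale, std$columns),
                 dropped = as.character(std$dropped %||% character(0)),
                 method = std$method))
  }
  model <- methods::new("OplsModel",
    weights = setNames(obj$weights, fn),
    loadings = setNames(obj$loadings, fn),
    yLoading = obj$yLoading,
    orthoWeights = toMat(obj$orthoWeights),
    orthoLoadings = toMat(obj$orthoLoadings),
    nOrth = as.integer(obj$nOrth),
    yMean = obj$yMean,
    yCoding = unlist(obj$yCoding),
    scaling = scaling,
    featureNames = fn,
    trainingIds = as.character(obj$trainingIds %||% character(0)),
    scores = as.numeric(obj$scores),
    fitted = as.numeric(obj$fitted))
  methods::validObject(model)
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fingerprint of a model's feature space
#'
#' A short FNV-1a hash over the ordered feature names and orthogonal
#' component count, stamped into index results for provenance.
#'
#' @param model an [OplsModel-class].
#' @return 8-hex-digit character scalar.
#' @export
modelFingerprint <- function(model) {
  s <- paste(c(model@featureNames, model@nOrth,
               model@yCoding), collapse = "|")
  fnv1a32(s)
}

# 32-bit FNV-1a over a character scalar, arithmetic kept exact in doubles
# (the 32x24-bit product is split so intermediates stay below 2^53)
fnv1a32 <- function(s) {
  h <- 2166136261
  prime <- 16777619
  for (b in utf8ToInt(s)) {
    h <- bitwXor64(h, b)
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (((hi * prime) %% 65536) * 65536 + lo * prime) %% 4294967296
  }
  lo <- h %% 65536
  sprintf("%04x%04x", as.integer((h - lo) / 65536), as.integer(lo))
}

bitwXor64 <- function(a, b) {
  # bitwXor works on 32-bit ints; split the double into two halves
  lo <- a %% 65536
  hi <- (a - lo) / 65536
  lob <- b %% 65536
  hib <- (b - lob) / 65536
  bitwXor(hi, hib) * 65536 + bitwXor(lo, lob)
}
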