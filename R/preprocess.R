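#' Adjust volume features for intracranial volume
#'
#' Three modes:
#' \describe{
#'   \item{residualize}{each volume-kind column is replaced by the
#'     residuals from a straight-line fit of the column on ICV, estimated
#'     on the training rows and applied to all rows; thickness columns are
#'     untouched. The default for morphometry.}
#'   \item{append}{ICV is appended as one extra column named \code{ICV}
#'     (standardized downstream like any other feature).}
#'   \item{none}{identity.}
#' }
#'
#' @param X subjects-by-features numeric matrix.
#' @param icvValues per-row intracranial volume, finite and positive.
#' @param volumeCols integer indices (or names) of volume-kind columns.
#' @param mode one of \code{"residualize"}, \code{"append"}, \code{"none"}.
#' @param trainMask integer indices of training rows used to estimate the
#'   line fits; defaults to all rows.
#' @return list with \code{features} (adjusted matrix) and \code{params}
#'   (the fitted adjustment, reusable via [applyIcvAdjustment()]).
#' @export
adjustIcv <- function(X, icvValues, volumeCols,
                      mode = c("residualize", "append", "none"),
                      trainMask = seq_len(nrow(X))) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  if (mode == "none")
    return(list(features = X, params = list(mode = "none")))
  if (length(icvValues) != nrow(X) || !all(is.finite(icvValues)) ||
      any(icvValues <= 0))
    stop("icv must be finite, positive and one value per row")
  if (mode == "append") {
    out <- cbind(X, ICV = icvValues)
    return(list(features = out, params = list(mode = "append")))
  }
  if (length(trainMask) == 0) stop("trainMask must be non-empty")
  if (is.character(volumeCols)) volumeCols <- match(volumeCols, colnames(X))
  icvTr <- icvValues[trainMask]
  if (var(icvTr) < 1e-12)
    stop("degenerate covariate: zero ICV variance in training rows")
  coefs <- vapply(volumeCols, function(j) {
    xj <- X[trainMask, j]
    slope <- cov(icvTr, xj) / var(icvTr)
    c(intercept = mean(xj) - slope * mean(icvTr), slope = slope)
  }, numeric(2))
  colnames(coefs) <- colnames(X)[volumeCols]
  params <- list(mode = "residualize", coefs = coefs,
                 volumeCols = colnames(X)[volumeCols])
  list(features = applyIcvAdjustment(X, icvValues, params), params = params)
}

#' Apply a stored ICV adjustment to new rows
#'
#' @param X subjects-by-features matrix with the same columns as at fit
#'   time.
#' @param icvValues per-row ICV.
#' @param params the \code{params} element returned by [adjustIcv()].
#' @return adjusted matrix.
#' @export
applyIcvAdjustment <- function(X, icvValues, params) {
  X <- as.matrix(X)
  if (is.null(params) || params$mode == "none") return(X)
  if (params$mode == "append") return(cbind(X, ICV = icvValues))
  cols <- params$volumeCols
  if (!all(cols %in% colnames(X)))
    stop("alignment error: volume columns missing from matrix")
  X[, cols] <- X[, cols] -
    (rep(1, nrow(X)) %*% t(params$coefs["intercept", ]) +
       icvValues %*% t(params$coefs["slope", ]))
  X
}

#' Standardize feature columns with train/apply separation
#'
#' When \code{params} is absent, per-column centre and scale are estimated
#' on the training rows (sd with n-1 denominator), columns with zero
#' training variance are dropped with a warning, and the transform is
#' applied to all rows. When \code{params} is supplied the stored transform
#' is applied without re-estimation, so statistics never leak from
#' projected subjects.
#'
#' @param X subjects-by-features matrix.
#' @param trainMask training row indices (defaults to all rows).
#' @param method \code{"uv"} (unit variance, the default) or
#'   \code{"pareto"} (scale by sqrt of sd).
#' @param params previously fitted parameters, to apply instead of fit.
#' @return list with \code{features} and \code{params} (centre, scale,
#'   dropped column names, method).
#' @export
standardizeFeatures <- function(X, trainMask = seq_len(nrow(X)),
                                method = c("uv", "pareto"), params = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  if (!is.null(params))
    return(list(features = applyStandardization(X, params), params = params))
  method <- match.arg(method)
  if (length(trainMask) == 0) stop("trainMask must be non-empty")
  tr <- X[trainMask, , drop = FALSE]
  ctr <- colMeans(tr)
  sds <- apply(tr, 2, sd)
  dropped <- colnames(X)[sds < 1e-12]
  if (length(dropped))
    warning("dropping zero-variance column(s): ",
            paste(dropped, collapse = ", "))
  keep <- sds >= 1e-12
  scl <- if (method == "pareto") sqrt(sds[keep]) else sds[keep]
  params <- list(center = ctr[keep], scale = scl, dropped = dropped,
                 method = method)
  list(features = applyStandardization(X, params), params = params)
}

#' Apply stored standardization parameters
#'
#' @param X matrix whose columns cover the fitted columns by name.
#' @param params \code{params} from [standardizeFeatures()].
#' @return standardized matrix restricted to the retained columns.
#' @export
applyStandardization <- function(X, params) {
  X <- as.matrix(X)
  cols <- names(params$center)
  if (is.null(colnames(X))) {
    if (length(params$dropped) || ncol(X) != length(cols))
      stop("alignment error: unnamed matrix cannot be aligned to scaling ",
           "params")
    colnames(X) <- cols
  }
  if (!all(cols %in% colnames(X)))
    stop("alignment error: matrix is missing fitted column(s)")
  sweep(sweep(X[, cols, drop = FALSE], 2, params$center, "-"),
        2, params$scale, "/")
}
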