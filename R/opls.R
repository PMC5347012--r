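#' Fit an OPLS discriminant model
#'
#' Orthogonal projections to latent structures for a binary response:
#' systematic predictor variation is split into one predictive component
#' (correlated with the class code) and \code{nOrth} orthogonal components
#' (class-uncorrelated, removed by deflation). With the response coded
#' control = 0 / disease = 1 and centred, each orthogonal round computes
#' the candidate weight w* proportional to X'y, its score t* = Xw* and
#' loading p* = X't*/(t*'t*), the orthogonal weight w_o proportional to
#' p* - (w*'p*)w*, score t_o = Xw_o and loading p_o = X't_o/(t_o't_o), and
#' deflates X <- X - t_o p_o'. The single predictive component is then
#' fitted on the deflated matrix (w proportional to X'y, t = Xw,
#' p = X't/(t't), c = y't/(t't)); the prediction for a subject x is
#' c * t(x) + mean(y) after removing the stored orthogonal variation.
#'
#' @param X numeric matrix, subjects x features; normally standardized
#'   (see [standardizeFeatures()]). Row names, if present, are kept as
#'   training ids.
#' @param y numeric response coded 0 (control) / 1 (disease); both classes
#'   must be present.
#' @param nOrth number of orthogonal components (>= 0).
#' @param yCoding optional named character vector
#'   \code{c(control=, disease=)} recording which labels the codes stand
#'   for.
#' @return an [OplsModel-class].
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(60), 20, 3)
#' y <- rep(c(0, 1), each = 10)
#' m <- fitOpls(scale(X), y, nOrth = 1)
#' @export
fitOpls <- function(X, y, nOrth = 0L,
                    yCoding = c(control = "0", disease = "1")) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  if (!all(y %in% c(0, 1)) || length(unique(y)) < 2)
    stop("degenerate labels: y must contain both classes coded 0/1")
  nOrth <- as.integer(nOrth)
  if (nOrth < 0) stop("nOrth must be >= 0")
  if (nrow(X) < nOrth + 2) stop("need at least nOrth + 2 rows")
  p <- ncol(X)
  yMean <- mean(y)
  yc <- y - yMean
  Xd <- X
  Wo <- matrix(0, p, nOrth)
  Po <- matrix(0, p, nOrth)
  for (i in seq_len(nOrth)) {
    wstar <- drop(crossprod(Xd, yc))
    nw <- sqrt(sum(wstar^2))
    if (nw < 1e-12) stop("no covariance between X and y")
    wstar <- wstar / nw
    tstar <- drop(Xd %*% wstar)
    pstar <- drop(crossprod(Xd, tstar)) / sum(tstar^2)
    wo <- pstar - sum(wstar * pstar) * wstar
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-12)
      stop("no orthogonal variation left after ", i - 1, " component(s)")
    wo <- wo / nwo
    to <- drop(Xd %*% wo)
    po <- drop(crossprod(Xd, to)) / sum(to^2)
    Xd <- Xd - tcrossprod(to, po)
    Wo[, i] <- wo
    Po[, i] <- po
  }
  w <- drop(crossprod(Xd, yc))
  nw <- sqrt(sum(w^2))
  if (nw < 1e-12) stop("no covariance between X and y")
  w <- w / nw
  tt <- drop(Xd %*% w)
  pp <- drop(crossprod(Xd, tt)) / sum(tt^2)
  cc <- sum(yc * tt) / sum(tt^2)
  fn <- if (is.null(colnames(X))) paste0("V", seq_len(p)) else colnames(X)
  rownames(Wo) <- rownames(Po) <- fn
  methods::new("OplsModel",
    weights = setNames(w, fn), loadings = setNames(pp, fn), yLoading = cc,
    orthoWeights = Wo, orthoLoadings = Po, nOrth = nOrth, yMean = yMean,
    yCoding = yCoding, scaling = list(),
    featureNames = fn,
    trainingIds = if (is.null(rownames(X))) character(0) else rownames(X),
    scores = unname(tt), fitted = unname(cc * tt + yMean))
}

# remove the stored orthogonal components from rows of X (model space)
deflateOrtho <- function(model, X) {
  for (i in seq_len(model@nOrth)) {
    to <- drop(X %*% model@orthoWeights[, i])
    X <- X - tcrossprod(to, model@orthoLoadings[, i])
  }
  X
}

# align columns of X to the model feature space, by name when available
alignToModel <- function(model, X) {
  X <- as.matrix(X)
  fn <- model@featureNames
  if (!is.null(colnames(X))) {
    if (!all(fn %in% colnames(X)))
      stop("alignment error: matrix is missing model feature(s)")
    X <- X[, fn, drop = FALSE]
  } else if (ncol(X) != length(fn)) {
    stop("alignment error: column count does not match the model")
  }
  X
}

#' Project subjects onto a fitted OPLS model
#'
#' For each row the stored orthogonal components are removed sequentially
#' (t_o = x'w_o; x <- x - t_o p_o), the predictive score t = x'w is formed
#' and the severity index c*t + yMean is returned, on the coded-y scale
#' (close to 0 = control-like, close to 1 = disease-like; values are not
#' clipped). Projecting the training matrix reproduces the training fitted
#' values exactly.
#'
#' @param object an [OplsModel-class].
#' @param newdata subjects-by-features matrix. If \code{raw = TRUE} it is
#'   first passed through the ICV adjustment and standardization stored in
#'   the model (fitted on the training set only).
#' @param raw whether \code{newdata} is on the raw feature scale.
#' @param icvValues per-row ICV, required when \code{raw = TRUE} and the
#'   model stores a residualizing ICV adjustment.
#' @param ... ignored.
#' @return numeric vector of severity indices, named by row.
#' @export
setMethod("predict", "OplsModel",
          function(object, newdata, raw = FALSE, icvValues = NULL, ...) {
  X <- as.matrix(newdata)
  if (raw) {
    if (length(object@scaling) == 0)
      stop("model stores no scaling parameters; cannot project raw data")
    X <- applyIcvAdjustment(X, icvValues, object@scaling$icv)
    X <- applyStandardization(X, object@scaling$std)
  }
  X <- alignToModel(object, X)
  X <- deflateOrtho(object, X)
  tt <- drop(X %*% object@weights)
  setNames(object@yLoading * tt + object@yMean, rownames(X))
})

#' Seeded stratified fold assignment
#'
#' Class-stratified: each class's shuffled members are dealt around the
#' folds with a continuing counter, so fold sizes differ by at most one
#' overall and per class.
#'
#' @param y class labels.
#' @param k number of folds.
#' @param seed RNG seed.
#' @return integer fold id (1..k) per subject.
#' @export
stratifiedFolds <- function(y, k, seed = 1L) {
  k <- as.integer(k)
  if (k < 2) stop("k must be >= 2")
  tab <- table(y)
  if (any(tab < k))
    stop("stratification error: every class needs at least k members")
  set.seed(seed)
  folds <- integer(length(y))
  counter <- 0L
  for (cl in names(tab)) {
    idx <- sample(which(y == cl))
    folds[idx] <- ((counter + seq_along(idx) - 1L) %% k) + 1L
    counter <- counter + length(idx)
  }
  folds
}

#' Cross-validate an OPLS discriminant model
#'
#' Stratified k-fold cross-validation with the entire preprocessing chain
#' (optional ICV adjustment, standardization) re-estimated inside each
#' training split, so no statistic leaks from held-out subjects. Reports
#' Q2 = 1 - PRESS/SS (SS about the overall response mean) together with
#' sensitivity and specificity of the cross-validated predictions
#' thresholded at 0.5 (disease class positive).
#'
#' @param X raw subjects-by-features matrix.
#' @param y response coded 0/1.
#' @param k number of folds (default 7).
#' @param nOrth orthogonal components per fold model.
#' @param seed seed for the fold assignment.
#' @param icvValues optional per-row ICV enabling the ICV stage.
#' @param volumeCols volume column indices/names for residualization.
#' @param icvMode see [adjustIcv()].
#' @param method scaling method, see [standardizeFeatures()].
#' @return an [OplsCv-class].
#' @export
crossValidate <- function(X, y, k = 7L, nOrth = 0L, seed = 1L,
                          icvValues = NULL, volumeCols = NULL,
                          icvMode = c("residualize", "append", "none"),
                          method = "uv") {
  icvMode <- if (is.null(icvValues)) "none" else match.arg(icvMode)
  X <- as.matrix(X)
  y <- as.numeric(y)
  folds <- stratifiedFolds(y, k, seed)
  pred <- numeric(length(y))
  for (f in seq_len(k)) {
    tr <- which(folds != f)
    te <- which(folds == f)
    adj <- adjustIcv(X, icvValues, volumeCols, icvMode, trainMask = tr)
    std <- suppressWarnings(
      standardizeFeatures(adj$features, trainMask = tr, method = method))
    m <- fitOpls(std$features[tr, , drop = FALSE], y[tr], nOrth)
    pred[te] <- predict(m, std$features[te, , drop = FALSE])
  }
  press <- sum((y - pred)^2)
  ss <- sum((y - mean(y))^2)
  methods::new("OplsCv",
    q2 = 1 - press / ss, press = press, ss = ss, predictions = pred,
    observed = y, folds = folds,
    sensitivity = mean(pred[y == 1] >= 0.5),
    specificity = mean(pred[y == 0] < 0.5),
    nOrth = as.integer(nOrth))
}

#' Choose the orthogonal component count by cross-validated Q2 gain
#'
#' Returns the smallest n such that Q2(n+1) - Q2(n) < \code{tol}, capped at
#' \code{maxOrth}. Deterministic given the seed.
#'
#' @inheritParams crossValidate
#' @param maxOrth upper bound on the component count.
#' @param tol minimum Q2 gain that justifies one more component.
#' @return integer component count.
#' @export
selectOrthogonalComponents <- function(X, y, k = 7L, seed = 1L,
                                       maxOrth = 5L, tol = 0.01,
                                       icvValues = NULL, volumeCols = NULL,
                                       icvMode = "residualize",
                                       method = "uv") {
  maxOrth <- as.integer(maxOrth)
  if (maxOrth <= 0) return(0L)
  q2s <- vapply(0:maxOrth, function(n)
    q2(crossValidate(X, y, k = k, nOrth = n, seed = seed,
                     icvValues = icvValues, volumeCols = volumeCols,
                     icvMode = icvMode, method = method)),
    numeric(1))
  for (n in 0:(maxOrth - 1)) {
    if (q2s[n + 2] - q2s[n + 1] < tol) return(n)
  }
  maxOrth
}

#' Rank variables by their covariance with the predictive score
#'
#' Computes, for every feature of the (orthogonality-filtered,
#' standardized) training matrix, the sample covariance and correlation
#' with the predictive score t, ranked by absolute covariance. The sign is
#' oriented so that positive covariance means a larger value in the
#' control class (atrophied regions rank positive, enlarged ventricles
#' negative).
#'
#' @param model fitted [OplsModel-class].
#' @param X the standardized training matrix the model was fitted on
#'   (i.e. the matrix passed to [fitOpls()]).
#' @param topK number of top-ranked features to return (default 25);
#'   \code{Inf} returns all.
#' @return data.frame with \code{feature}, \code{covariance},
#'   \code{correlation}, ordered by importance.
#' @export
variableImportance <- function(model, X, topK = 25) {
  X <- alignToModel(model, X)
  Xd <- deflateOrtho(model, X)
  tt <- drop(Xd %*% model@weights)
  covv <- drop(cov(Xd, tt))
  sds <- apply(Xd, 2, sd)
  corr <- ifelse(sds < 1e-12, 0, covv / (sds * sd(tt)))
  # orient: t points towards disease=1, so flip to "positive = larger in
  # controls"
  covv <- -covv
  corr <- -corr
  ord <- order(abs(covv), decreasing = TRUE)
  out <- data.frame(feature = model@featureNames[ord],
                    covariance = covv[ord], correlation = corr[ord],
                    row.names = NULL)
  utils::head(out, topK)
}

#' Train a severity model on a cohort
#'
#' High-level wrapper: builds the control/disease feature matrix, applies
#' ICV adjustment and standardization (estimated on the training set and
#' stored in the model), optionally selects the orthogonal component count
#' by cross-validated Q2 gain, and fits the OPLS discriminant model. The
#' returned model projects raw unseen subjects via [predict()] or
#' [computeIndex()].
#'
#' @param cohort a [MorphCohort-class].
#' @param disease,control group labels coded 1 and 0.
#' @param nOrth integer, or \code{"auto"} for Q2-gain selection.
#' @param folds CV folds used for selection (default 7).
#' @param seed seed for fold assignment.
#' @param icvMode see [adjustIcv()].
#' @param method scaling method.
#' @param maxOrth cap for automatic selection.
#' @return an [OplsModel-class] with scaling and training ids filled in.
#' @export
trainSeverityModel <- function(cohort, disease = "AD", control = "HC",
                               nOrth = "auto", folds = 7L, seed = 1L,
                               icvMode = "residualize", method = "uv",
                               maxOrth = 5L) {
  X <- featureMatrix(cohort, c(control, disease))
  grp <- cohortGroups(cohort)
  grp <- grp[grp %in% c(control, disease)]
  y <- as.numeric(grp == disease)
  icvs <- icv(cohort)[rownames(X)]
  volumeCols <- roiSchema(cohort)$name[schemaVolumeColumns(roiSchema(cohort))]
  if (identical(nOrth, "auto"))
    nOrth <- selectOrthogonalComponents(
      X, y, k = folds, seed = seed, maxOrth = maxOrth,
      icvValues = icvs, volumeCols = volumeCols, icvMode = icvMode,
      method = method)
  adj <- adjustIcv(X, icvs, volumeCols, icvMode)
  std <- suppressWarnings(standardizeFeatures(adj$features, method = method))
  model <- fitOpls(std$features, y, nOrth,
                   yCoding = c(control = control, disease = disease))
  model@scaling <- list(icv = adj$params, std = std$params)
  model@trainingIds <- rownames(X)
  methods::validObject(model)
  model
}
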