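test_that("fit matches a literal transcription of the deflation recipe", {
  set.seed(10)
  for (nOrth in 0:2) {
    X <- scale(matrix(rnorm(6 * 3), 6, 3))
    attr(X, "scaled:center") <- attr(X, "scaled:scale") <- NULL
    y <- c(0, 0, 0, 1, 1, 1)
    m <- fitOpls(X, y, nOrth)
    o <- oracleOplsFit(X, y, nOrth)
    expect_equal(unname(m@weights), o$w, tolerance = 1e-10)
    expect_equal(unname(m@loadings), o$p, tolerance = 1e-10)
    expect_equal(m@yLoading, o$c, tolerance = 1e-10)
    expect_equal(m@fitted, o$fitted, tolerance = 1e-10)
    if (nOrth > 0) {
      for (i in seq_len(nOrth)) {
        expect_equal(unname(m@orthoWeights[, i]), o$Wo[[i]],
                     tolerance = 1e-10)
        expect_equal(unname(m@orthoLoadings[, i]), o$Po[[i]],
                     tolerance = 1e-10)
      }
    }
  }
})

test_that("a perfect predictor column gets all the weight", {
  y <- rep(c(0, 1), each = 5)
  yc <- y - mean(y)
  set.seed(4)
  X <- cbind(sig = yc, n1 = rnorm(10), n2 = rnorm(10))
  # make noise columns exactly orthogonal to y so weights vanish there
  X[, "n1"] <- X[, "n1"] - yc * sum(X[, "n1"] * yc) / sum(yc^2)
  X[, "n2"] <- X[, "n2"] - yc * sum(X[, "n2"] * yc) / sum(yc^2)
  m <- fitOpls(X, y, 0)
  expect_equal(abs(unname(m@weights["sig"])), 1, tolerance = 1e-12)
  expect_equal(unname(abs(m@weights[c("n1", "n2")])), c(0, 0),
               tolerance = 1e-12)
  expect_equal(m@fitted, y, tolerance = 1e-10)
})

test_that("nOrth = 0 reduces to closed-form single-component PLS1", {
  set.seed(5)
  for (i in 1:5) {
    X <- matrix(rnorm(20 * 7), 20, 7)
    y <- rep(c(0, 1), each = 10)
    yc <- y - mean(y)
    m <- fitOpls(X, y, 0)
    wClosed <- drop(crossprod(X, yc))
    wClosed <- wClosed / sqrt(sum(wClosed^2))
    expect_equal(unname(m@weights), wClosed, tolerance = 1e-12)
  }
})

test_that("orthogonal scores have zero covariance with y and with t", {
  set.seed(6)
  X <- scale(matrix(rnorm(30 * 12), 30, 12))
  y <- rep(c(0, 1), each = 15)
  m <- fitOpls(X, y, 3)
  Xd <- X
  for (i in 1:3) {
    to <- drop(Xd %*% m@orthoWeights[, i])
    expect_lt(abs(sum(to * (y - mean(y)))), 1e-8)
    expect_lt(abs(sum(to * m@scores)), 1e-8)
    Xd <- Xd - tcrossprod(to, m@orthoLoadings[, i])
  }
})

test_that("projection reproduces training fits and centering identity", {
  set.seed(7)
  X <- scale(matrix(rnorm(24 * 9), 24, 9))
  attr(X, "scaled:center") <- attr(X, "scaled:scale") <- NULL
  y <- rep(c(0, 1), c(16, 8))
  m <- fitOpls(X, y, 2)
  expect_equal(unname(predict(m, X)), m@fitted, tolerance = 1e-12)
  # the all-training-mean profile maps to the disease prevalence
  expect_equal(unname(predict(m, matrix(0, 1, 9))), mean(y),
               tolerance = 1e-12)
})

test_that("indices are invariant to orthogonal-loading perturbations", {
  set.seed(8)
  X <- scale(matrix(rnorm(40 * 15), 40, 15))
  y <- rep(c(0, 1), each = 20)
  m <- fitOpls(X, y, 2)
  x0 <- X[3, , drop = FALSE]
  base <- predict(m, x0)
  for (alpha in c(-2, 0.5, 3)) {
    pert <- x0 + alpha * m@orthoLoadings[, 1] + 0.7 * alpha *
      m@orthoLoadings[, 2]
    expect_equal(unname(predict(m, matrix(pert, 1))), unname(base),
                 tolerance = 1e-8)
  }
})

test_that("scaling the planted contrast strictly increases the index", {
  cfg <- simulationConfig(seed = 21)
  coh <- generateCohort(cfg)
  m <- trainSeverityModel(coh, nOrth = 1, seed = 21)
  # raw-scale contrast: effect (d units) times baseline feature sd
  sch <- roiSchema(coh)
  eff <- makeAtrophyPattern(sch, defaultEffectMap())
  baseSd <- ifelse(sch$kind == "thickness", 0.15,
                   ifelse(grepl("^(lh|rh)_", sch$name), 500,
                          ifelse(grepl("vent", tolower(sch$name)), 350, 400)))
  hcMean <- colMeans(featureMatrix(coh, "HC"))
  idx <- sapply(c(0, 0.5, 1, 1.5), function(lam) {
    x <- matrix(hcMean + lam * eff * baseSd, 1,
                dimnames = list("probe", sch$name))
    unname(predict(m, x, raw = TRUE, icvValues = cfg$icvMean))
  })
  expect_true(all(diff(idx) > 0))
})

test_that("degenerate inputs raise informative errors", {
  X <- matrix(rnorm(12), 6, 2)
  expect_error(fitOpls(X, rep(1, 6), 0), "degenerate")
  expect_error(fitOpls(X, c(0, 0, 0, 1, 1, 1), -1), "nOrth")
  expect_error(fitOpls(matrix(0, 6, 2), c(0, 0, 0, 1, 1, 1), 0),
               "covariance")
  m <- fitOpls(X, c(0, 0, 0, 1, 1, 1), 0)
  expect_error(predict(m, matrix(rnorm(9), 3, 3)), "alignment")
})

test_that("variable importance ranks the planted pattern on top", {
  coh <- generateCohort(simulationConfig(seed = 9))
  m <- trainSeverityModel(coh, nOrth = 1, seed = 9)
  X <- featureMatrix(coh, c("HC", "AD"))
  Xstd <- applyStandardization(
    applyIcvAdjustment(X, icv(coh)[rownames(X)], m@scaling$icv),
    m@scaling$std)
  imp <- variableImportance(m, Xstd, topK = 25)
  planted <- names(which(makeAtrophyPattern(roiSchema(coh),
                                            defaultEffectMap()) != 0))
  expect_true(all(planted %in% imp$feature))
  # atrophied regions positive (larger in controls), ventricles negative
  expect_true(all(imp$covariance[imp$feature %in%
    c("Left-Hippocampus", "rh_entorhinal_thickness")] > 0))
  expect_true(all(imp$covariance[imp$feature %in%
    c("Left-Inf-Lat-Vent", "Right-Inf-Lat-Vent")] < 0))
  # a feature independent of y ranks at the bottom of the full list
  full <- variableImportance(m, Xstd, topK = Inf)
  expect_gt(min(abs(full$covariance[1:25])),
            abs(full$covariance[nrow(full)]))
})
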