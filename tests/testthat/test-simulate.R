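smallConfig <- function(seed = 1, ...) {
  simulationConfig(groupSizes = c(HC = 20, SMD = 15, MCI = 5, AD = 12),
                   nAdLikeSmd = 3, seed = seed, ...)
}

test_that("atrophy pattern expansion maps region keys onto the schema", {
  sch <- defaultRoiSchema()
  expect_true(all(makeAtrophyPattern(sch, c()) == 0))

  eff <- makeAtrophyPattern(sch, c(hippocampus = -2.5,
                                   "inf-lat-vent" = 2))
  nz <- names(eff[eff != 0])
  expect_setequal(nz, c("Left-Hippocampus", "Right-Hippocampus",
                        "Left-Inf-Lat-Vent", "Right-Inf-Lat-Vent"))
  expect_equal(unname(eff["Left-Hippocampus"]), -2.5)
  expect_equal(unname(eff["Right-Inf-Lat-Vent"]), 2)

  expect_error(makeAtrophyPattern(sch, c(cerebellum_vermis = -1)),
               "not found")
})

test_that("default pattern covers exactly the configured AD signature", {
  eff <- makeAtrophyPattern(defaultRoiSchema(), defaultEffectMap())
  nz <- names(eff[eff != 0])
  regions <- c("hippocampus", "entorhinal", "inferiorparietal", "amygdala",
               "precuneus", "inflatvent")
  hit <- sapply(nz, function(n)
    any(sapply(regions, grepl, x = gsub("[^a-z0-9]", "", tolower(n)),
               fixed = TRUE)))
  expect_true(all(hit))
  # both hemispheres, thickness and volume for cortical regions
  expect_true(all(c("lh_entorhinal_thickness", "rh_entorhinal_volume",
                    "Left-Amygdala", "rh_precuneus_volume",
                    "lh_inferiorparietal_thickness") %in% nz))
  expect_true(all(eff[c("Left-Inf-Lat-Vent", "Right-Inf-Lat-Vent")] > 0))
  expect_true(all(eff[setdiff(nz, c("Left-Inf-Lat-Vent",
                                    "Right-Inf-Lat-Vent"))] < 0))
})

test_that("generation is deterministic and conserves the planted truth", {
  cfg <- smallConfig(seed = 11)
  a <- generateCohort(cfg)
  b <- generateCohort(cfg)
  expect_identical(SummarizedExperiment::assay(a),
                   SummarizedExperiment::assay(b))
  expect_identical(as.data.frame(SummarizedExperiment::colData(a)),
                   as.data.frame(SummarizedExperiment::colData(b)))
  expect_equal(sum(SummarizedExperiment::colData(a)$truth_adlike), 3)
  expect_equal(as.vector(table(cohortGroups(a))[c("HC", "SMD", "MCI", "AD")]),
               c(20, 15, 5, 12))
  fa <- generateFollowup(a, cfg)
  fb <- generateFollowup(b, cfg)
  expect_identical(fa, fb)
})

test_that("default config reproduces the study group sizes", {
  coh <- generateCohort(simulationConfig(seed = 2))
  expect_equal(as.vector(table(cohortGroups(coh))[c("HC", "SMD", "MCI", "AD")]),
               c(69, 86, 45, 38))
  expect_equal(sum(SummarizedExperiment::colData(coh)$truth_adlike), 11)
})

test_that("group means match the closed-form generating distribution", {
  cfg <- simulationConfig(seed = 5)
  coh <- generateCohort(cfg)
  X <- featureMatrix(coh, "AD")
  # hippocampus: baseline 4000 (sd 400), d = -2.5, ICV coupling with
  # E[icv/mean]=1 leaves the expectation at the shifted mean
  mu <- 4000 + 400 * (-2.5)
  tau <- cfg$icvSd / cfg$icvMean
  sdProd <- sqrt(400^2 * (1 + tau^2) + mu^2 * tau^2)
  se <- sdProd / sqrt(nrow(X))
  expect_lt(abs(mean(X[, "Left-Hippocampus"]) - mu), 3 * se)
  # HC hippocampus sits at the unshifted baseline
  Xh <- featureMatrix(coh, "HC")
  seH <- sqrt(400^2 * (1 + tau^2) + 4000^2 * tau^2) / sqrt(nrow(Xh))
  expect_lt(abs(mean(Xh[, "Left-Hippocampus"]) - 4000), 3 * seH)
})

test_that("zero effect map produces no systematic AD-vs-HC difference", {
  cfg <- simulationConfig(effectMap = c(), seed = 31)
  coh <- generateCohort(cfg)
  X <- featureMatrix(coh, c("HC", "AD"))
  grp <- cohortGroups(coh)[cohortGroups(coh) %in% c("HC", "AD")]
  ps <- apply(X[, 1:40], 2, function(x)
    t.test(x[grp == "AD"], x[grp == "HC"])$p.value)
  expect_lte(mean(ps < 0.05), 0.2)
})

test_that("larger planted effects give larger AD-vs-HC separation", {
  cohensD <- function(d) {
    cfg <- simulationConfig(
      effectMap = c(hippocampus = -d), icvVolumeCoupling = 0,
      groupSizes = c(HC = 60, SMD = 2, MCI = 2, AD = 60), nAdLikeSmd = 0,
      seed = 77)
    coh <- generateCohort(cfg)
    x <- featureMatrix(coh, "HC")[, "Left-Hippocampus"]
    z <- featureMatrix(coh, "AD")[, "Left-Hippocampus"]
    (mean(x) - mean(z)) / sqrt((var(x) + var(z)) / 2)
  }
  seps <- sapply(c(0.5, 1.5, 2.5), cohensD)
  expect_true(all(diff(seps) > 0))
})

test_that("follow-up honours outcome probabilities and the visit grid", {
  cfg <- smallConfig(seed = 13)
  allStable <- lapply(cfg$outcomeProbs, function(p) {
    p[] <- 0; p["stable"] <- 1; p })
  cfgStable <- smallConfig(seed = 13, outcomeProbs = allStable)
  coh <- generateCohort(cfgStable)
  fu <- generateFollowup(coh, cfgStable)
  out <- finalOutcome(fu)
  expect_true(all(out$progressed == FALSE))
  expect_true(all(fu$month %in% cfg$followupMonths))
  km <- kmCurve(out$month, as.integer(out$progressed))
  expect_true(all(km$survival == 1))
})

test_that("configured AD-like SMD outcome mass matches 8 of 11 progressing", {
  p <- defaultOutcomeProbs()$SMD_ADlike
  expect_equal(unname(p["toAD"] + p["toPD"] + p["toMCI"] + p["died"]),
               8 / 11, tolerance = 1e-12)
  expect_error(simulationConfig(outcomeProbs = list(HC = c(stable = 2))),
               "malformed|probabilities")
})
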