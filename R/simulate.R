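#' Default planted atrophy pattern
#'
#' The default disease contrast concentrates atrophy in the medial temporal
#' and parietal structures most consistently reported in Alzheimer's
#' disease morphometry — hippocampus, entorhinal cortex, inferior parietal
#' cortex, amygdala and precuneus (standardized shift d = -2.5 in
#' AD-pattern carriers) — together with enlarged inferior lateral
#' ventricles (d = +2.5).
#'
#' @return named numeric vector of region keys to Cohen's d shifts.
#' @export
defaultEffectMap <- function() {
  c(hippocampus = -2.5, entorhinal = -2.5, inferiorparietal = -2.5,
    amygdala = -2.5, precuneus = -2.5, "inf-lat-vent" = 2.5)
}

normalizeRoiKey <- function(x) gsub("[^a-z0-9]", "", tolower(x))

#' Expand a region effect map into a per-feature effect vector
#'
#' Each name in \code{effectMap} is matched (case-insensitively, ignoring
#' separators) as a substring of the schema feature names, so
#' \code{"hippocampus"} covers both hemispheres and \code{"entorhinal"}
#' covers thickness and volume. Entries outside the map are zero. The sign
#' convention is negative = reduced in disease-pattern carriers; ventricular
#' entries are conventionally positive (enlargement).
#'
#' @param schema ROI schema.
#' @param effectMap named numeric vector, region key -> d (standard
#'   deviation units).
#' @return numeric effect vector of length \code{nrow(schema)}, named by
#'   feature.
#' @examples
#' eff <- makeAtrophyPattern(defaultRoiSchema(), defaultEffectMap())
#' sum(eff != 0)
#' @export
makeAtrophyPattern <- function(schema, effectMap = defaultEffectMap()) {
  schema <- validateRoiSchema(schema)
  eff <- setNames(numeric(nrow(schema)), schema$name)
  keys <- normalizeRoiKey(schema$name)
  for (nm in names(effectMap)) {
    hit <- grepl(normalizeRoiKey(nm), keys, fixed = TRUE)
    if (!any(hit)) stop("effect map region not found in schema: ", nm)
    eff[hit] <- effectMap[[nm]]
  }
  eff
}

#' Simulation configuration
#'
#' Captures every knob of the synthetic-cohort generator. Defaults emulate
#' the study conditions of the reference cohort: group sizes HC 69 / SMD 86
#' / MCI 45 / AD 38, an 11-subject AD-like subpopulation planted among the
#' SMD group, the default atrophy pattern at |d| = 2.5, exchangeable
#' within-block feature correlation 0.3, ICV ~ N(1.5e6, 1.5e5) mm^3 with
#' multiplicative volume coupling, follow-up visits at 0/18/36/54/72/90
#' months, and per-group outcome frequencies matching the published
#' follow-up table.
#'
#' @param groupSizes named counts for HC, SMD, MCI, AD.
#' @param nAdLikeSmd number of AD-distributed subjects hidden in the SMD
#'   group (truth labels kept in colData column \code{truth_adlike}).
#' @param effectMap region -> d map, see [makeAtrophyPattern()].
#' @param mciEffectFraction fraction of the AD effect applied to MCI.
#' @param featureCorrelation exchangeable correlation within each feature
#'   block (cortical thickness / cortical volume / subcortical), in [0, 1).
#' @param icvMean,icvSd intracranial volume distribution (mm^3).
#' @param icvVolumeCoupling exponent of the multiplicative ICV-volume
#'   coupling; 1 = proportional scaling.
#' @param suvrParams per-group list of \code{c(mean, sd)} for amyloid SUVR
#'   (groups: HC, SMD_HClike, SMD_ADlike, MCI, AD).
#' @param followupMonths ordered visit grid, first entry 0.
#' @param outcomeProbs per-analysis-group named probability vectors over
#'   \code{toHC,toSMD,toMCI,toAD,toPD,died,stable,missing}; each must sum
#'   to 1 (the \code{missing} mass reproduces subjects without follow-up).
#' @param mmseBaseline,cdrBaseline per-group \code{c(mean, sd)} at baseline.
#' @param mmseSlope,cdrSlope per-group per-month trajectory slopes.
#' @param schema ROI schema used for feature generation.
#' @param seed integer seed; identical (config, seed) gives byte-identical
#'   output.
#' @return a validated config (classed list).
#' @export
simulationConfig <- function(
    groupSizes = c(HC = 69, SMD = 86, MCI = 45, AD = 38),
    nAdLikeSmd = 11,
    effectMap = defaultEffectMap(),
    mciEffectFraction = 0.5,
    featureCorrelation = 0.3,
    icvMean = 1.5e6, icvSd = 1.5e5,
    icvVolumeCoupling = 1,
    suvrParams = list(HC = c(1.25, 0.2), SMD_HClike = c(1.25, 0.2),
                      SMD_ADlike = c(1.9, 0.3), MCI = c(1.8, 0.4),
                      AD = c(2.2, 0.3)),
    followupMonths = c(0, 18, 36, 54, 72, 90),
    outcomeProbs = defaultOutcomeProbs(),
    mmseBaseline = list(HC = c(29.0, 1.1), SMD = c(28.6, 1.3),
                        MCI = c(27.2, 2.2), AD = c(20.4, 5.5)),
    cdrBaseline = list(HC = c(0.01, 0.06), SMD = c(0.05, 0.15),
                       MCI = c(1.05, 0.78), AD = c(4.95, 2.95)),
    mmseSlope = c(HC = -0.002, SMD_HClike = -0.002, SMD_ADlike = -0.014,
                  MCI = -0.026, AD = -0.153),
    cdrSlope = c(HC = 0.000, SMD_HClike = 0.000, SMD_ADlike = 0.004,
                 MCI = 0.016, AD = 0.084),
    schema = defaultRoiSchema(),
    seed = 1L) {
  cfg <- list(groupSizes = groupSizes, nAdLikeSmd = nAdLikeSmd,
              effectMap = effectMap, mciEffectFraction = mciEffectFraction,
              featureCorrelation = featureCorrelation, icvMean = icvMean,
              icvSd = icvSd, icvVolumeCoupling = icvVolumeCoupling,
              suvrParams = suvrParams, followupMonths = followupMonths,
              outcomeProbs = outcomeProbs, mmseBaseline = mmseBaseline,
              cdrBaseline = cdrBaseline, mmseSlope = mmseSlope,
              cdrSlope = cdrSlope, schema = validateRoiSchema(schema),
              seed = as.integer(seed))
  class(cfg) <- "SimulationConfig"
  validateSimulationConfig(cfg)
}

#' Default follow-up outcome frequencies
#'
#' Per-analysis-group probabilities of the terminal follow-up outcome,
#' calibrated to the published outcome table: e.g. 6/11 of the AD-like SMD
#' subpopulation convert to AD dementia and 2/11 die, so the expected
#' progressed fraction is 8/11.
#'
#' @return named list of probability vectors.
#' @export
defaultOutcomeProbs <- function() {
  out <- function(toHC = 0, toSMD = 0, toMCI = 0, toAD = 0, toPD = 0,
                  died = 0, missing = 0, n) {
    v <- c(toHC = toHC, toSMD = toSMD, toMCI = toMCI, toAD = toAD,
           toPD = toPD, died = died, missing = missing)
    c(v, stable = n - sum(v)) / n
  }
  list(
    HC         = out(toSMD = 25, toMCI = 7, died = 1, missing = 1, n = 69),
    SMD_HClike = out(toHC = 11, toMCI = 9, toAD = 1, died = 3, missing = 1,
                     n = 75),
    SMD_ADlike = out(toAD = 6, died = 2, n = 11),
    MCI        = out(toHC = 1, toSMD = 2, toAD = 17, toPD = 1, died = 8,
                     missing = 2, n = 45),
    AD         = out(died = 9, missing = 10, n = 38))
}

validateSimulationConfig <- function(cfg) {
  gs <- cfg$groupSizes
  if (!all(c("HC", "SMD", "MCI", "AD") %in% names(gs)) || any(gs < 0))
    stop("groupSizes must name non-negative HC, SMD, MCI, AD counts")
  if (cfg$nAdLikeSmd > gs[["SMD"]])
    stop("nAdLikeSmd cannot exceed the SMD group size")
  if (cfg$featureCorrelation < 0 || cfg$featureCorrelation >= 1)
    stop("featureCorrelation outside [0, 1): implied covariance is not ",
         "positive definite")
  if (any(diff(cfg$followupMonths) <= 0) || cfg$followupMonths[1] != 0)
    stop("followupMonths must start at 0 and be strictly increasing")
  for (g in names(cfg$outcomeProbs)) {
    p <- cfg$outcomeProbs[[g]]
    if (any(p < -1e-12) || abs(sum(p) - 1) > 1e-8)
      stop("malformed outcome probabilities for group ", g)
  }
  cfg
}

# baseline mean/sd per feature, by kind and coarse structure size
featureBaseline <- function(schema) {
  m <- numeric(nrow(schema)); s <- numeric(nrow(schema))
  thick <- schema$kind == "thickness"
  m[thick] <- 2.5;  s[thick] <- 0.15
  cortvol <- schema$kind == "volume" & grepl("^(lh|rh)_", schema$name)
  m[cortvol] <- 5000; s[cortvol] <- 500
  sub <- schema$kind == "volume" & !cortvol
  m[sub] <- 4000; s[sub] <- 400
  key <- tolower(schema$name)
  big <- sub & grepl("cerebral-white-matter|cerebral-cortex", key)
  m[big] <- 250000; s[big] <- 25000
  cereb <- sub & grepl("cerebellum", key)
  m[cereb] <- 55000; s[cereb] <- 5500
  stem <- sub & grepl("brain-stem", key)
  m[stem] <- 20000; s[stem] <- 2000
  vent <- sub & grepl("vent", key)
  m[vent] <- 1500; s[vent] <- 350
  small <- sub & grepl("vessel|chiasm|csf|hypointens|lesion|cc_", key)
  m[small] <- 900; s[small] <- 200
  data.frame(mean = m, sd = s)
}

# feature block id for the exchangeable correlation structure
featureBlocks <- function(schema) {
  ifelse(schema$kind == "thickness", "thickness",
         ifelse(grepl("^(lh|rh)_", schema$name), "cortvol", "subcortical"))
}

#' Generate a seeded synthetic baseline cohort
#'
#' Features are drawn per subject from a correlated normal model: within
#' each block (cortical thickness, cortical volume, subcortical volume) the
#' latent standardized values share an exchangeable correlation
#' \code{featureCorrelation}; group means shift by the planted effect
#' vector (AD: full d; MCI: \code{mciEffectFraction} x d; SMD: mixture of
#' HC-distributed subjects and \code{nAdLikeSmd} AD-distributed subjects
#' whose hidden truth is stored in colData \code{truth_adlike}). Volume
#' features are multiplicatively coupled to the subject's intracranial
#' volume. Identical (config, seed) gives bit-identical output.
#'
#' @param config a [simulationConfig()].
#' @return a [MorphCohort-class] with metadata columns \code{group},
#'   \code{age}, \code{sex}, \code{education}, \code{icv}, \code{suvr},
#'   \code{apoe_e4_count} and \code{truth_adlike}.
#' @export
generateCohort <- function(config = simulationConfig()) {
  config <- validateSimulationConfig(config)
  set.seed(config$seed)
  schema <- config$schema
  p <- nrow(schema)
  base <- featureBaseline(schema)
  blocks <- featureBlocks(schema)
  eff <- makeAtrophyPattern(schema, config$effectMap)

  gs <- config$groupSizes[c("HC", "SMD", "MCI", "AD")]
  groups <- rep(names(gs), gs)
  n <- length(groups)
  ids <- sprintf("%s%03d", groups, unlist(lapply(gs, seq_len)))

  truth <- rep(FALSE, n)
  smdIdx <- which(groups == "SMD")
  truth[sample(smdIdx, config$nAdLikeSmd)] <- TRUE

  # per-subject multiplier of the planted effect vector
  mult <- numeric(n)
  mult[groups == "AD"] <- 1
  mult[groups == "MCI"] <- config$mciEffectFraction
  mult[truth] <- 1

  rho <- config$featureCorrelation
  z <- matrix(rnorm(n * p), n, p)
  for (b in unique(blocks)) {
    cols <- blocks == b
    shared <- rnorm(n)
    z[, cols] <- sqrt(rho) * shared + sqrt(1 - rho) * z[, cols]
  }
  latent <- z + outer(mult, eff)
  feats <- sweep(sweep(latent, 2, base$sd, "*"), 2, base$mean, "+")

  icvs <- pmax(rnorm(n, config$icvMean, config$icvSd), 0.5 * config$icvMean)
  volCols <- schemaVolumeColumns(schema)
  feats[, volCols] <- feats[, volCols] *
    (icvs / config$icvMean)^config$icvVolumeCoupling
  feats[, volCols] <- pmax(feats[, volCols], 1)
  colnames(feats) <- schema$name

  ageMean <- c(HC = 72.7, SMD = 72.8, MCI = 76.4, AD = 72.6)
  ageSd <- c(HC = 7.2, SMD = 7.1, MCI = 7.3, AD = 8.8)
  pctFemale <- c(HC = 0.51, SMD = 0.52, MCI = 0.51, AD = 0.58)
  apoeProb <- list(HC = c(37, 30, 2), SMD = c(53, 31, 2),
                   MCI = c(19, 21, 5), AD = c(9, 19, 8))
  age <- round(rnorm(n, ageMean[groups], ageSd[groups]), 1)
  sex <- ifelse(runif(n) < pctFemale[groups], "F", "M")
  education <- sample(0:4, n, replace = TRUE,
                      prob = c(0.05, 0.2, 0.35, 0.25, 0.15))
  apoe <- vapply(groups, function(g)
    sample(0:2, 1, prob = apoeProb[[g]]), integer(1))
  agrp <- analysisGroupLabels(groups, truth)
  suvr <- vapply(agrp, function(g) {
    pr <- config$suvrParams[[g]]
    max(rnorm(1, pr[1], pr[2]), 0.5)
  }, numeric(1))

  meta <- data.frame(subject_id = ids, group = groups, age = age, sex = sex,
                     education = education, icv = icvs, suvr = round(suvr, 3),
                     apoe_e4_count = apoe, truth_adlike = truth,
                     stringsAsFactors = FALSE)
  MorphCohort(feats, meta, schema)
}

# map (diagnostic group, hidden truth) to the analysis-group label used for
# outcome/SUVR parameters
analysisGroupLabels <- function(groups, truth) {
  ifelse(groups == "SMD", ifelse(truth, "SMD_ADlike", "SMD_HClike"), groups)
}

#' Generate seeded synthetic follow-up outcomes
#'
#' Each subject draws a terminal outcome from its analysis-group
#' distribution (AD-like SMD subjects use the planted truth label); the
#' event visit is drawn uniformly from the post-baseline visit grid.
#' Diagnoses persist from the event visit onwards, death truncates the
#' visit record, lateral HC<->SMD moves are recorded but are not
#' progression events, and subjects drawn as \code{missing} keep only the
#' baseline visit. MMSE and CDR-SOB follow per-group linear trajectories
#' plus noise.
#'
#' @param cohort a [MorphCohort-class] produced by [generateCohort()] (or
#'   any cohort with a \code{group} column; \code{truth_adlike} defaults to
#'   all-FALSE).
#' @param config the [simulationConfig()] used (its \code{seed} governs the
#'   follow-up draws via a derived stream).
#' @return long-format follow-up data.frame (see [readFollowupTable()]).
#' @export
generateFollowup <- function(cohort, config = simulationConfig()) {
  config <- validateSimulationConfig(config)
  set.seed(config$seed + 1000L)
  groups <- cohortGroups(cohort)
  cd <- SummarizedExperiment::colData(cohort)
  truth <- if ("truth_adlike" %in% colnames(cd)) cd$truth_adlike
           else rep(FALSE, ncol(cohort))
  agrp <- analysisGroupLabels(groups, truth)
  months <- config$followupMonths
  later <- months[-1]

  rows <- lapply(seq_along(groups), function(i) {
    probs <- config$outcomeProbs[[agrp[i]]]
    if (is.null(probs))
      stop("no outcome probabilities configured for group ", agrp[i])
    cat_ <- sample(names(probs), 1, prob = probs)
    eventMonth <- if (length(later) == 1) later else sample(later, 1)
    dx <- rep(groups[i], length(months))
    vital <- rep("alive", length(months))
    keep <- rep(TRUE, length(months))
    if (cat_ == "missing") {
      keep[-1] <- FALSE
    } else if (cat_ == "died") {
      vital[months == eventMonth] <- "dead"
      keep[months > eventMonth] <- FALSE
    } else if (cat_ != "stable") {
      target <- sub("^to", "", cat_)
      dx[months >= eventMonth] <- target
    }
    mb <- config$mmseBaseline[[groups[i]]]
    cb <- config$cdrBaseline[[groups[i]]]
    mmse <- round(mb[1] + config$mmseSlope[[agrp[i]]] * months +
                    rnorm(length(months), 0, 0.8))
    mmse <- pmin(pmax(mmse, 0), 30)
    cdr <- pmax(round((cb[1] + config$cdrSlope[[agrp[i]]] * months +
                         rnorm(length(months), 0, 0.15)) * 2) / 2, 0)
    data.frame(subject_id = subjectIds(cohort)[i], month = months[keep],
               diagnosis = dx[keep], mmse = mmse[keep], cdr_sob = cdr[keep],
               vital_status = vital[keep], stringsAsFactors = FALSE)
  })
  validateFollowupTable(do.call(rbind, rows))
}
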