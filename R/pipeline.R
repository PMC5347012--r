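#' Pipeline run configuration
#'
#' One object configures a full simulate -> preprocess -> fit -> project ->
#' classify -> validate run. A single \code{seed} governs simulation, fold
#' assignment and any other sampling (stage sub-seeds are derived from it
#' deterministically), so one number reproduces a run.
#'
#' @param outDir directory for the report bundle.
#' @param cohortFile,followupFile optional input CSV paths; when
#'   \code{cohortFile} is NULL a synthetic cohort is simulated.
#' @param disease,control class labels for the discriminant model.
#' @param targetGroup group projected as unseen data.
#' @param folds CV folds (>= 2, default 7).
#' @param nOrth \code{"auto"} or a fixed integer.
#' @param cutoff subtype threshold (default 0.5).
#' @param icvMode see [adjustIcv()].
#' @param bhQ FDR level for the log-rank p-value correction.
#' @param seed master seed.
#' @param simConfig optional [simulationConfig()] override (its seed is
#'   replaced by \code{seed}).
#' @param validate run the follow-up validation stage.
#' @return classed list.
#' @export
runConfig <- function(outDir, cohortFile = NULL, followupFile = NULL,
                      disease = "AD", control = "HC", targetGroup = "SMD",
                      folds = 7L, nOrth = "auto", cutoff = 0.5,
                      icvMode = "residualize", bhQ = 0.05, seed = 1L,
                      simConfig = NULL, validate = TRUE) {
  if (folds < 2) stop("folds must be >= 2")
  if (!is.finite(cutoff)) stop("cutoff must be finite")
  cfg <- list(outDir = outDir, cohortFile = cohortFile,
              followupFile = followupFile, disease = disease,
              control = control, targetGroup = targetGroup,
              folds = as.integer(folds), nOrth = nOrth, cutoff = cutoff,
              icvMode = icvMode, bhQ = bhQ, seed = as.integer(seed),
              simConfig = simConfig, validate = isTRUE(validate))
  class(cfg) <- "RunConfig"
  cfg
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the arguments of [runConfig()].
#'
#' @param path YAML file.
#' @param outDir output directory (overrides any value in the file).
#' @return a \code{RunConfig}.
#' @export
readRunConfig <- function(path, outDir = NULL) {
  vals <- yaml::read_yaml(path)
  if (!is.null(outDir)) vals$outDir <- outDir
  do.call(runConfig, vals)
}

configHash <- function(cfg) {
  flat <- cfg[setdiff(names(cfg), c("simConfig", "outDir"))]
  fnv1a32(paste(names(flat), vapply(flat, function(v)
    paste(format(v), collapse = ","), character(1)),
    sep = "=", collapse = ";"))
}

#' Run the full severity-index pipeline
#'
#' Stages, in order: simulate (or load) the cohort and follow-up; train
#' the OPLS severity model on disease vs control with stratified CV
#' (logging Q2, sensitivity, specificity and the top-25 variable
#' importances); project the target group and classify subtypes at the
#' cutoff; validate the subtypes against follow-up (outcome table,
#' progression proportions/ratios, Kaplan-Meier grids, log-rank tests with
#' Benjamini-Hochberg correction). Every artifact is stamped with the
#' config hash and seed; identical config + seed gives identical reports.
#'
#' Artifacts written to \code{outDir}: \code{cohort.csv},
#' \code{followup.csv} (when simulated), \code{model.json},
#' \code{index.csv}, \code{report.json}, \code{run.log}.
#'
#' @param cfg a [runConfig()].
#' @return invisibly, a list with the cohort, model, cv, index and report.
#' @export
runPipeline <- function(cfg) {
  stopifnot(inherits(cfg, "RunConfig"))
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  logLines <- c(sprintf("dsindex run | seed=%d | config=%s | %s",
                        cfg$seed, configHash(cfg),
                        format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
                sprintf("settings: disease=%s control=%s target=%s folds=%d nOrth=%s cutoff=%g icvMode=%s bhQ=%g",
                        cfg$disease, cfg$control, cfg$targetGroup,
                        cfg$folds, format(cfg$nOrth), cfg$cutoff,
                        cfg$icvMode, cfg$bhQ))
  say <- function(...) logLines <<- c(logLines, sprintf(...))

  # --- stage: simulate / load -----------------------------------------
  if (is.null(cfg$cohortFile)) {
    simCfg <- cfg$simConfig
    if (is.null(simCfg)) simCfg <- simulationConfig(seed = cfg$seed)
    simCfg$seed <- cfg$seed
    cohort <- generateCohort(simCfg)
    followup <- generateFollowup(cohort, simCfg)
    writeCohortTable(cohort, file.path(cfg$outDir, "cohort.csv"))
    writeFollowupTable(followup, file.path(cfg$outDir, "followup.csv"))
    say("simulate stage: %d subjects generated", ncol(cohort))
  } else {
    cohort <- readCohortTable(cfg$cohortFile)
    followup <- if (!is.null(cfg$followupFile))
      readFollowupTable(cfg$followupFile) else NULL
    say("load stage: %d subjects read from %s", ncol(cohort),
        cfg$cohortFile)
  }

  # --- stage: fit ------------------------------------------------------
  model <- trainSeverityModel(cohort, disease = cfg$disease,
                              control = cfg$control, nOrth = cfg$nOrth,
                              folds = cfg$folds, seed = cfg$seed,
                              icvMode = cfg$icvMode)
  X <- featureMatrix(cohort, c(cfg$control, cfg$disease))
  y <- as.numeric(cohortGroups(cohort)[
    cohortGroups(cohort) %in% c(cfg$control, cfg$disease)] == cfg$disease)
  volumeCols <- roiSchema(cohort)$name[
    schemaVolumeColumns(roiSchema(cohort))]
  cv <- crossValidate(X, y, k = cfg$folds, nOrth = model@nOrth,
                      seed = cfg$seed, icvValues = icv(cohort)[rownames(X)],
                      volumeCols = volumeCols, icvMode = cfg$icvMode)
  Xstd <- applyStandardization(
    applyIcvAdjustment(X, icv(cohort)[rownames(X)], model@scaling$icv),
    model@scaling$std)
  importance <- variableImportance(model, Xstd, topK = 25)
  writeOplsModel(model, file.path(cfg$outDir, "model.json"))
  say("fit stage: nOrth=%d Q2=%.4f sensitivity=%.3f specificity=%.3f",
      model@nOrth, q2(cv), cv@sensitivity, cv@specificity)

  # --- stage: project + classify --------------------------------------
  idx <- computeIndex(model, cohort, cfg$targetGroup)
  idx <- classifySubtypes(idx, cutoff = cfg$cutoff)
  writeIndexTable(idx, file.path(cfg$outDir, "index.csv"))
  nAdLike <- sum(idx$subtype == "AD-like")
  say("project stage: %d/%d %s subjects classified AD-like at cutoff %g",
      nAdLike, nrow(idx), cfg$targetGroup, cfg$cutoff)

  # --- stage: validate -------------------------------------------------
  report <- list(seed = cfg$seed, config = configHash(cfg),
                 model = modelFingerprint(model),
                 q2 = q2(cv), sensitivity = cv@sensitivity,
                 specificity = cv@specificity, nOrth = model@nOrth,
                 adLikeCount = nAdLike, targetCount = nrow(idx),
                 cutoff = cfg$cutoff, importance = importance)
  if (cfg$validate) {
    if (is.null(followup))
      stop("outcomes stage: follow-up table required for validation but ",
           "none was provided")
    grp <- setNames(cohortGroups(cohort), subjectIds(cohort))
    agrp <- grp
    agrp[idx$subject_id] <- ifelse(idx$subtype == "AD-like",
                                   "AD-like SMD", "HC-like SMD")
    outcomes <- finalOutcome(followup)
    counts <- outcomeTable(outcomes, agrp)
    prog <- progressionStats(counts, "AD-like SMD", "HC")
    progHcLike <- progressionStats(counts, "AD-like SMD", "HC-like SMD")
    ev <- eventTimes(outcomes)
    ev$group <- agrp[ev$subject_id]
    km <- lapply(split(ev, ev$group),
                 function(d) kmCurve(d$time, d$status))
    pairs <- list(c("AD-like SMD", "HC"), c("AD-like SMD", "HC-like SMD"),
                  c("HC-like SMD", "HC"))
    lr <- lapply(pairs, function(pr)
      c(list(groups = paste(pr, collapse = " vs ")),
        logrankTest(ev[ev$group == pr[1], ], ev[ev$group == pr[2], ])))
    bh <- bhCorrect(vapply(lr, `[[`, numeric(1), "p"), q = cfg$bhQ)
    for (i in seq_along(lr)) {
      lr[[i]]$pAdjusted <- bh$adjusted[i]
      lr[[i]]$significant <- bh$reject[i]
    }
    report$outcomeCounts <- counts
    report$progression <- list(adLikeVsHc = prog,
                               adLikeVsHcLike = progHcLike)
    report$km <- km
    report$logrank <- lr
    say("validate stage: progression %.1f%% (AD-like SMD) vs %.1f%% (HC), ratio %.1f",
        prog$percentA, prog$percentB, prog$ratio)
  }
  jsonlite::write_json(report, file.path(cfg$outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "columns", matrix = "rowmajor")
  writeLines(logLines, file.path(cfg$outDir, "run.log"))
  invisible(list(cohort = cohort, model = model, cv = cv, index = idx,
                 report = report))
}
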