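diagnosisRank <- c(HC = 0, SMD = 0, MCI = 1, AD = 2, PD = 2)

#' Terminal outcome and event time per subject
#'
#' Walks each subject's visit record in month order. The outcome is the
#' first visit whose diagnosis is worse than the baseline category
#' (ordering HC = SMD < MCI < dementia, where dementia covers AD and
#' other dementias such as PD) or death, whichever comes first; the event
#' month is that visit's month. Lateral HC <-> SMD moves and reversions
#' are not events: such subjects are stable, censored at their last
#' attended visit, with the last diagnosis recorded. Subjects with no
#' visit beyond baseline have outcome \code{missing}.
#'
#' @param followup long-format follow-up table (see
#'   [readFollowupTable()]).
#' @return data.frame with one row per subject: \code{subject_id},
#'   \code{baseline}, \code{outcome} (one of HC, SMD, MCI, AD, PD, died,
#'   missing), \code{month} (event or censor month), \code{progressed}
#'   (logical; NA when missing).
#' @export
finalOutcome <- function(followup) {
  followup <- validateFollowupTable(followup)
  out <- lapply(split(followup, followup$subject_id), function(d) {
    d <- d[order(d$month), ]
    base <- d$diagnosis[d$month == 0]
    if (!base %in% names(diagnosisRank))
      stop("unknown baseline diagnosis: ", base)
    baseRank <- diagnosisRank[[base]]
    for (i in seq_len(nrow(d))) {
      if (identical(d$vital_status[i], "dead"))
        return(data.frame(subject_id = d$subject_id[1], baseline = base,
                          outcome = "died", month = d$month[i],
                          progressed = TRUE))
      r <- diagnosisRank[[d$diagnosis[i]]]
      if (is.null(r)) stop("unknown diagnosis: ", d$diagnosis[i])
      if (r > baseRank)
        return(data.frame(subject_id = d$subject_id[1], baseline = base,
                          outcome = d$diagnosis[i], month = d$month[i],
                          progressed = TRUE))
    }
    if (nrow(d) == 1)
      return(data.frame(subject_id = d$subject_id[1], baseline = base,
                        outcome = "missing", month = NA_real_,
                        progressed = NA))
    data.frame(subject_id = d$subject_id[1], baseline = base,
               outcome = d$diagnosis[nrow(d)], month = d$month[nrow(d)],
               progressed = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

outcomeLevels <- c("HC", "SMD", "MCI", "AD", "PD", "died", "missing")

#' Tabulate terminal outcomes per analysis group
#'
#' @param outcomes data.frame from [finalOutcome()].
#' @param groups named character vector mapping subject_id to an analysis
#'   group (e.g. HC / HC-like SMD / AD-like SMD / MCI / AD).
#' @return outcome x group count matrix (rows HC, SMD, MCI, AD, PD, died,
#'   missing).
#' @export
outcomeTable <- function(outcomes, groups) {
  unmapped <- setdiff(outcomes$subject_id, names(groups))
  if (length(unmapped))
    stop("mapping error: subject(s) without analysis group: ",
         paste(utils::head(unmapped, 3), collapse = ", "))
  g <- groups[outcomes$subject_id]
  tab <- table(factor(outcomes$outcome, levels = outcomeLevels),
               factor(g, levels = unique(groups)))
  m <- matrix(as.integer(tab), nrow = length(outcomeLevels),
              dimnames = dimnames(tab))
  m
}

roundHalfUp <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Progression proportions and their ratio for two groups
#'
#' Progression = MCI + any dementia (AD or other) + died, divided by the
#' subjects with recorded follow-up (missing excluded from the
#' denominator). Percentages and the ratio are reported to 1 decimal,
#' rounding half away from zero; \code{rawA}/\code{rawB} keep the
#' unrounded fractions.
#'
#' @param counts outcome x group matrix from [outcomeTable()].
#' @param groupA,groupB column names to compare (ratio = A / B).
#' @return list with \code{percentA}, \code{percentB}, \code{ratio},
#'   \code{rawA}, \code{rawB}, \code{nA}, \code{nB}.
#' @export
progressionStats <- function(counts, groupA, groupB) {
  prop <- function(g) {
    if (!g %in% colnames(counts)) stop("group not found: ", g)
    denom <- sum(counts[setdiff(outcomeLevels, "missing"), g])
    if (denom == 0) stop("undefined ratio: zero non-missing total in ", g)
    sum(counts[c("MCI", "AD", "PD", "died"), g]) / denom
  }
  pa <- prop(groupA)
  pb <- prop(groupB)
  if (pb == 0) stop("undefined ratio: no progression in ", groupB)
  list(percentA = roundHalfUp(100 * pa), percentB = roundHalfUp(100 * pb),
       ratio = roundHalfUp(pa / pb), rawA = pa, rawB = pb,
       nA = sum(counts[setdiff(outcomeLevels, "missing"), groupA]),
       nB = sum(counts[setdiff(outcomeLevels, "missing"), groupB]))
}

#' Event/censor times from per-subject outcomes
#'
#' @param outcomes data.frame from [finalOutcome()]; missing-outcome
#'   subjects are dropped.
#' @return data.frame with \code{time} (months) and \code{status} (1 =
#'   progression/death event, 0 = censored).
#' @export
eventTimes <- function(outcomes) {
  keep <- outcomes$outcome != "missing"
  data.frame(subject_id = outcomes$subject_id[keep],
             time = outcomes$month[keep],
             status = as.integer(outcomes$progressed[keep]))
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator over the distinct event times (via the survival
#' package); censored subjects leave the risk set after their censor time.
#' The returned grid starts at time 0 with survival 1.
#'
#' @param time event/censor times (months, >= 0).
#' @param status 1 = event, 0 = censored.
#' @return data.frame with \code{time}, \code{nRisk}, \code{nEvent},
#'   \code{survival} (non-increasing, starting at 1).
#' @export
kmCurve <- function(time, status) {
  if (any(time < 0)) stop("negative event time")
  fit <- survival::survfit(survival::Surv(time, status) ~ 1)
  out <- data.frame(time = fit$time, nRisk = fit$n.risk,
                    nEvent = fit$n.event, survival = fit$surv)
  if (nrow(out) == 0 || out$time[1] > 0)
    out <- rbind(data.frame(time = 0, nRisk = length(time), nEvent = 0,
                            survival = 1), out)
  rownames(out) <- NULL
  out
}

#' Two-group log-rank test
#'
#' Standard log-rank statistic over the pooled event times, compared to a
#' chi-square distribution with 1 degree of freedom.
#'
#' @param eventsA,eventsB data.frames with \code{time} and \code{status}
#'   columns (as from [eventTimes()]).
#' @return list with \code{chi2}, \code{df} (1) and \code{p}.
#' @export
logrankTest <- function(eventsA, eventsB) {
  if (sum(eventsA$status) + sum(eventsB$status) == 0)
    stop("undefined statistic: no events in either group")
  time <- c(eventsA$time, eventsB$time)
  status <- c(eventsA$status, eventsB$status)
  grp <- rep(c("A", "B"), c(nrow(eventsA), nrow(eventsB)))
  sd_ <- survival::survdiff(survival::Surv(time, status) ~ grp)
  list(chi2 = unname(sd_$chisq), df = 1L,
       p = pchisq(sd_$chisq, df = 1, lower.tail = FALSE))
}

#' Dichotomize MMSE scores at the conventional 24 threshold
#'
#' @param scores integer MMSE scores in 0..30.
#' @return character vector, \code{"normal"} (>= 24) or \code{"abnormal"}
#'   (< 24).
#' @export
dichotomizeMmse <- function(scores) {
  if (any(!is.finite(scores)) || any(scores < 0 | scores > 30) ||
      any(scores != round(scores)))
    stop("MMSE scores must be integers in 0..30")
  ifelse(scores >= 24, "normal", "abnormal")
}

#' Classify amyloid PET SUVR at the 1.5 positivity threshold
#'
#' @param suvr positive SUVR values.
#' @return character vector, \code{"positive"} (>= 1.5) or
#'   \code{"negative"}.
#' @export
classifyPib <- function(suvr) {
  if (any(!is.finite(suvr)) || any(suvr <= 0))
    stop("SUVR must be positive")
  ifelse(suvr >= 1.5, "positive", "negative")
}

#' Benjamini-Hochberg false discovery rate correction
#'
#' Step-up rule at level \code{q}: with the p-values sorted ascending,
#' reject hypotheses 1..i for the largest i with p(i) <= (i/m) q. Adjusted
#' values are the usual step-up adjusted p-values (capped at 1, original
#' order restored); a hypothesis is rejected iff its adjusted value is
#' <= q.
#'
#' @param pvalues numeric vector in [0, 1].
#' @param q FDR level in (0, 1).
#' @return list with \code{adjusted} and logical \code{reject}, in input
#'   order.
#' @export
bhCorrect <- function(pvalues, q = 0.05) {
  if (length(pvalues) == 0)
    return(list(adjusted = numeric(0), reject = logical(0)))
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  if (q <= 0 || q >= 1) stop("q must lie in (0, 1)")
  adjusted <- stats::p.adjust(pvalues, method = "BH")
  list(adjusted = adjusted, reject = adjusted <= q)
}
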