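visits <- function(id, ...) {
  v <- list(...)
  data.frame(subject_id = id,
             month = vapply(v, `[[`, numeric(1), 1),
             diagnosis = vapply(v, `[[`, character(1), 2),
             mmse = 28, cdr_sob = 0,
             vital_status = vapply(v, function(x)
               if (length(x) > 2 && x[[3]]) "dead" else "alive",
               character(1)),
             stringsAsFactors = FALSE)
}

test_that("terminal outcomes follow the first-worsening-or-death rule", {
  fu <- rbind(
    visits("a", list(0, "SMD"), list(18, "SMD"), list(36, "MCI")),
    visits("b", list(0, "SMD"), list(18, "HC")),
    visits("c", list(0, "SMD"), list(18, "SMD"), list(54, "SMD", TRUE)),
    visits("d", list(0, "HC"), list(18, "SMD"), list(36, "SMD")),
    visits("e", list(0, "MCI"), list(36, "AD")),
    visits("f", list(0, "AD"), list(18, "AD")),
    visits("g", list(0, "HC")))
  out <- finalOutcome(fu)
  got <- setNames(split(out[, c("outcome", "month", "progressed")],
                        seq_len(nrow(out))), out$subject_id)
  expect_identical(out$outcome[out$subject_id == "a"], "MCI")
  expect_equal(out$month[out$subject_id == "a"], 36)
  # reversion is not progression: censored at last visit
  expect_identical(out$outcome[out$subject_id == "b"], "HC")
  expect_false(out$progressed[out$subject_id == "b"])
  expect_equal(out$month[out$subject_id == "b"], 18)
  expect_identical(out$outcome[out$subject_id == "c"], "died")
  expect_equal(out$month[out$subject_id == "c"], 54)
  # HC -> SMD lateral move is not an event
  expect_false(out$progressed[out$subject_id == "d"])
  expect_true(out$progressed[out$subject_id == "e"])
  expect_false(out$progressed[out$subject_id == "f"])
  # baseline-only record counts as missing follow-up
  expect_identical(out$outcome[out$subject_id == "g"], "missing")
})

test_that("outcome table reproduces the published column totals", {
  t5 <- table5Followup()
  out <- finalOutcome(t5$followup)
  counts <- outcomeTable(out, t5$groups)
  nonMissing <- colSums(counts) - counts["missing", ]
  expect_equal(unname(nonMissing[c("HC", "HC-like SMD", "AD-like SMD",
                                   "MCI", "AD")]),
               c(68, 74, 11, 43, 28))
  # conservation: outcomes + missing = group size
  expect_equal(unname(colSums(counts)[c("HC", "HC-like SMD", "AD-like SMD",
                                        "MCI", "AD")]),
               c(69, 75, 11, 45, 38))
  expect_error(outcomeTable(out, t5$groups[-1]), "mapping")
})

test_that("progression proportions and ratios match the printed values", {
  t5 <- table5Followup()
  counts <- outcomeTable(finalOutcome(t5$followup), t5$groups)
  pr <- progressionStats(counts, "AD-like SMD", "HC")
  expect_identical(pr$percentA, 72.7)
  expect_identical(pr$percentB, 11.8)
  expect_identical(pr$ratio, 6.2)
  pr2 <- progressionStats(counts, "HC-like SMD", "HC")
  expect_identical(pr2$percentA, 17.6)
  empty <- counts; empty[, "HC"] <- 0L
  expect_error(progressionStats(empty, "AD-like SMD", "HC"), "undefined")
})

test_that("Kaplan-Meier estimates match hand-computed product limits", {
  # 3 subjects: after the censor at 36 only one remains at risk at 54
  km <- kmCurve(c(18, 36, 54), c(1, 0, 1))
  expect_equal(km$survival[km$time == 0], 1)
  expect_equal(km$survival[km$time == 18], 2 / 3)
  expect_equal(km$survival[km$time == 54], 0)
  expect_true(all(diff(km$survival) <= 0))
  # 4 subjects: S(18) = 3/4, then 2 at risk at 54 -> S(54) = 3/4 * 1/2
  km4 <- kmCurve(c(18, 36, 54, 60), c(1, 0, 1, 0))
  expect_equal(km4$survival[km4$time == 18], 3 / 4)
  expect_equal(km4$survival[km4$time == 54], (3 / 4) * (1 / 2))
  # no events: flat at 1
  expect_true(all(kmCurve(c(10, 20), c(0, 0))$survival == 1))
  # all events at one time: single step of height events/n
  km2 <- kmCurve(rep(36, 4), rep(1, 4))
  expect_equal(km2$survival[km2$time == 36], 0)
  # without censoring KM equals 1 - empirical CDF
  tms <- c(10, 20, 20, 40, 55)
  km3 <- kmCurve(tms, rep(1, 5))
  for (i in seq_len(nrow(km3)))
    expect_equal(km3$survival[i], 1 - ecdf(tms)(km3$time[i]))
  expect_error(kmCurve(c(-1, 3), c(1, 1)), "negative")
})

test_that("log-rank statistic matches the observed-minus-expected oracle", {
  a <- data.frame(time = c(10, 25, 40, 60), status = c(1, 1, 0, 1))
  b <- data.frame(time = c(15, 30, 50, 70), status = c(0, 1, 1, 0))
  lr <- logrankTest(a, b)
  expect_equal(lr$chi2,
               oracleLogrank(a$time, a$status, b$time, b$status),
               tolerance = 1e-10)
  expect_equal(lr$p, pchisq(lr$chi2, 1, lower.tail = FALSE))
  # identical event lists: no separation
  expect_lt(logrankTest(a, a)$chi2, 1e-10)
  # extreme separation clears the 5% critical value
  early <- data.frame(time = rep(10, 10), status = 1)
  late <- data.frame(time = rep(90, 10), status = 0)
  expect_gt(logrankTest(early, late)$chi2, 3.84)
  expect_error(logrankTest(late, late), "no events")
})

test_that("threshold rules behave at their boundaries", {
  expect_identical(dichotomizeMmse(c(24, 23, 30, 0)),
                   c("normal", "abnormal", "normal", "abnormal"))
  expect_error(dichotomizeMmse(31), "0..30")
  expect_error(dichotomizeMmse(22.5), "integers")
  expect_identical(classifyPib(c(1.5, 1.49, 3.0)),
                   c("positive", "negative", "positive"))
  expect_error(classifyPib(0), "positive")
})

test_that("BH correction matches direct step-up enumeration", {
  cases <- list(c(0.01, 0.02, 0.04, 0.10),
                rep(0.001, 14),
                c(0.2, 0.8, 0.04, 0.3, 0.001, 0.049),
                runif(25))
  set.seed(30)
  for (p in cases) {
    got <- bhCorrect(p, q = 0.05)
    want <- oracleBh(p, 0.05)
    expect_equal(got$adjusted, want$adjusted, tolerance = 1e-12)
    expect_identical(got$reject, want$reject)
  }
  # worked example: first two rejected only
  expect_identical(bhCorrect(c(0.01, 0.02, 0.04, 0.10))$reject,
                   c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(bhCorrect(rep(0.001, 14))$reject, rep(TRUE, 14))
  expect_length(bhCorrect(numeric(0))$reject, 0)
  # monotone in q; never rejects p > q when m = 1
  set.seed(31)
  p <- runif(12)
  prev <- 0
  for (q in c(0.01, 0.05, 0.1, 0.3)) {
    n <- sum(bhCorrect(p, q)$reject)
    expect_gte(n, prev)
    prev <- n
  }
  expect_false(bhCorrect(0.06, q = 0.05)$reject)
  expect_error(bhCorrect(c(0.5, 1.2)), "\\[0, 1\\]")
})
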