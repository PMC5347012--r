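# Independent oracles and small fixture builders. Everything here is a
# deliberately naive, loop-by-loop re-implementation used only to check the
# package's vectorized code paths.

# literal transcription of the orthogonal-deflation recipe, explicit loops
oracleOplsFit <- function(X, y, nOrth) {
  n <- nrow(X); p <- ncol(X)
  ymean <- mean(y)
  yc <- y - ymean
  Wo <- list(); Po <- list()
  Xc <- X
  if (nOrth > 0) {
    for (comp in seq_len(nOrth)) {
      wstar <- numeric(p)
      for (j in 1:p) wstar[j] <- sum(Xc[, j] * yc)
      wstar <- wstar / sqrt(sum(wstar^2))
      tstar <- numeric(n)
      for (i in 1:n) tstar[i] <- sum(Xc[i, ] * wstar)
      pstar <- numeric(p)
      for (j in 1:p) pstar[j] <- sum(Xc[, j] * tstar) / sum(tstar * tstar)
      wo <- pstar - sum(wstar * pstar) * wstar
      wo <- wo / sqrt(sum(wo * wo))
      to <- numeric(n)
      for (i in 1:n) to[i] <- sum(Xc[i, ] * wo)
      po <- numeric(p)
      for (j in 1:p) po[j] <- sum(Xc[, j] * to) / sum(to * to)
      for (i in 1:n) for (j in 1:p) Xc[i, j] <- Xc[i, j] - to[i] * po[j]
      Wo[[comp]] <- wo; Po[[comp]] <- po
    }
  }
  w <- numeric(p)
  for (j in 1:p) w[j] <- sum(Xc[, j] * yc)
  w <- w / sqrt(sum(w * w))
  tt <- numeric(n)
  for (i in 1:n) tt[i] <- sum(Xc[i, ] * w)
  pp <- numeric(p)
  for (j in 1:p) pp[j] <- sum(Xc[, j] * tt) / sum(tt * tt)
  cc <- sum(yc * tt) / sum(tt * tt)
  list(w = w, p = pp, c = cc, Wo = Wo, Po = Po, t = tt,
       fitted = cc * tt + ymean, yMean = ymean)
}

# naive two-group log-rank observed-minus-expected table
oracleLogrank <- function(timeA, statusA, timeB, statusB) {
  time <- c(timeA, timeB)
  status <- c(statusA, statusB)
  grp <- rep(c(1, 2), c(length(timeA), length(timeB)))
  O <- 0; E <- 0; V <- 0
  for (tj in sort(unique(time[status == 1]))) {
    atRiskA <- sum(time >= tj & grp == 1)
    atRisk <- sum(time >= tj)
    dA <- sum(time == tj & status == 1 & grp == 1)
    d <- sum(time == tj & status == 1)
    O <- O + dA
    E <- E + d * atRiskA / atRisk
    if (atRisk > 1)
      V <- V + d * (atRiskA / atRisk) * (1 - atRiskA / atRisk) *
        (atRisk - d) / (atRisk - 1)
  }
  (O - E)^2 / V
}

# direct enumeration of the BH step-up rule
oracleBh <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- 0
  for (i in seq_len(m)) if (ps[i] <= i / m * q) k <- i
  reject <- logical(m)
  if (k > 0) reject[ord[seq_len(k)]] <- TRUE
  adj <- numeric(m)
  for (i in seq_len(m)) adj[i] <- min(1, min(m / seq(i, m) * ps[seq(i, m)]))
  adjusted <- numeric(m)
  adjusted[ord] <- adj
  list(adjusted = adjusted, reject = reject)
}

# small custom schema for fast io / preprocessing tests
tinySchema <- function() {
  data.frame(
    name = c("lh_toy_thickness", "rh_toy_thickness", "Left-HippoToy",
             "Right-HippoToy", "Left-VentToy", "Right-VentToy"),
    kind = c("thickness", "thickness", "volume", "volume", "volume",
             "volume"),
    hemisphere = c("left", "right", "left", "right", "left", "right"),
    stringsAsFactors = FALSE)
}

tinyCohort <- function(n = 8, seed = 42) {
  set.seed(seed)
  sch <- tinySchema()
  feat <- matrix(rnorm(n * nrow(sch), mean = 100, sd = 5), n,
                 dimnames = list(NULL, sch$name))
  meta <- data.frame(subject_id = sprintf("T%02d", 1:n),
                     group = rep(c("HC", "AD"), length.out = n),
                     age = round(rnorm(n, 72, 5), 1),
                     sex = rep(c("F", "M"), length.out = n),
                     education = rep(0:4, length.out = n),
                     icv = rnorm(n, 1.5e6, 1e5),
                     stringsAsFactors = FALSE)
  MorphCohort(feat, meta, sch)
}

# subject-level follow-up records reproducing the published outcome table:
# per analysis group, counts of terminal outcomes over a 90-month window
table5Followup <- function() {
  spec <- list(
    "HC"          = list(base = "HC",  stay = 35, toSMD = 25, toMCI = 7,
                         toAD = 0, toPD = 0, died = 1, missing = 1),
    "HC-like SMD" = list(base = "SMD", stay = 50, toHC = 11, toMCI = 9,
                         toAD = 1, toPD = 0, died = 3, missing = 1),
    "AD-like SMD" = list(base = "SMD", stay = 3, toMCI = 0, toAD = 6,
                         toPD = 0, died = 2, missing = 0),
    "MCI"         = list(base = "MCI", stay = 14, toHC = 1, toSMD = 2,
                         toAD = 17, toPD = 1, died = 8, missing = 2),
    "AD"          = list(base = "AD",  stay = 19, died = 9, missing = 10))
  rows <- list(); groups <- character(0); sid <- 0
  visit <- function(id, month, dx, dead = FALSE)
    data.frame(subject_id = id, month = month, diagnosis = dx, mmse = 28,
               cdr_sob = 0, vital_status = if (dead) "dead" else "alive",
               stringsAsFactors = FALSE)
  for (g in names(spec)) {
    s <- spec[[g]]
    addSubject <- function(visits) {
      sid <<- sid + 1
      id <- sprintf("P%03d", sid)
      visits$subject_id <- id
      rows[[length(rows) + 1]] <<- visits
      groups[id] <<- g
    }
    for (cat_ in setdiff(names(s), "base")) {
      cnt <- s[[cat_]]
      if (cnt == 0) next
      for (i in seq_len(cnt)) {
        v <- switch(cat_,
          stay    = rbind(visit("x", 0, s$base), visit("x", 90, s$base)),
          toHC    = rbind(visit("x", 0, s$base), visit("x", 90, "HC")),
          toSMD   = rbind(visit("x", 0, s$base), visit("x", 90, "SMD")),
          toMCI   = rbind(visit("x", 0, s$base), visit("x", 36, "MCI")),
          toAD    = rbind(visit("x", 0, s$base), visit("x", 54, "AD")),
          toPD    = rbind(visit("x", 0, s$base), visit("x", 54, "PD")),
          died    = rbind(visit("x", 0, s$base),
                          visit("x", 54, s$base, dead = TRUE)),
          missing = visit("x", 0, s$base))
        addSubject(v)
      }
    }
  }
  list(followup = do.call(rbind, rows), groups = groups)
}
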