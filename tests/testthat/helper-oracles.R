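# Independent brute-force oracles and tiny fixture builders shared by
# the tests. These deliberately use the most literal formulation of
# each quantity (double loops, explicit tables) so they stay
# independent of the package's vectorised implementations.

# Harrell's C by exhaustive pair enumeration.
bruteCIndex <- function(risk, time, event) {
  conc <- 0; total <- 0
  n <- length(risk)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (event[i] == 1 && time[i] < time[j]) {
      total <- total + 1
      if (risk[i] > risk[j]) conc <- conc + 1
      else if (risk[i] == risk[j]) conc <- conc + 0.5
    }
  }
  if (total == 0) NA_real_ else conc / total
}

# Breslow negative log partial likelihood, O(n^2), mean over events.
bruteCoxNll <- function(risk, time, event) {
  d <- sum(event == 1)
  s <- 0
  for (i in which(event == 1))
    s <- s + risk[i] - log(sum(exp(risk[time >= time[i]])))
  -s / d
}

# Product-limit estimator by explicit event-time walk.
bruteKM <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  surv <- numeric(length(ts))
  p <- 1
  for (k in seq_along(ts)) {
    nRisk <- sum(time >= ts[k])
    dEv <- sum(time == ts[k] & event == 1)
    p <- p * (1 - dEv / nRisk)
    surv[k] <- p
  }
  data.frame(time = ts, surv = surv)
}

# Two-sample log-rank by the observed-vs-expected table.
bruteLogrank <- function(time, event, group) {
  group <- as.integer(as.factor(group))
  ts <- sort(unique(time[event == 1]))
  o1 <- e1 <- v <- 0
  for (tk in ts) {
    atRisk <- time >= tk
    n <- sum(atRisk); n1 <- sum(atRisk & group == 1)
    d <- sum(time == tk & event == 1)
    d1 <- sum(time == tk & event == 1 & group == 1)
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  stat <- (o1 - e1)^2 / v
  list(statistic = stat,
       pValue = stats::pchisq(stat, 1, lower.tail = FALSE))
}

# Small random censored survival instance.
randomSurvInstance <- function(n, pEvent = 0.6, tieProb = 0.3) {
  time <- if (runif(1) < tieProb) sample(seq_len(max(2, n %/% 2)), n,
                                         replace = TRUE)
          else round(rexp(n, 0.01) + 1, 3)
  event <- rbinom(n, 1, pEvent)
  if (sum(event) == 0) event[sample(n, 1)] <- 1
  list(risk = rnorm(n), time = time, event = event)
}

# Tiny normalized cohort with real signal, for fast training tests.
tinyCohort <- function(n = 120L, seed = 3L) {
  spec <- simulationSpec(nSamples = n, nSignalGenes = 30L,
                         nNoiseGenes = 6L, nEmptyGenes = 4L,
                         nLatentFactors = 3L, beta = c(1.2, -1, 0.8),
                         seed = seed)
  ge <- generateExpression(spec)
  rownames(ge$factors) <- rownames(ge$expr)
  gs <- generateSurvival(ge$factors, spec)
  pp <- preprocessExpression(ge$expr)
  list(expr = pp$expr, surv = gs$surv, eta = gs$eta,
       factors = ge$factors, spec = spec)
}

tinyConfig <- function(...) {
  args <- utils::modifyList(
    list(hiddenDim = 16L, latentDim = 4L, pretrainEpochs = 3L,
         lrHoldEpochs = 2L, pretrainBatch = 32L,
         finetuneEpochs = 5L, criticIters = 2L, seed = 1L),
    list(...))
  do.call(savaeConfig, args)
}
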