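#' Loss weights for the composite generator objective
#'
#' @param lambdaP gradient-penalty weight (default 10, the usual
#'   Wasserstein-GP magnitude)
#' @param lambda1 Kullback-Leibler weight (default 1e-3)
#' @param lambda2 L1 reconstruction weight (default 10)
#' @return classed list of nonnegative weights
#' @export
lossWeights <- function(lambdaP = 10, lambda1 = 1e-3, lambda2 = 10) {
  if (any(c(lambdaP, lambda1, lambda2) < 0))
    stop("loss weights must be nonnegative")
  structure(list(lambdaP = lambdaP, lambda1 = lambda1, lambda2 = lambda2),
            class = "savae_loss_weights")
}

#' Wasserstein critic loss (minimization form)
#'
#' The critic maximizes `E[D(real)] - E[D(fake)] - lambdaP * penalty`;
#' the negated quantity is returned so a minimizer trains it:
#' `mean(dFake) - mean(dReal) + lambdaP * penalty`.
#'
#' @param dReal,dFake critic scores on real and reconstructed batches
#' @param penalty gradient penalty value
#' @param lambdaP penalty weight
#' @return scalar loss
#' @export
criticLoss <- function(dReal, dFake, penalty = 0, lambdaP = 10) {
  if (length(dReal) == 0L || length(dFake) == 0L)
    stop("empty score batch")
  if (length(dReal) != length(dFake))
    stop("real and fake batches must have equal size")
  mean(dFake) - mean(dReal) + lambdaP * penalty
}

# Gradient of the critic score with respect to its *input*, for a whole
# batch at once. Activation masks from the cached forward.
.criticInputGrad <- function(fw, critic) {
  L <- length(critic@layers)
  B <- nrow(fw$x)
  d <- fw$masks[[L]] * rep(critic@wOut, each = B)
  if (L > 1L) for (i in seq(L - 1L, 1L)) {
    d <- (d %*% critic@layers[[i + 1L]]$W) * fw$masks[[i]]
  }
  d %*% critic@layers[[1L]]$W        # B x inputDim
}

#' Gradient penalty at real/fake interpolates
#'
#' Evaluates `mean_b (||grad_x D(xhat_b)||_2 - 1)^2` at
#' `xhat = eps * xReal + (1 - eps) * xFake` with per-sample uniform
#' `eps`, driving the critic towards unit input-gradient norm on the
#' sample space between data and reconstructions.
#'
#' @param critic a [SavaeCritic-class]
#' @param xReal,xFake batches of identical shape
#' @param epsilon uniform(0,1) draws, one per sample (recycled to the
#'   batch); default draws them
#' @return scalar penalty (>= 0), with attribute `"interpolates"`
#' @export
gradientPenalty <- function(critic, xReal, xFake,
                            epsilon = runif(nrow(as.matrix(xReal)))) {
  xReal <- as.matrix(xReal); xFake <- as.matrix(xFake)
  stopifnot(identical(dim(xReal), dim(xFake)))
  xHat <- xReal * epsilon + xFake * (1 - epsilon)
  fw <- .criticForward(xHat, critic, cache = TRUE)
  g <- .criticInputGrad(fw, critic)
  norms <- sqrt(rowSums(g^2))
  p <- mean((norms - 1)^2)
  attr(p, "interpolates") <- xHat
  p
}

#' Kullback-Leibler divergence to the standard normal prior
#'
#' Per sample `sum_i (mu_i^2 + sigma_i^2 - log sigma_i^2 - 1)` over
#' latent dimensions, averaged over the batch. The conventional 1/2
#' factor is omitted by default (the KL weight absorbs constants);
#' `half = TRUE` restores the textbook form.
#'
#' @param mu,logVar latent Gaussian parameters, samples x latent
#' @param half apply the 1/2 factor
#' @return scalar divergence
#' @export
klDivergence <- function(mu, logVar, half = FALSE) {
  mu <- as.matrix(mu); logVar <- as.matrix(logVar)
  stopifnot(identical(dim(mu), dim(logVar)))
  per <- rowSums(mu^2 + exp(logVar) - logVar - 1)
  mean(per) * if (half) 0.5 else 1
}

#' Mean absolute reconstruction error
#'
#' @param xRec,xIn matrices of identical shape
#' @return scalar mean |xRec - xIn|
#' @export
l1Loss <- function(xRec, xIn) {
  xRec <- as.matrix(xRec); xIn <- as.matrix(xIn)
  stopifnot(identical(dim(xRec), dim(xIn)))
  mean(abs(xRec - xIn))
}

#' Composite generator loss
#'
#' `-mean(dFake) + lambda1 * kl + lambda2 * l1`: the generator's side of
#' the Wasserstein game plus the weighted divergence and reconstruction
#' terms.
#'
#' @param dFake critic scores on reconstructions
#' @param kl,l1 precomputed loss components
#' @param weights a [lossWeights()] list
#' @return scalar loss
#' @export
generatorLoss <- function(dFake, kl, l1, weights = lossWeights()) {
  -mean(dFake) + weights$lambda1 * kl + weights$lambda2 * l1
}

#' Cox negative log partial likelihood
#'
#' Breslow form: `-(1/d) * sum_{i: event} [ r_i - log sum_{j: t_j >= t_i}
#' exp(r_j) ]` with d the number of observed events; tied event times
#' share the full risk set. The mean-over-events reduction keeps the
#' scale batch-size independent. With zero events the loss is defined as
#' 0 and flagged via attribute `"noEvents"`. `form = "printed"` drops the
#' exponential inside the log-sum (a linear-risk variant, undefined when
#' the risk-set sum is nonpositive).
#'
#' @param risk numeric risk scores (log relative hazards)
#' @param time follow-up times
#' @param event 0/1 indicator, 1 = death observed
#' @param form `"standard"` (default) or `"printed"`
#' @return scalar loss
#' @export
coxNegLogLik <- function(risk, time, event, form = c("standard", "printed")) {
  form <- match.arg(form)
  n <- length(risk)
  stopifnot(length(time) == n, length(event) == n)
  d <- sum(event == 1)
  if (d == 0L) {
    out <- 0
    attr(out, "noEvents") <- TRUE
    warning("no observed events; cox loss defined as 0")
    return(out)
  }
  ord <- order(time, decreasing = TRUE)   # descending: cumsum = risk sets
  r <- risk[ord]; tt <- time[ord]; ev <- event[ord]
  if (form == "standard") {
    m <- max(r)
    cs <- cumsum(exp(r - m))
    # tied times share one risk set: take the last cumsum within a tie run
    last <- .tieRunLast(tt)
    logDen <- log(cs[last]) + m
  } else {
    cs <- cumsum(r)
    last <- .tieRunLast(tt)
    den <- cs[last]
    logDen <- suppressWarnings(log(den))
  }
  -sum((r - logDen)[ev == 1]) / d
}

# For a non-increasing time vector, index of the last element of the tie
# run each position belongs to (so cumsum at that index covers all
# samples with t >= t_i).
.tieRunLast <- function(tt) {
  n <- length(tt)
  runEnd <- integer(n)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && tt[j + 1L] == tt[i]) j <- j + 1L
    runEnd[i:j] <- j
    i <- j + 1L
  }
  runEnd
}

#' Analytic gradient of the Cox loss with respect to risk scores
#'
#' @inheritParams coxNegLogLik
#' @return numeric gradient vector, same length as `risk`
#' @export
coxLossGradient <- function(risk, time, event) {
  n <- length(risk)
  d <- sum(event == 1)
  if (d == 0L) return(numeric(n))
  ord <- order(time, decreasing = TRUE)
  r <- risk[ord]; tt <- time[ord]; ev <- event[ord]
  m <- max(r)
  er <- exp(r - m)
  cs <- cumsum(er)
  last <- .tieRunLast(tt)
  den <- cs[last]                         # risk-set sums per sample's time
  # sum over event times with t_i <= t_k of 1/den_i, accumulated from the
  # end (ascending time) since ordering is descending.
  inv <- ifelse(ev == 1, 1 / den, 0)
  accum <- rev(cumsum(rev(inv)))
  # samples in the same tie run enter the same risk sets; align to run start
  runStart <- .tieRunFirst(tt)
  accum <- accum[runStart]
  g <- (er * accum - ev) / d
  out <- numeric(n)
  out[ord] <- g
  out
}

.tieRunFirst <- function(tt) {
  n <- length(tt)
  runStart <- integer(n)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && tt[j + 1L] == tt[i]) j <- j + 1L
    runStart[i:j] <- i
    i <- j + 1L
  }
  runStart
}

#' Check the analytic Cox gradient against central differences
#'
#' @inheritParams coxNegLogLik
#' @param h finite-difference step
#' @return maximum relative deviation over coordinates
#' @export
coxGradientCheck <- function(risk, time, event, h = 1e-5) {
  g <- coxLossGradient(risk, time, event)
  num <- vapply(seq_along(risk), function(k) {
    up <- risk; up[k] <- up[k] + h
    dn <- risk; dn[k] <- dn[k] - h
    (coxNegLogLik(up, time, event) - coxNegLogLik(dn, time, event)) / (2 * h)
  }, numeric(1))
  scale <- pmax(abs(g), abs(num), 1e-8)
  max(abs(g - num) / scale)
}
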