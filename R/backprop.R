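# Hand-derived reverse-mode gradients for the generator, the critic and
# the gradient-penalty term, plus a flat-vector Adam optimizer. All
# functions here are internal; correctness is pinned by finite-difference
# tests on tiny networks.

# ---- parameter flattening ----------------------------------------------

.getGenParams <- function(model) {
  list(enc = model@encoder[c("W_h", "b_h", "W_mu", "b_mu", "W_nu", "b_nu")],
       att = model@attention[c("W_q", "W_k", "W_v", "b_q", "b_k", "b_v",
                               "alpha")],
       dec = model@decoder[c("W", "b")])
}

.setGenParams <- function(model, p) {
  model@encoder[names(p$enc)] <- p$enc
  model@attention[names(p$att)] <- p$att
  model@decoder[names(p$dec)] <- p$dec
  model
}

.getCoxParams <- function(model) {
  list(enc = model@encoder[c("W_h", "b_h", "W_mu", "b_mu", "W_nu", "b_nu")],
       att = model@attention[c("W_q", "W_k", "W_v", "b_q", "b_k", "b_v",
                               "alpha")],
       cox = list(w = model@coxHead))
}

.setCoxParams <- function(model, p) {
  model@encoder[names(p$enc)] <- p$enc
  model@attention[names(p$att)] <- p$att
  model@coxHead <- as.numeric(p$cox$w)
  model
}

.getCriticParams <- function(critic) {
  list(layers = critic@layers, wOut = critic@wOut, bOut = critic@bOut)
}

.setCriticParams <- function(critic, p) {
  critic@layers <- p$layers
  critic@wOut <- as.numeric(p$wOut)
  critic@bOut <- as.numeric(p$bOut)
  critic
}

.flattenParams <- function(p) {
  if (is.list(p)) return(unlist(lapply(p, .flattenParams), use.names = FALSE))
  as.numeric(p)
}

.unflattenParams <- function(flat, skeleton, pos = 1L) {
  if (is.list(skeleton)) {
    out <- skeleton
    for (i in seq_along(skeleton)) {
      r <- .unflattenParams(flat, skeleton[[i]], pos)
      out[[i]] <- r$value
      pos <- r$pos
    }
    return(list(value = out, pos = pos))
  }
  n <- length(skeleton)
  v <- flat[pos:(pos + n - 1L)]
  if (is.matrix(skeleton)) dim(v) <- dim(skeleton)
  list(value = v, pos = pos + n)
}

.zeroLike <- function(p) {
  if (is.list(p)) return(lapply(p, .zeroLike))
  p0 <- p; p0[] <- 0; p0
}

# ---- Adam ---------------------------------------------------------------

.adamInit <- function(nPar) {
  list(m = numeric(nPar), v = numeric(nPar), t = 0L)
}

.adamStep <- function(theta, grad, state, lr, beta1, beta2, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mh <- state$m / (1 - beta1^state$t)
  vh <- state$v / (1 - beta2^state$t)
  list(theta = theta - lr * mh / (sqrt(vh) + eps), state = state)
}

# ---- attention backward -------------------------------------------------

# go: gradient arriving at the residual-attention output (B x H).
# cache: .saForward(..., cache = TRUE) output; hAct the attention input.
# Returns dHAct plus parameter grads (including alpha and residual path).
.attentionBackward <- function(go, cache, att, hAct) {
  B <- nrow(go); H <- ncol(go)
  grp <- cache$grp
  A <- cache$A
  kExp <- cache$k[grp, , drop = FALSE]
  vExp <- cache$v[grp, , drop = FALSE]
  qVec <- as.vector(t(cache$q))
  goVec <- as.vector(t(go))
  dAlpha <- sum(go * hAct)
  dHAct <- att$alpha * go
  dV <- rowsum(A * goVec, grp, reorder = FALSE)
  dA <- vExp * goVec
  rs <- rowSums(A * dA)
  dS <- A * (dA - rs)
  dQ <- matrix(rowSums(dS * kExp), B, H, byrow = TRUE)
  dK <- rowsum(dS * qVec, grp, reorder = FALSE)
  dHAct <- dHAct + dQ %*% att$W_q + dK %*% att$W_k + dV %*% att$W_v
  list(dHAct = dHAct,
       grads = list(W_q = t(dQ) %*% hAct, W_k = t(dK) %*% hAct,
                    W_v = t(dV) %*% hAct,
                    b_q = colSums(dQ), b_k = colSums(dK),
                    b_v = colSums(dV), alpha = dAlpha))
}

# ---- encoder backward ---------------------------------------------------

# cache: .encodeForward(..., cache = TRUE). dMu/dLogVar: upstream grads.
# Returns grads for enc + att lists (att zeros when attention is off).
.encoderBackward <- function(model, cache, dMu, dLogVar) {
  enc <- model@encoder
  act <- .activations[[enc$activation]]
  dHOut <- dMu %*% enc$W_mu + dLogVar %*% enc$W_nu
  gW_mu <- t(dMu) %*% cache$hOut
  gb_mu <- colSums(dMu)
  gW_nu <- t(dLogVar) %*% cache$hOut
  gb_nu <- colSums(dLogVar)
  if (model@useAttention) {
    ab <- .attentionBackward(dHOut, cache$sa, model@attention, cache$hAct)
    dHAct <- ab$dHAct
    attGrads <- ab$grads
  } else {
    dHAct <- dHOut
    attGrads <- .zeroLike(model@attention[c("W_q", "W_k", "W_v",
                                            "b_q", "b_k", "b_v", "alpha")])
  }
  dHPre <- dHAct * act$df(cache$hPre)
  list(enc = list(W_h = t(dHPre) %*% cache$x, b_h = colSums(dHPre),
                  W_mu = gW_mu, b_mu = gb_mu, W_nu = gW_nu, b_nu = gb_nu),
       att = attGrads)
}

# ---- generator step gradient -------------------------------------------

# Full generator-loss gradient for one batch. x: B x G normalized input;
# zeta: B x L draws; critic evaluated at xRec for the adversarial term.
# Returns grads in .getGenParams layout plus the loss components.
.generatorGradient <- function(model, critic, x, zeta, weights,
                               klHalf = FALSE, reparamForm = "standard") {
  B <- nrow(x); G <- ncol(x)
  cache <- .encodeForward(x, model, cache = TRUE)
  sigma <- exp(cache$logVar / 2)
  z <- if (reparamForm == "standard") cache$mu + sigma * zeta
       else cache$mu * zeta + sigma
  xRec <- z %*% t(model@decoder$W) + rep(model@decoder$b, each = B)

  fwD <- .criticForward(xRec, critic, cache = TRUE)
  kl <- klDivergence(cache$mu, cache$logVar, half = klHalf)
  l1 <- l1Loss(xRec, x)
  loss <- generatorLoss(fwD$score, kl, l1, weights)

  # d loss / d xRec: adversarial + L1 terms
  dXRec <- -(1 / B) * .criticInputGrad(fwD, critic) +
    weights$lambda2 * sign(xRec - x) / (B * G)
  # decoder
  dZ <- dXRec %*% model@decoder$W
  gDec <- list(W = t(dXRec) %*% z, b = colSums(dXRec))
  # reparameterization
  if (reparamForm == "standard") {
    dMu <- dZ
    dLogVar <- dZ * (0.5 * sigma * zeta)
  } else {
    dMu <- dZ * zeta
    dLogVar <- dZ * (0.5 * sigma)
  }
  # KL terms (mean over batch; optional 1/2)
  fac <- weights$lambda1 * (if (klHalf) 0.5 else 1) / B
  dMu <- dMu + fac * 2 * cache$mu
  dLogVar <- dLogVar + fac * (exp(cache$logVar) - 1)

  eb <- .encoderBackward(model, cache, dMu, dLogVar)
  list(grads = list(enc = eb$enc, att = eb$att, dec = gDec),
       loss = loss, kl = kl, l1 = l1, advScore = mean(fwD$score))
}

# ---- critic step gradient ----------------------------------------------

# Parameter gradients of mean(D(xFake)) - mean(D(xReal)) + lambdaP * GP.
.criticGradient <- function(critic, xReal, xFake, epsilon, lambdaP) {
  B <- nrow(xReal)
  fwR <- .criticForward(xReal, critic, cache = TRUE)
  fwF <- .criticForward(xFake, critic, cache = TRUE)
  g <- .addGrads(.criticScoreBackward(critic, fwR, rep(-1 / B, B)),
                 .criticScoreBackward(critic, fwF, rep(1 / B, B)))
  xHat <- xReal * epsilon + xFake * (1 - epsilon)
  gp <- .gradientPenaltyBackward(critic, xHat)
  g <- .addGrads(g, .scaleGrads(gp$grads, lambdaP))
  loss <- mean(fwF$score) - mean(fwR$score) + lambdaP * gp$penalty
  list(grads = g, loss = loss, penalty = gp$penalty,
       dReal = fwR$score, dFake = fwF$score)
}

# Standard backprop of sum_b ds_b * D(x_b) w.r.t. critic parameters.
.criticScoreBackward <- function(critic, fw, ds) {
  L <- length(critic@layers)
  B <- length(ds)
  hPrev <- if (L > 1L) fw$hs[[L - 1L]] else fw$x
  gOut <- list(wOut = colSums(fw$hs[[L]] * ds), bOut = sum(ds))
  dh <- tcrossprod(ds, critic@wOut)     # B x H_L
  gLayers <- vector("list", L)
  for (i in seq(L, 1L)) {
    dz <- dh * fw$masks[[i]]
    hIn <- if (i > 1L) fw$hs[[i - 1L]] else fw$x
    gLayers[[i]] <- list(W = t(dz) %*% hIn, b = colSums(dz))
    if (i > 1L) dh <- dz %*% critic@layers[[i]]$W
  }
  list(layers = gLayers, wOut = gOut$wOut, bOut = gOut$bOut)
}

# Double-backward of the gradient penalty. Activation second derivatives
# vanish almost everywhere for (leaky) ReLU, so masks are treated as
# locally constant: the input gradient g_b is then bilinear in the layer
# weights and the parameter gradient follows from one tangent forward
# pass seeded with q_b = dP/dg_b, mirrored by a weight-accumulating
# backward pass. Biases receive no gradient from this term.
.gradientPenaltyBackward <- function(critic, xHat) {
  L <- length(critic@layers)
  B <- nrow(xHat)
  fw <- .criticForward(xHat, critic, cache = TRUE)
  g <- .criticInputGrad(fw, critic)
  norms <- sqrt(rowSums(g^2))
  penalty <- mean((norms - 1)^2)
  safe <- pmax(norms, 1e-12)
  q <- g * ((2 / B) * (norms - 1) / safe)
  # tangent forward
  tList <- vector("list", L + 1L)
  tList[[1L]] <- q
  tk <- q
  for (i in seq_len(L)) {
    tk <- (tk %*% t(critic@layers[[i]]$W)) * fw$masks[[i]]
    tList[[i + 1L]] <- tk
  }
  gWOut <- colSums(tList[[L + 1L]])
  # backward pass accumulating weight gradients
  r <- matrix(critic@wOut, B, length(critic@wOut), byrow = TRUE)
  gLayers <- vector("list", L)
  for (i in seq(L, 1L)) {
    rz <- r * fw$masks[[i]]
    gLayers[[i]] <- list(W = t(rz) %*% tList[[i]],
                         b = numeric(nrow(critic@layers[[i]]$W)))
    if (i > 1L) r <- rz %*% critic@layers[[i]]$W
  }
  list(grads = list(layers = gLayers, wOut = gWOut, bOut = 0),
       penalty = penalty)
}

.addGrads <- function(a, b) {
  if (is.list(a)) {
    for (i in seq_along(a)) a[[i]] <- .addGrads(a[[i]], b[[i]])
    return(a)
  }
  a + b
}

.scaleGrads <- function(a, s) {
  if (is.list(a)) return(lapply(a, .scaleGrads, s = s))
  a * s
}

# ---- cox fine-tuning gradient ------------------------------------------

# Gradient of the Cox negative log partial likelihood through the
# encoder mean path and the linear head. Returns .getCoxParams layout.
.coxStageGradient <- function(model, x, time, event) {
  cache <- .encodeForward(x, model, cache = TRUE)
  risk <- as.numeric(cache$mu %*% model@coxHead)
  loss <- coxNegLogLik(risk, time, event)
  dRisk <- coxLossGradient(risk, time, event)
  gW <- as.numeric(t(cache$mu) %*% dRisk)
  dMu <- tcrossprod(dRisk, model@coxHead)
  dLogVar <- matrix(0, nrow(dMu), ncol(dMu))
  eb <- .encoderBackward(model, cache, dMu, dLogVar)
  list(grads = list(enc = eb$enc, att = eb$att, cox = list(w = gW)),
       loss = as.numeric(loss), risk = risk)
}
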