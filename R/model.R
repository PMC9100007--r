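# Registered activations for the encoder hidden layer. Each entry holds
# the map and its derivative as a function of the *pre-activation*.
.activations <- list(
  relu = list(f = function(x) pmax(x, 0),
              df = function(x) (x > 0) * 1),
  tanh = list(f = tanh,
              df = function(x) 1 - tanh(x)^2),
  identity = list(f = function(x) x,
                  df = function(x) array(1, dim(x)))
)

# PyTorch-style Linear default: U(-1/sqrt(fanIn), 1/sqrt(fanIn)).
.initAffine <- function(nOut, nIn) {
  b <- 1 / sqrt(nIn)
  list(W = matrix(runif(nOut * nIn, -b, b), nOut, nIn),
       b = runif(nOut, -b, b))
}

#' Construct an untrained SAVAE model
#'
#' Initialises all parameter containers. Affine layers use the uniform
#' fan-in init; the attention query/key/value maps start at small scale
#' so early attention output is gentle, and the residual weight alpha
#' starts at 1 (residual-dominant). The Cox head starts at zero.
#'
#' @param inputDim number of genes
#' @param hiddenDim hidden layer width (default 1024)
#' @param latentDim latent width (default 128)
#' @param useAttention include the residual self-attention block
#' @param activation hidden activation name (default `"relu"`)
#' @param geneIds optional gene identifiers recorded on the model
#' @param attentionScale sd of the normal init of the Q/K/V maps
#' @return a [SavaeModel-class] object
#' @export
savaeModel <- function(inputDim, hiddenDim = 1024L, latentDim = 128L,
                       useAttention = TRUE, activation = "relu",
                       geneIds = character(), attentionScale = 0.02) {
  h <- .initAffine(hiddenDim, inputDim)
  mu <- .initAffine(latentDim, hiddenDim)
  nu <- .initAffine(latentDim, hiddenDim)
  dec <- .initAffine(inputDim, latentDim)
  att <- list(
    W_q = matrix(rnorm(hiddenDim^2, 0, attentionScale), hiddenDim, hiddenDim),
    W_k = matrix(rnorm(hiddenDim^2, 0, attentionScale), hiddenDim, hiddenDim),
    W_v = matrix(rnorm(hiddenDim^2, 0, attentionScale), hiddenDim, hiddenDim),
    b_q = numeric(hiddenDim), b_k = numeric(hiddenDim),
    b_v = numeric(hiddenDim), alpha = 1)
  new("SavaeModel",
      encoder = list(W_h = h$W, b_h = h$b, W_mu = mu$W, b_mu = mu$b,
                     W_nu = nu$W, b_nu = nu$b, activation = activation),
      attention = att,
      decoder = list(W = dec$W, b = dec$b),
      coxHead = numeric(latentDim),
      useAttention = isTRUE(useAttention),
      geneIds = as.character(geneIds))
}

#' Construct an untrained Wasserstein critic
#'
#' Widths halve at every layer starting from the input dimension.
#'
#' @param inputDim number of genes
#' @param nLayers number of halving hidden layers (default 3)
#' @param leak leaky-ReLU negative slope
#' @return a [SavaeCritic-class] object
#' @export
savaeCritic <- function(inputDim, nLayers = 3L, leak = 0.2) {
  widths <- inputDim %/% 2^seq_len(nLayers)
  if (any(widths < 1L))
    stop("input dimension too small for ", nLayers, " halving layers")
  layers <- vector("list", nLayers)
  prev <- inputDim
  for (i in seq_len(nLayers)) {
    layers[[i]] <- .initAffine(widths[i], prev)
    prev <- widths[i]
  }
  out <- .initAffine(1L, prev)
  new("SavaeCritic", layers = layers, wOut = as.numeric(out$W),
      bOut = out$b, leak = leak)
}

# Vectorised batched self-attention over hidden features within each
# sample. h is B x H; q,k,v are B x H. The B*H x H score layout puts
# sample b, query feature i at row (b-1)*H + i, so the softmax and the
# value combination are single vectorised operations. Returns the output
# and, when cache = TRUE, the intermediates needed by the backward pass.
.saForward <- function(h, att, cache = FALSE) {
  B <- nrow(h); H <- ncol(h)
  q <- h %*% t(att$W_q) + rep(att$b_q, each = B)
  k <- h %*% t(att$W_k) + rep(att$b_k, each = B)
  v <- h %*% t(att$W_v) + rep(att$b_v, each = B)
  grp <- rep(seq_len(B), each = H)
  kExp <- k[grp, , drop = FALSE]               # (B*H) x H
  qVec <- as.vector(t(q))                      # length B*H, sample-major
  S <- kExp * qVec                             # row (b,i): q_bi * k_b.
  S <- S - .rowMax(S)
  A <- exp(S)
  A <- A / rowSums(A)
  vExp <- v[grp, , drop = FALSE]
  o <- matrix(rowSums(A * vExp), B, H, byrow = TRUE)
  if (!cache) return(o)
  list(o = o, A = A, q = q, k = k, v = v, grp = grp)
}

# rowMax without extra deps
.rowMax <- function(m) {
  out <- m[, 1L]
  for (j in seq_len(ncol(m))[-1L]) out <- pmax(out, m[, j])
  out
}

#' Self-attention over hidden features
#'
#' For each sample's hidden vector h, computes
#' `softmax_rows(q k^T) v` where `q = W_q h + b_q`, `k = W_k h + b_k`,
#' `v = W_v h + b_v`: attention weights between every pair of hidden
#' features, row-normalized over the key axis. Attention acts within a
#' sample; samples never attend to each other.
#'
#' @param h batch matrix, samples x hidden
#' @param att attention parameter list (`W_q`, `W_k`, `W_v`, biases,
#'   `alpha`)
#' @return matrix of the same shape as `h`
#' @export
selfAttention <- function(h, att) {
  h <- as.matrix(h)
  if (ncol(h) != ncol(att$W_q))
    stop("hidden width does not match attention maps")
  .saForward(h, att)
}

#' Residual self-attention
#'
#' `sa(h) + alpha * h`, with learnable scalar `alpha` adaptively weighting
#' the residual path.
#'
#' @inheritParams selfAttention
#' @return matrix of the same shape as `h`
#' @export
residualAttention <- function(h, att) {
  selfAttention(h, att) + att$alpha * as.matrix(h)
}

# Full encoder forward with optional cache for backprop.
.encodeForward <- function(x, model, cache = FALSE) {
  enc <- model@encoder
  act <- .activations[[enc$activation]]
  x <- as.matrix(x)
  B <- nrow(x)
  hPre <- x %*% t(enc$W_h) + rep(enc$b_h, each = B)
  hAct <- act$f(hPre)
  if (model@useAttention) {
    sa <- .saForward(hAct, model@attention, cache = cache)
    o <- if (cache) sa$o else sa
    hOut <- o + model@attention$alpha * hAct
  } else {
    sa <- NULL
    hOut <- hAct
  }
  mu <- hOut %*% t(enc$W_mu) + rep(enc$b_mu, each = B)
  logVar <- hOut %*% t(enc$W_nu) + rep(enc$b_nu, each = B)
  if (!cache) return(list(mu = mu, logVar = logVar))
  list(mu = mu, logVar = logVar, x = x, hPre = hPre, hAct = hAct,
       sa = sa, hOut = hOut)
}

#' Encode a batch to its latent Gaussian parameters
#'
#' `mu = W_mu(ResAtt(act(W_h x + b_h))) + b_mu` and analogously the
#' log-variance head; the variance `exp(logVar)` is strictly positive for
#' any finite input. At the survival stage only `mu` is used.
#'
#' @param x batch matrix, samples x genes, min-max normalized
#' @param model a [SavaeModel-class]
#' @return list with `mu` and `logVar`, both samples x latent
#' @export
encode <- function(x, model) {
  if (ncol(as.matrix(x)) != inputDim(model))
    stop("input gene count does not match the model")
  p <- .paramCheckFinite(model)
  if (!p) stop("model contains non-finite parameters")
  .encodeForward(x, model)
}

.paramCheckFinite <- function(model) {
  all(vapply(c(model@encoder[1:6], model@attention,
               model@decoder, list(model@coxHead)),
             function(p) all(is.finite(as.numeric(p))), logical(1)))
}

#' Reparameterization: z = mu + sigma * zeta
#'
#' Draws the latent sample through the standard reparameterization with
#' `sigma = exp(logVar / 2)` and standard-normal `zeta`, so gradients
#' flow through the sampler. `form = "paper"` selects the alternative
#' printed composition `z = mu * zeta + sigma`.
#'
#' @param mu,logVar latent Gaussian parameters (samples x latent)
#' @param zeta standard-normal draws of the same shape
#' @param form `"standard"` (default) or `"paper"`
#' @return latent sample matrix z
#' @export
reparameterize <- function(mu, logVar, zeta, form = c("standard", "paper")) {
  form <- match.arg(form)
  stopifnot(identical(dim(as.matrix(mu)), dim(as.matrix(logVar))),
            identical(dim(as.matrix(mu)), dim(as.matrix(zeta))))
  sigma <- exp(logVar / 2)
  if (form == "standard") mu + sigma * zeta else mu * zeta + sigma
}

#' Decode a latent batch back to gene space
#'
#' A single affine map: `x_rec = W z + b`.
#'
#' @param z latent batch, samples x latent
#' @param model a [SavaeModel-class]
#' @return reconstruction, samples x genes
#' @export
decode <- function(z, model) {
  z <- as.matrix(z)
  if (ncol(z) != latentDim(model))
    stop("latent width does not match the model")
  z %*% t(model@decoder$W) + rep(model@decoder$b, each = nrow(z))
}

# Critic forward with optional cache (pre-activations kept as masks).
.criticForward <- function(x, critic, cache = FALSE) {
  x <- as.matrix(x)
  B <- nrow(x)
  hs <- vector("list", length(critic@layers))
  masks <- vector("list", length(critic@layers))
  h <- x
  for (i in seq_along(critic@layers)) {
    l <- critic@layers[[i]]
    z <- h %*% t(l$W) + rep(l$b, each = B)
    m <- ifelse(z > 0, 1, critic@leak)
    h <- z * m
    hs[[i]] <- h; masks[[i]] <- m
  }
  s <- as.numeric(h %*% critic@wOut + critic@bOut)
  if (!cache) return(s)
  list(score = s, x = x, hs = hs, masks = masks)
}

#' Critic score for a batch
#'
#' One unbounded real per sample (a Wasserstein critic carries no
#' sigmoid).
#'
#' @param x batch matrix, samples x genes
#' @param critic a [SavaeCritic-class]
#' @return numeric vector of scores
#' @export
discriminate <- function(x, critic) {
  if (ncol(as.matrix(x)) != inputDim(critic))
    stop("input width does not match the critic")
  .criticForward(x, critic)
}

#' Full generator forward pass
#'
#' Composition encode -> reparameterize -> decode. Pure: identical
#' inputs, parameters and draws give identical outputs.
#'
#' @inheritParams encode
#' @param zeta standard-normal draws, samples x latent
#' @param form reparameterization form, see [reparameterize()]
#' @return list with `xRec`, `mu`, `logVar`, `z`
#' @export
forwardGenerator <- function(x, model, zeta, form = "standard") {
  e <- encode(x, model)
  z <- reparameterize(e$mu, e$logVar, zeta, form = form)
  list(xRec = decode(z, model), mu = e$mu, logVar = e$logVar, z = z)
}

#' Linear Cox risk score
#'
#' The log-relative-hazard `w . mu(x)` per sample; `exp` of it is the
#' hazard ratio against baseline. Uses the latent mean only (no
#' sampling), as at the survival stage.
#'
#' @inheritParams encode
#' @return numeric vector of risk scores
#' @export
hazardScore <- function(x, model) {
  if (length(model@coxHead) == 0L)
    stop("model has no cox head")
  e <- encode(x, model)
  as.numeric(e$mu %*% model@coxHead)
}

#' Save / load a model checkpoint
#'
#' Checkpoints are RDS files holding the parameter containers; save and
#' load round-trip bit-exactly.
#'
#' @param object a [SavaeModel-class] or [SavaeCritic-class]
#' @param path file path
#' @return `path` invisibly for save; the object for load
#' @export
saveCheckpoint <- function(object, path) {
  saveRDS(object, path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  obj <- readRDS(path)
  validObject(obj)
  obj
}
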