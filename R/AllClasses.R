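#' @import methods
#' @importFrom stats rnorm runif sd var cor pchisq quantile setNames
#' @importFrom utils head modifyList
NULL

#' SavaeModel: self-attention VAE with a Cox risk head
#'
#' Parameter container for the generator network: an encoder
#' (affine input->hidden, activation, optional residual self-attention,
#' affine heads for the latent mean and log-variance), a linear decoder
#' back to gene space, and a linear Cox head on the latent mean. All
#' slots hold plain numeric matrices/vectors so forward passes are pure
#' functions of (input, parameters).
#'
#' Slot layout (G genes, H hidden units, L latent nodes):
#' \describe{
#'   \item{encoder}{list with `W_h` (H x G), `b_h` (H), `W_mu` (L x H),
#'     `b_mu` (L), `W_nu` (L x H), `b_nu` (L), `activation` (name).}
#'   \item{attention}{list with `W_q`, `W_k`, `W_v` (H x H),
#'     `b_q`, `b_k`, `b_v` (H), and scalar `alpha` weighting the
#'     residual path.}
#'   \item{decoder}{list with `W` (G x L), `b` (G).}
#'   \item{coxHead}{numeric length-L weight vector of the linear
#'     log-relative-hazard map.}
#'   \item{useAttention}{logical; `FALSE` replaces the attention block
#'     with the identity.}
#'   \item{geneIds}{character vector of the genes the model was built
#'     for (column order of its inputs).}
#' }
#'
#' @aliases SavaeModel-class
#' @exportClass SavaeModel
setClass("SavaeModel",
  representation(
    encoder = "list",
    attention = "list",
    decoder = "list",
    coxHead = "numeric",
    useAttention = "logical",
    geneIds = "character"
  )
)

setValidity("SavaeModel", function(object) {
  enc <- object@encoder
  att <- object@attention
  dec <- object@decoder
  msgs <- character()
  need <- function(lst, nm, where) {
    miss <- setdiff(nm, names(lst))
    if (length(miss)) sprintf("%s missing fields: %s", where,
                              paste(miss, collapse = ", "))
  }
  msgs <- c(msgs,
    need(enc, c("W_h", "b_h", "W_mu", "b_mu", "W_nu", "b_nu", "activation"),
         "encoder"),
    need(att, c("W_q", "W_k", "W_v", "b_q", "b_k", "b_v", "alpha"),
         "attention"),
    need(dec, c("W", "b"), "decoder"))
  if (length(msgs)) return(msgs)
  G <- ncol(enc$W_h); H <- nrow(enc$W_h); L <- nrow(enc$W_mu)
  if (ncol(enc$W_mu) != H || ncol(enc$W_nu) != H || nrow(enc$W_nu) != L)
    msgs <- c(msgs, "latent heads must map hidden -> latent with equal dims")
  if (length(enc$b_h) != H || length(enc$b_mu) != L || length(enc$b_nu) != L)
    msgs <- c(msgs, "encoder bias lengths inconsistent")
  if (!identical(dim(att$W_q), c(H, H)) ||
      !identical(dim(att$W_k), c(H, H)) ||
      !identical(dim(att$W_v), c(H, H)))
    msgs <- c(msgs, "attention maps must be hidden x hidden")
  if (length(att$alpha) != 1L || !is.finite(att$alpha))
    msgs <- c(msgs, "attention alpha must be a finite scalar")
  if (nrow(dec$W) != G || ncol(dec$W) != L || length(dec$b) != G)
    msgs <- c(msgs, "decoder must map latent -> input dimension")
  if (length(object@coxHead) != 0L && length(object@coxHead) != L)
    msgs <- c(msgs, "cox head length must equal latent dimension")
  if (length(object@geneIds) != 0L && length(object@geneIds) != G)
    msgs <- c(msgs, "geneIds length must equal input dimension")
  if (!is.character(enc$activation) ||
      !enc$activation %in% names(.activations))
    msgs <- c(msgs, sprintf("activation must be one of: %s",
                            paste(names(.activations), collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' SavaeCritic: Wasserstein critic network
#'
#' A chain of width-halving affine layers with leaky-ReLU activations and
#' a final affine map to a single unbounded real score (no sigmoid).
#'
#' @aliases SavaeCritic-class
#' @exportClass SavaeCritic
setClass("SavaeCritic",
  representation(
    layers = "list",
    wOut = "numeric",
    bOut = "numeric",
    leak = "numeric"
  )
)

setValidity("SavaeCritic", function(object) {
  msgs <- character()
  widths <- vapply(object@layers, function(l) nrow(l$W), integer(1))
  if (length(widths) == 0L) msgs <- c(msgs, "critic needs >= 1 hidden layer")
  if (length(widths) > 1L && any(diff(widths) >= 0))
    msgs <- c(msgs, "layer widths must be strictly decreasing")
  for (i in seq_along(object@layers)) {
    l <- object@layers[[i]]
    if (length(l$b) != nrow(l$W))
      msgs <- c(msgs, sprintf("layer %d bias length mismatch", i))
    if (i > 1L && ncol(l$W) != nrow(object@layers[[i - 1L]]$W))
      msgs <- c(msgs, sprintf("layer %d input width mismatch", i))
  }
  if (length(object@layers) &&
      length(object@wOut) != nrow(object@layers[[length(object@layers)]]$W))
    msgs <- c(msgs, "output layer width mismatch")
  if (length(object@bOut) != 1L)
    msgs <- c(msgs, "output bias must be scalar")
  if (length(object@leak) != 1L || object@leak < 0 || object@leak >= 1)
    msgs <- c(msgs, "leak slope must lie in [0, 1)")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn SavaeModel number of input genes
#' @param object a `SavaeModel` or `SavaeCritic`
#' @export
setGeneric("inputDim", function(object) standardGeneric("inputDim"))

#' @describeIn SavaeModel width of the hidden layer
#' @export
setGeneric("hiddenDim", function(object) standardGeneric("hiddenDim"))

#' @describeIn SavaeModel number of latent nodes
#' @export
setGeneric("latentDim", function(object) standardGeneric("latentDim"))

#' @describeIn SavaeModel whether the residual self-attention block is active
#' @export
setGeneric("useAttention", function(object) standardGeneric("useAttention"))

#' @describeIn SavaeModel Cox head weight vector (length = latent dim)
#' @export
setGeneric("coxHead", function(object) standardGeneric("coxHead"))

setMethod("inputDim", "SavaeModel", function(object) ncol(object@encoder$W_h))
setMethod("hiddenDim", "SavaeModel", function(object) nrow(object@encoder$W_h))
setMethod("latentDim", "SavaeModel", function(object) nrow(object@encoder$W_mu))
setMethod("useAttention", "SavaeModel", function(object) object@useAttention)
setMethod("coxHead", "SavaeModel", function(object) object@coxHead)
setMethod("inputDim", "SavaeCritic",
          function(object) ncol(object@layers[[1L]]$W))

setMethod("show", "SavaeModel", function(object) {
  cat(sprintf(
    "SavaeModel: %d genes -> %d hidden -> %d latent (%s, attention %s)\n",
    inputDim(object), hiddenDim(object), latentDim(object),
    object@encoder$activation,
    if (object@useAttention) "on" else "off"))
  cat(sprintf("  cox head: %s\n",
      if (length(object@coxHead)) "fitted" else "absent"))
  invisible(object)
})

setMethod("show", "SavaeCritic", function(object) {
  widths <- vapply(object@layers, function(l) nrow(l$W), integer(1))
  cat(sprintf("SavaeCritic: %d -> %s -> 1 (leaky ReLU %.2f)\n",
      inputDim(object), paste(widths, collapse = " -> "), object@leak))
  invisible(object)
})
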