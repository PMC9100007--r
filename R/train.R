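#' Training configuration
#'
#' All hyperparameters of the two training stages. Defaults follow the
#' published protocol where one is stated (Adam; pretraining at learning
#' rate 1e-4 for 300 epochs, batch 256, constant for the first 150
#' epochs then linearly decaying to 0; fine-tuning at 1e-3 for 20
#' epochs, batch 512; five-fold cross-validation; 9:1 pretraining
#' train/test split) and standard WGAN-GP/VAE practice where it is not
#' (critic iterations 5; adversarial-stage Adam betas (0.5, 0.9),
#' fine-tune betas (0.9, 0.999); penalty/KL/L1 weights 10 / 1e-3 / 10).
#'
#' @param hiddenDim,latentDim encoder widths
#' @param pretrainLr,pretrainEpochs,pretrainBatch,lrHoldEpochs
#'   adversarial-stage settings
#' @param finetuneLr,finetuneEpochs,finetuneBatch Cox-stage settings
#' @param criticIters critic updates per generator update
#' @param weights a [lossWeights()] list
#' @param seed RNG seed governing every stochastic choice
#' @param variant one of `"full"`, `"no_pretrain"`, `"no_attention"`,
#'   `"cox_mlp"`
#' @param cvFolds number of cross-validation folds
#' @param testFraction held-out fraction during pretraining
#' @param activation encoder activation name
#' @param klHalf use the textbook 1/2 factor in the KL term
#' @param reparamForm reparameterization form, see [reparameterize()]
#' @param coxForm Cox loss form, see [coxNegLogLik()]
#' @param freezeEncoder update only the Cox head during fine-tuning
#' @param pretrainBetas,finetuneBetas Adam (beta1, beta2) pairs
#' @return classed list of settings
#' @export
savaeConfig <- function(hiddenDim = 1024L, latentDim = 128L,
                        pretrainLr = 1e-4, pretrainEpochs = 300L,
                        pretrainBatch = 256L, lrHoldEpochs = 150L,
                        finetuneLr = 1e-3, finetuneEpochs = 20L,
                        finetuneBatch = 512L, criticIters = 5L,
                        weights = lossWeights(), seed = 0L,
                        variant = c("full", "no_pretrain", "no_attention",
                                    "cox_mlp"),
                        cvFolds = 5L, testFraction = 0.1,
                        activation = "relu", klHalf = FALSE,
                        reparamForm = "standard", coxForm = "standard",
                        freezeEncoder = FALSE,
                        pretrainBetas = c(0.5, 0.9),
                        finetuneBetas = c(0.9, 0.999)) {
  variant <- match.arg(variant)
  stopifnot(pretrainEpochs >= 1L, finetuneEpochs >= 1L,
            pretrainBatch >= 2L, finetuneBatch >= 2L,
            lrHoldEpochs <= pretrainEpochs, criticIters >= 1L,
            cvFolds >= 2L, testFraction > 0, testFraction < 1)
  structure(list(
    hiddenDim = as.integer(hiddenDim), latentDim = as.integer(latentDim),
    pretrainLr = pretrainLr, pretrainEpochs = as.integer(pretrainEpochs),
    pretrainBatch = as.integer(pretrainBatch),
    lrHoldEpochs = as.integer(lrHoldEpochs),
    finetuneLr = finetuneLr, finetuneEpochs = as.integer(finetuneEpochs),
    finetuneBatch = as.integer(finetuneBatch),
    criticIters = as.integer(criticIters), weights = weights,
    seed = as.integer(seed), variant = variant,
    cvFolds = as.integer(cvFolds), testFraction = testFraction,
    activation = activation, klHalf = isTRUE(klHalf),
    reparamForm = reparamForm, coxForm = coxForm,
    freezeEncoder = isTRUE(freezeEncoder),
    pretrainBetas = pretrainBetas, finetuneBetas = finetuneBetas),
    class = "savae_config")
}

#' Learning-rate schedule factor
#'
#' 1 for the first `holdEpochs` epochs, then linear decay reaching 0 at
#' `totalEpochs`.
#'
#' @param epoch 0-based epoch index, `0 <= epoch <= totalEpochs`
#' @param totalEpochs,holdEpochs schedule parameters
#' @return factor in [0, 1]
#' @export
lrFactor <- function(epoch, totalEpochs, holdEpochs) {
  if (any(epoch < 0) || any(epoch > totalEpochs))
    stop("epoch out of [0, totalEpochs]")
  ifelse(epoch <= holdEpochs, 1,
         (totalEpochs - epoch) / (totalEpochs - holdEpochs))
}

.batchIndices <- function(idx, batch) {
  n <- length(idx)
  starts <- seq(1L, n, by = batch)
  out <- lapply(starts, function(s) idx[s:min(s + batch - 1L, n)])
  out[vapply(out, length, integer(1)) >= 2L]
}

#' Adversarial pretraining of the SAVAE generator
#'
#' Alternates `criticIters` Wasserstein-critic updates (with gradient
#' penalty) and one generator update (adversarial + KL + L1) per batch,
#' with Adam and the hold-then-linear-decay learning-rate schedule. The
#' input is split 9:1 into train/held-out by a seeded shuffle; held-out
#' reconstruction error (deterministic decode of the latent mean) is
#' tracked per epoch. Deterministic given (seed, config, input).
#'
#' @param expr min-max normalized samples x genes matrix
#' @param config a [savaeConfig()]
#' @param model,critic optional warm-start networks; fresh ones are
#'   initialised from the seed otherwise
#' @return list: `model`, `critic`, `history` (one row per epoch)
#' @export
pretrainSavae <- function(expr, config = savaeConfig(), model = NULL,
                          critic = NULL) {
  expr <- expressionMatrix(expr)
  set.seed(config$seed)
  n <- nrow(expr)
  nTest <- max(1L, round(config$testFraction * n))
  perm <- sample.int(n)
  testIdx <- perm[seq_len(nTest)]
  trainIdx <- perm[-seq_len(nTest)]
  if (config$pretrainBatch > length(trainIdx))
    stop("pretraining batch size exceeds the training split (",
         length(trainIdx), " samples)")
  useAtt <- config$variant %in% c("full", "no_pretrain")
  if (is.null(model))
    model <- savaeModel(ncol(expr), config$hiddenDim, config$latentDim,
                        useAttention = useAtt,
                        activation = config$activation,
                        geneIds = colnames(expr))
  if (is.null(critic)) critic <- savaeCritic(ncol(expr))
  L <- latentDim(model)

  genP <- .getGenParams(model)
  criP <- .getCriticParams(critic)
  genFlat <- .flattenParams(genP)
  criFlat <- .flattenParams(criP)
  genState <- .adamInit(length(genFlat))
  criState <- .adamInit(length(criFlat))
  b1g <- config$pretrainBetas[1L]; b2g <- config$pretrainBetas[2L]

  E <- config$pretrainEpochs
  hist <- data.frame(epoch = seq_len(E), genLoss = NA_real_,
                     criticLoss = NA_real_, kl = NA_real_, l1 = NA_real_,
                     penalty = NA_real_, valRecon = NA_real_,
                     lrFactor = NA_real_)
  xTest <- expr[testIdx, , drop = FALSE]
  for (e in seq_len(E)) {
    fac <- lrFactor(e - 1L, E, config$lrHoldEpochs)
    lr <- config$pretrainLr * fac
    batches <- .batchIndices(sample(trainIdx), config$pretrainBatch)
    gl <- cl <- klv <- l1v <- pen <- 0; ng <- 0L; nc <- 0L
    for (bi in batches) {
      x <- expr[bi, , drop = FALSE]
      B <- nrow(x)
      for (ci in seq_len(config$criticIters)) {
        zeta <- matrix(rnorm(B * L), B, L)
        fg <- forwardGenerator(x, model, zeta, form = config$reparamForm)
        epsilon <- runif(B)
        cg <- .criticGradient(critic, x, fg$xRec, epsilon,
                              config$weights$lambdaP)
        up <- .adamStep(criFlat, .flattenParams(cg$grads), criState,
                        lr, b1g, b2g)
        criFlat <- up$theta; criState <- up$state
        critic <- .setCriticParams(
          critic, .unflattenParams(criFlat, criP)$value)
        cl <- cl + cg$loss; pen <- pen + cg$penalty; nc <- nc + 1L
      }
      zeta <- matrix(rnorm(B * L), B, L)
      gg <- .generatorGradient(model, critic, x, zeta, config$weights,
                               klHalf = config$klHalf,
                               reparamForm = config$reparamForm)
      up <- .adamStep(genFlat, .flattenParams(gg$grads), genState,
                      lr, b1g, b2g)
      genFlat <- up$theta; genState <- up$state
      model <- .setGenParams(model, .unflattenParams(genFlat, genP)$value)
      gl <- gl + gg$loss; klv <- klv + gg$kl; l1v <- l1v + gg$l1
      ng <- ng + 1L
    }
    eTest <- .encodeForward(xTest, model)
    recon <- decode(eTest$mu, model)
    hist$genLoss[e] <- gl / max(ng, 1L)
    hist$criticLoss[e] <- cl / max(nc, 1L)
    hist$kl[e] <- klv / max(ng, 1L)
    hist$l1[e] <- l1v / max(ng, 1L)
    hist$penalty[e] <- pen / max(nc, 1L)
    hist$valRecon[e] <- l1Loss(recon, xTest)
    hist$lrFactor[e] <- fac
  }
  list(model = model, critic = critic, history = hist,
       trainIdx = trainIdx, testIdx = testIdx)
}

#' Transfer a pretrained encoder into a fresh survival model
#'
#' Copies the encoder and attention weights; the decoder is discarded
#' (zeroed) and the Cox head starts at zero, independent of the
#' pretraining history.
#'
#' @param pretrained a pretrained [SavaeModel-class]
#' @return a fresh [SavaeModel-class] ready for Cox fine-tuning
#' @export
transferEncoder <- function(pretrained) {
  stopifnot(is(pretrained, "SavaeModel"))
  m <- pretrained
  m@decoder$W[] <- 0
  m@decoder$b[] <- 0
  m@coxHead <- numeric(latentDim(pretrained))
  validObject(m)
  m
}

#' Cox partial-likelihood fine-tuning
#'
#' Minimises the Breslow negative log partial likelihood over the
#' encoder, attention and Cox head jointly (or the head alone with
#' `freezeEncoder`) with Adam. Training is full-batch when the cohort
#' fits in `finetuneBatch` (the default regime for cohorts of hundreds
#' of samples), otherwise seeded minibatches with the risk set computed
#' within each batch; batches without events are skipped and counted.
#'
#' @param model a [SavaeModel-class] (typically from
#'   [transferEncoder()])
#' @param expr normalized samples x genes matrix
#' @param surv survival table (aligned by sample identifier)
#' @param config a [savaeConfig()]
#' @param valExpr,valSurv optional held-out data; per-epoch validation
#'   concordance is then recorded
#' @return list: `model`, `history`, `skippedBatches`
#' @export
finetuneCox <- function(model, expr, surv, config = savaeConfig(),
                        valExpr = NULL, valSurv = NULL) {
  al <- alignCohort(expr, surv)
  x <- al$expr; sv <- al$surv
  set.seed(config$seed + 1000L)
  p <- .getCoxParams(model)
  flat <- .flattenParams(p)
  state <- .adamInit(length(flat))
  b1 <- config$finetuneBetas[1L]; b2 <- config$finetuneBetas[2L]
  n <- nrow(x)
  fullBatch <- n <= config$finetuneBatch
  E <- config$finetuneEpochs
  hist <- data.frame(epoch = seq_len(E), coxLoss = NA_real_,
                     valCIndex = NA_real_)
  skipped <- 0L
  nCoxW <- length(p$cox$w)
  for (e in seq_len(E)) {
    batches <- if (fullBatch) list(seq_len(n))
               else .batchIndices(sample.int(n), config$finetuneBatch)
    lsum <- 0; nb <- 0L
    for (bi in batches) {
      if (sum(sv$event[bi]) == 0) { skipped <- skipped + 1L; next }
      gg <- .coxStageGradient(model, x[bi, , drop = FALSE],
                              sv$time[bi], sv$event[bi])
      gFlat <- .flattenParams(gg$grads)
      if (config$freezeEncoder)
        gFlat[seq_len(length(gFlat) - nCoxW)] <- 0
      up <- .adamStep(flat, gFlat, state, config$finetuneLr, b1, b2)
      flat <- up$theta; state <- up$state
      model <- .setCoxParams(model, .unflattenParams(flat, p)$value)
      lsum <- lsum + gg$loss; nb <- nb + 1L
    }
    hist$coxLoss[e] <- if (nb) lsum / nb else NA_real_
    if (!is.null(valExpr)) {
      vr <- hazardScore(valExpr, model)
      hist$valCIndex[e] <- concordanceIndex(vr, valSurv$time, valSurv$event)
    }
  }
  list(model = model, history = hist, skippedBatches = skipped)
}

.cvFolds <- function(n, k, seed) {
  set.seed(seed + 2000L)
  sample(rep_len(seq_len(k), n))
}

# Build the starting model for one CV fold under a variant.
.foldStartModel <- function(variant, pretrained, nGenes, config, foldSeed) {
  if (variant %in% c("full", "no_attention")) {
    transferEncoder(pretrained)
  } else {
    set.seed(foldSeed)
    savaeModel(nGenes, config$hiddenDim, config$latentDim,
               useAttention = variant == "no_pretrain",
               activation = config$activation)
  }
}

#' Cross-validated concordance of a training variant
#'
#' Seeded balanced fold assignment; for each fold the model is
#' fine-tuned on the remaining folds and Harrell's concordance is
#' computed on the held-out fold. Variants needing pretraining
#' (`full`, `no_attention`) pretrain once on the full expression matrix
#' (pretraining is unsupervised and uses no survival labels) unless a
#' `pretrained` model is supplied.
#'
#' @param expr normalized samples x genes matrix
#' @param surv aligned survival table
#' @param config a [savaeConfig()]; `config$variant` selects the model
#'   form
#' @param pretrained optional pretrained [SavaeModel-class]
#' @return list: `perFold` concordances, `mean`, `folds` assignment,
#'   `models`
#' @export
crossValidate <- function(expr, surv, config = savaeConfig(),
                          pretrained = NULL) {
  al <- alignCohort(expr, surv)
  x <- al$expr; sv <- al$surv
  n <- nrow(x)
  k <- config$cvFolds
  if (n < k) stop("fewer samples than folds")
  if (config$variant %in% c("full", "no_attention") && is.null(pretrained))
    pretrained <- pretrainSavae(x, config)$model
  folds <- .cvFolds(n, k, config$seed)
  perFold <- numeric(k)
  models <- vector("list", k)
  for (f in seq_len(k)) {
    vi <- folds == f
    if (sum(sv$event[!vi]) == 0 || sum(sv$event[vi]) == 0)
      stop("fold ", f, " has no observed events")
    m0 <- .foldStartModel(config$variant, pretrained, ncol(x), config,
                          config$seed + 100L * f)
    ft <- finetuneCox(m0, x[!vi, , drop = FALSE], sv[!vi, , drop = FALSE],
                      config)
    risk <- hazardScore(x[vi, , drop = FALSE], ft$model)
    perFold[f] <- concordanceIndex(risk, sv$time[vi], sv$event[vi])
    models[[f]] <- ft$model
  }
  list(perFold = perFold, mean = mean(perFold), folds = folds,
       models = models)
}

#' Ablation study across the four model variants
#'
#' Runs `full`, `no_pretrain`, `no_attention` and `cox_mlp` under
#' identical fold assignments and seeds (optionally averaging over
#' several seeds) and ranks them 1-4 in descending mean concordance.
#'
#' @param expr normalized samples x genes matrix
#' @param surv aligned survival table
#' @param config a [savaeConfig()] (its `variant` field is ignored)
#' @param seeds integer vector of seeds to average over
#' @return list: `table` (variant, cindex, rank), `perSeed` (variant x
#'   seed matrix of mean concordances), `perFold`
#' @export
runAblation <- function(expr, surv, config = savaeConfig(),
                        seeds = config$seed) {
  variants <- c("full", "no_pretrain", "no_attention", "cox_mlp")
  perSeed <- matrix(NA_real_, length(variants), length(seeds),
                    dimnames = list(variants, paste0("seed", seeds)))
  perFold <- list()
  for (si in seq_along(seeds)) {
    cfgSeed <- modifyList(unclass(config), list(seed = as.integer(seeds[si])))
    class(cfgSeed) <- "savae_config"
    pre <- list()
    for (v in variants) {
      cfg <- cfgSeed; cfg$variant <- v
      key <- if (v %in% c("full", "no_pretrain")) "att" else "noatt"
      pretrained <- NULL
      if (v %in% c("full", "no_attention")) {
        if (is.null(pre[[key]]))
          pre[[key]] <- pretrainSavae(expr, cfg)$model
        pretrained <- pre[[key]]
      }
      cvr <- crossValidate(expr, surv, cfg, pretrained = pretrained)
      perSeed[v, si] <- cvr$mean
      perFold[[paste(v, seeds[si], sep = ".")]] <- cvr$perFold
    }
  }
  means <- rowMeans(perSeed)
  ranks <- rank(-means, ties.method = "first")
  list(table = data.frame(variant = variants, cindex = unname(means),
                          rank = unname(ranks), stringsAsFactors = FALSE),
       perSeed = perSeed, perFold = perFold)
}
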