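# savaecox

Deep Cox survival modelling for high-dimensional gene expression, built
around an adversarially pretrained self-attention variational
autoencoder whose encoder is transferred to a Cox
partial-likelihood head.

## The problem and who this is for

Bulk transcriptome cohorts pose a hard survival-regression setting:
~10⁴ gene features, a few hundred patients, heavy right-censoring. A
linear Cox proportional-hazards fit on the raw matrix is
under-determined; a deep model trained on one cohort overfits. This
package is for computational biologists who want a tested, dependency-
light R implementation of the two-stage remedy:

1. **Pretrain** a variational autoencoder — encoder with a residual
   self-attention block over hidden features — adversarially against a
   Wasserstein critic with gradient penalty, plus KL and L1
   reconstruction terms, on pooled (pan-cancer-style) expression:

   μ(x) = W_μ·(sa(h) + α·h) + b_μ,  h = ReLU(W_h·x + b_h),
   z = μ + σ⊙ζ,  x_rec = W_d·z + b_d

2. **Transfer** the encoder, attach a linear risk head on the latent
   mean, and fine-tune by the Breslow negative log partial likelihood

   −(1/d) Σ_{i: event} [ w·μ(x_i) − log Σ_{t_j ≥ t_i} exp(w·μ(x_j)) ].

Around the core: Xena-dialect TSV I/O, noise/empty-gene filtering
(std < 0.4 or mean < 0.8 on the log scale) with feature-wise min-max
normalization, Harrell concordance, mean-threshold risk groups with
Kaplan–Meier curves and log-rank tests, latent-node–gene correlation
("leader gene") analysis, a four-variant ablation harness, and a
synthetic proportional-hazards cohort generator with planted ground
truth. All network gradients (including the WGAN-GP double-backward)
are hand-derived, vectorised base R — no deep-learning framework is
required — and pinned by finite-difference tests.

## Worked example

A full run on a synthetic 600-sample, 200-gene cohort with a strong
planted signal (true-predictor concordance 0.88, ~35% censoring),
using a compact network (hidden 64, latent 16) and 20 + 20 epochs:

```r
library(savaecox)

rc  <- referenceCohort("strong", seed = 0)   # expr, surv, known truth
pp  <- preprocessExpression(rc$expr)         # filter + min-max
length(pp$removed)
#> [1] 80                                     # the 50+30 planted genes

cfg <- savaeConfig(hiddenDim = 64L, latentDim = 16L,
                   pretrainEpochs = 20L, lrHoldEpochs = 10L,
                   finetuneEpochs = 20L, seed = 0L)
pt  <- pretrainSavae(pp$expr, cfg)           # WGAN-GP + KL + L1
round(range(pt$history$valRecon), 3)
#> [1] 0.455 0.505                            # held-out L1 falls

cv  <- crossValidate(pp$expr, rc$surv, cfg, pretrained = pt$model)
round(cv$perFold, 3); round(cv$mean, 3)
#> [1] 0.874 0.859 0.822 0.866 0.848
#> [1] 0.854
```

A five-fold cross-validated concordance of ~0.85 against a
ground-truth ceiling of 0.88 — the transferred encoder recovers most
of the planted latent signal. On the `null` profile the same pipeline
gives ~0.51: chance, as it should. `evaluationReport()` then produces
risk groups, KM curves, log-rank p-values, key latent nodes and their
leader genes; `runAblation()` compares `full`, `no_pretrain`,
`no_attention` and `cox_mlp` variants under identical folds.

A thin CLI wraps the same functions
(`inst/scripts/savae simulate|preprocess|pretrain|train|evaluate|ablate`).

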