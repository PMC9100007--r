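test_that("concordance index matches hand cases and the pair oracle", {
  # risks perfectly anti-ordered with times, no censoring
  expect_equal(concordanceIndex(c(5, 4, 3, 2), 1:4, rep(1, 4)), 1)
  # constant risks
  expect_equal(concordanceIndex(c(1, 1, 1), 1:3, rep(1, 3)), 0.5)
  # worked example
  expect_equal(concordanceIndex(c(3, 1, 2), c(1, 2, 3), c(1, 1, 0)), 2 / 3)
  expect_error(concordanceIndex(1, 5, 0), "comparable")
  # random censored instances vs exhaustive enumeration (exact)
  set.seed(41)
  for (r in 1:40) {
    inst <- randomSurvInstance(sample(4:40, 1))
    expect_identical(
      concordanceIndex(inst$risk, inst$time, inst$event),
      bruteCIndex(inst$risk, inst$time, inst$event))
  }
})

test_that("concordance agrees with survival::concordance on tie-free data", {
  set.seed(42)
  n <- 60
  risk <- rnorm(n)
  time <- sort(rexp(n, 0.01)) + seq_len(n) * 1e-6   # no ties
  event <- rbinom(n, 1, 0.7)
  ours <- concordanceIndex(risk, time, event)
  ref <- survival::concordance(
    survival::Surv(time, event) ~ risk, reverse = TRUE)$concordance
  expect_equal(ours, unname(ref), tolerance = 1e-12)
})

test_that("risk groups split at the mean, shift-invariantly", {
  g <- assignRiskGroups(c(1, 2, 3))
  expect_equal(as.character(g$group), c("low", "low", "high"))
  expect_equal(g$threshold, 2)
  g2 <- assignRiskGroups(c(1, 2, 3) + 100)
  expect_equal(g2$group, g$group)
  expect_warning(gAll <- assignRiskGroups(c(2, 2, 2)), "single risk group")
  expect_true(all(gAll$group == "low"))
})

test_that("KM curves reproduce hand product-limit arithmetic", {
  # no events -> flat at 1
  km0 <- kmCurve(c(3, 5, 7), c(0, 0, 0), rep("a", 3))
  expect_true(all(km0$a$surv == 1))
  # n = 2, events at t = 1, 2 -> steps 0.5 then 0
  km2 <- kmCurve(c(1, 2), c(1, 1), rep("a", 2))
  expect_equal(km2$a$surv, c(0.5, 0))
  # censoring reduces later at-risk counts without a step:
  # events at 1 and 5, censored at 2 -> S(1) = 2/3, S(5) = 1/3... with
  # the censored sample off the later risk set: S(5) = 2/3 * (1 - 1/1)
  km3 <- kmCurve(c(1, 2, 5), c(1, 0, 1), rep("a", 3))
  ev <- km3$a[km3$a$nEvent > 0, ]
  expect_equal(ev$surv, c(2 / 3, 0))
  expect_equal(ev$nRisk, c(3, 1))
  # without censoring KM equals the empirical survival function
  set.seed(43)
  tt <- sample(1:20, 30, replace = TRUE)
  km <- kmCurve(tt, rep(1, 30), rep("a", 30))$a
  emp <- vapply(km$time, function(s) mean(tt > s), numeric(1))
  expect_equal(km$surv, emp, tolerance = 1e-12)
  expect_error(kmCurve(1:3, c(1, 1, 1), factor(rep("a", 3), c("a", "b"))),
               "empty group")
})

test_that("log-rank test matches the observed-expected oracle", {
  # duplicated identical groups -> statistic 0, p = 1
  tt <- c(1, 3, 5, 7); ev <- c(1, 0, 1, 1)
  lr0 <- logrankTest(c(tt, tt), c(ev, ev), rep(c("a", "b"), each = 4))
  expect_equal(lr0$statistic, 0, tolerance = 1e-12)
  expect_equal(lr0$pValue, 1, tolerance = 1e-12)
  # hand-worked 6-sample example
  time <- c(1, 2, 3, 4, 5, 6)
  event <- c(1, 1, 0, 1, 1, 0)
  grp <- c("a", "b", "a", "b", "a", "b")
  ours <- logrankTest(time, event, grp)
  oracle <- bruteLogrank(time, event, grp)
  expect_equal(ours$statistic, oracle$statistic, tolerance = 1e-9)
  expect_equal(ours$pValue, oracle$pValue, tolerance = 1e-9)
  # invariant under label swap
  swapped <- logrankTest(time, event, ifelse(grp == "a", "b", "a"))
  expect_equal(swapped$statistic, ours$statistic, tolerance = 1e-12)
  expect_error(logrankTest(time, event, rep("a", 6)), "2 groups")
})

test_that("strongly separated groups give small log-rank p-values", {
  set.seed(44)
  n <- 200
  grp <- rep(c("lo", "hi"), each = n / 2)
  rate <- ifelse(grp == "hi", 3, 1) * 0.01
  tt <- rexp(n, rate)
  cc <- rexp(n, 0.004)
  time <- pmin(tt, cc); event <- as.numeric(tt <= cc)
  expect_lt(logrankTest(time, event, grp)$pValue, 0.01)
})

test_that("key-node selection ranks by activation variance", {
  set.seed(45)
  n <- 50
  mu <- cbind(rnorm(n, sd = 0.1), rnorm(n, sd = 3), rep(2, n),
              rnorm(n, sd = 1))
  # exact variance targets so recovery is deterministic
  kn <- selectKeyNodes(mu, k = 2)
  expect_equal(kn$nodes, c(2L, 4L))
  # constant node never outranks a varying node
  knAll <- selectKeyNodes(mu, k = 4)
  expect_equal(knAll$nodes[4], 3L)
  expect_error(selectKeyNodes(mu, k = 5), "latent dimension")
  # mean * variance alternative
  kn2 <- selectKeyNodes(mu, k = 1, score = "mean_variance")
  expect_true(kn2$nodes %in% c(2L, 3L))
})

test_that("node-gene correlation obeys its exact and null behaviour", {
  set.seed(46)
  n <- 1000
  node <- rnorm(n)
  expr <- expressionMatrix(
    cbind(node, -node, matrix(rnorm(n * 50), n, 50), rep(1, n)),
    paste0("s", 1:n), paste0("g", 1:53))
  mu <- cbind(node, rnorm(n))
  ngc <- nodeGeneCorrelation(mu, expr, nodes = 1:2)
  expect_equal(unname(ngc$r[1, 1]), 1)
  expect_equal(unname(ngc$r[1, 2]), -1)
  expect_equal(unname(ngc$r[, 53]), c(0, 0))   # zero-variance gene
  # independent pairs: |r| < 0.11 for at least 99% of entries
  nulls <- abs(ngc$r[2, 3:52])
  expect_gte(mean(nulls < 0.11), 0.99)
  expect_error(nodeGeneCorrelation(mu[1:2, ], expr[1:2, ]), "3 samples")
})

test_that("per-node KM analysis flags degenerate splits and finds signal", {
  tc <- tinyCohort(n = 150L, seed = 17L)
  # a node equal to the true risk separates survival
  mu <- cbind(tc$eta, rep(1, nrow(tc$surv)), rnorm(nrow(tc$surv)))
  suppressWarnings(nk <- nodeKmAnalysis(mu, 1:3, tc$surv))
  expect_equal(nrow(nk), 3L)
  expect_lt(nk$pValue[1], 0.05)
  expect_true(nk$degenerate[2])
  expect_true(is.na(nk$pValue[2]))
  expect_true(all(c("pAdjustBH") %in% colnames(nk)))
})

test_that("leader genes rank by absolute correlation, stably", {
  set.seed(47)
  n <- 80
  node <- rnorm(n)
  expr <- expressionMatrix(
    cbind(matrix(rnorm(n * 10), n, 10), -node),
    paste0("s", 1:n), c(paste0("g", 1:10), "gPlant"))
  ngc <- nodeGeneCorrelation(cbind(node), expr, nodes = 1)
  lg <- leaderGenes(ngc, perNode = 3)
  expect_equal(lg$node1$gene[1], "gPlant")
  # signed ranking demotes the negative regulator
  lgS <- leaderGenes(ngc, perNode = 11, signed = TRUE)
  expect_equal(lgS$node1$gene[11], "gPlant")
  # full ranking is a permutation of all genes
  expect_setequal(lgS$node1$gene, colnames(expr))
  # stable under gene-order permutation of the input
  perm <- sample(ncol(expr))
  ngcP <- nodeGeneCorrelation(cbind(node), expr[, perm], nodes = 1)
  lgP <- leaderGenes(ngcP, perNode = 3)
  expect_equal(lgP$node1, lg$node1)
})

test_that("evaluation reports are internally consistent and serializable", {
  tc <- tinyCohort(n = 100L)
  cfg <- tinyConfig(variant = "no_pretrain", finetuneEpochs = 6L)
  set.seed(cfg$seed)
  m0 <- savaeModel(ncol(tc$expr), cfg$hiddenDim, cfg$latentDim)
  ft <- finetuneCox(m0, tc$expr, tc$surv, cfg)
  rep <- evaluationReport(ft$model, tc$expr, tc$surv, nKeyNodes = 3L)
  risk <- hazardScore(tc$expr, ft$model)
  expect_equal(rep$cindex,
               concordanceIndex(risk, tc$surv$time, tc$surv$event))
  expect_equal(nrow(rep$riskGroups), nrow(tc$surv))
  expect_equal(length(rep$keyNodes$nodes), 3L)
  expect_equal(dim(rep$nodeGeneCorr$r), c(3L, ncol(tc$expr)))
  dir <- tempfile()
  writeEvaluationReport(rep, dir)
  expect_true(all(file.exists(file.path(dir,
    c("cindex.tsv", "groups.tsv", "logrank.tsv",
      "node_gene_corr.tsv", "leader_genes.tsv")))))
  back <- data.table::fread(file.path(dir, "groups.tsv"),
                            data.table = FALSE)
  expect_equal(back$risk, unname(rep$riskGroups$risk), tolerance = 1e-7)
  expect_equal(back$group, rep$riskGroups$group)
})
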