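#' Harrell's concordance index
#'
#' Fraction of censoring-comparable sample pairs in which the higher
#' predicted risk belongs to the earlier failure. A pair (i, j) is
#' comparable when `time_i < time_j` and sample i's death was observed;
#' tied risks are credited 0.5.
#'
#' @param risk predicted risk scores (higher = worse prognosis)
#' @param time follow-up times
#' @param event 0/1 indicator, 1 = death observed
#' @return concordance in [0, 1]
#' @export
concordanceIndex <- function(risk, time, event) {
  n <- length(risk)
  stopifnot(length(time) == n, length(event) == n)
  ev <- which(event == 1)
  conc <- 0; total <- 0
  for (i in ev) {
    later <- time > time[i]
    m <- sum(later)
    if (m == 0L) next
    total <- total + m
    conc <- conc + sum(risk[i] > risk[later]) +
      0.5 * sum(risk[i] == risk[later])
  }
  if (total == 0) stop("no comparable pairs under censoring")
  conc / total
}

#' Split samples into high/low risk at the mean risk
#'
#' The threshold is the arithmetic mean of the risk scores; samples
#' strictly above it are "high", the rest "low". Shift-invariant in the
#' risk scores. All-equal risks give an all-low split with a warning.
#'
#' @param risk numeric risk scores, optionally named by sample
#' @return list: `group` (factor high/low), `threshold`
#' @export
assignRiskGroups <- function(risk) {
  if (length(risk) < 2L) stop("need at least 2 samples to stratify")
  thr <- mean(risk)
  g <- ifelse(risk > thr, "high", "low")
  if (all(g == "low"))
    warning("all risks at or below the mean; single risk group")
  list(group = factor(g, levels = c("low", "high")), threshold = thr)
}

#' Kaplan-Meier survival curves per group
#'
#' Product-limit estimates via `survival::survfit`, returned as one
#' tidy data.frame per group with the event-ordered times, stepped
#' survival probabilities and at-risk counts.
#'
#' @param time,event follow-up data
#' @param group group labels (any number of groups, each nonempty)
#' @return named list of data.frames with columns `time`, `surv`,
#'   `nRisk`, `nEvent`
#' @export
kmCurve <- function(time, event, group) {
  group <- as.factor(group)
  out <- list()
  for (g in levels(group)) {
    sel <- group == g
    if (!any(sel)) stop("empty group: ", g)
    fit <- survival::survfit(survival::Surv(time[sel], event[sel]) ~ 1)
    out[[g]] <- data.frame(time = fit$time, surv = fit$surv,
                           nRisk = fit$n.risk, nEvent = fit$n.event)
  }
  out
}

#' Two-sample log-rank test
#'
#' Standard chi-squared (1 df) log-rank statistic via
#' `survival::survdiff` with its upper-tail p-value.
#'
#' @param time,event follow-up data
#' @param group labels with exactly two levels
#' @return list: `statistic`, `pValue`
#' @export
logrankTest <- function(time, event, group) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2L)
    stop("log-rank test needs exactly 2 groups, got ", nlevels(group))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  list(statistic = unname(sd$chisq),
       pValue = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Select the key prognostic latent nodes
#'
#' Ranks the latent (hidden-layer) nodes of the encoder mean by their
#' activation variance across samples and returns the top k. The
#' alternative `"mean_variance"` score multiplies mean and variance.
#'
#' @param mu samples x latent matrix of latent means
#' @param k number of nodes to keep (default 20)
#' @param score `"variance"` (default) or `"mean_variance"`
#' @return list: `nodes` (column indices, descending score), `scores`
#' @export
selectKeyNodes <- function(mu, k = 20L,
                           score = c("variance", "mean_variance")) {
  score <- match.arg(score)
  mu <- as.matrix(mu)
  if (k > ncol(mu)) stop("k exceeds the latent dimension")
  v <- apply(mu, 2L, var)
  s <- if (score == "variance") v else abs(colMeans(mu)) * v
  ord <- order(s, decreasing = TRUE)
  nodes <- ord[seq_len(k)]
  list(nodes = nodes, scores = s[nodes])
}

#' Pearson correlation of latent nodes with gene expression
#'
#' Correlates each selected node's activation with every gene across
#' samples. Zero-variance columns yield r = 0 by convention.
#'
#' @param mu samples x latent matrix
#' @param expr samples x genes matrix (same sample order)
#' @param nodes node indices (default all)
#' @return list: `r` (nodes x genes correlation matrix), `nodes`
#' @export
nodeGeneCorrelation <- function(mu, expr, nodes = seq_len(ncol(mu))) {
  mu <- as.matrix(mu); expr <- expressionMatrix(expr)
  if (nrow(mu) != nrow(expr)) stop("sample counts differ")
  if (nrow(mu) < 3L) stop("need at least 3 samples for correlation")
  sub <- mu[, nodes, drop = FALSE]
  sdN <- apply(sub, 2L, sd)
  sdG <- apply(expr, 2L, sd)
  r <- suppressWarnings(cor(sub, expr))
  r[sdN == 0, ] <- 0
  r[, sdG == 0] <- 0
  rownames(r) <- paste0("node", nodes)
  list(r = r, nodes = nodes)
}

#' Per-node Kaplan-Meier stratification
#'
#' Splits the cohort at each node's mean activation, then computes the
#' KM curves and the log-rank p-value, mirroring the per-node
#' prognostic analysis of the latent representation. Degenerate splits
#' (constant node) are flagged with `NA` statistics.
#'
#' @param mu samples x latent matrix
#' @param nodes node indices to analyse
#' @param surv survival table aligned to the rows of `mu`
#' @return data.frame with one row per node: `node`, `threshold`,
#'   `statistic`, `pValue`, `degenerate`; KM curves in
#'   `attr(, "curves")`
#' @export
nodeKmAnalysis <- function(mu, nodes, surv) {
  mu <- as.matrix(mu)
  stopifnot(nrow(mu) == nrow(surv))
  res <- data.frame(node = nodes, threshold = NA_real_,
                    statistic = NA_real_, pValue = NA_real_,
                    degenerate = FALSE)
  curves <- list()
  for (i in seq_along(nodes)) {
    a <- mu[, nodes[i]]
    gr <- suppressWarnings(assignRiskGroups(a))
    res$threshold[i] <- gr$threshold
    if (nlevels(droplevels(gr$group)) < 2L) {
      res$degenerate[i] <- TRUE
      next
    }
    lt <- logrankTest(surv$time, surv$event, gr$group)
    res$statistic[i] <- lt$statistic
    res$pValue[i] <- lt$pValue
    curves[[paste0("node", nodes[i])]] <-
      kmCurve(surv$time, surv$event, gr$group)
  }
  res$pAdjustBH <- stats::p.adjust(res$pValue, method = "BH")
  attr(res, "curves") <- curves
  res
}

#' Leader genes per latent node
#'
#' Ranks genes for each node by descending absolute Pearson correlation
#' (so negative regulators rank too; `signed = TRUE` ranks by signed r)
#' and returns the top `perNode` per node.
#'
#' @param corr result of [nodeGeneCorrelation()]
#' @param perNode genes to keep per node
#' @param signed rank by signed correlation instead of |r|
#' @return named list (per node) of data.frames `gene`, `r`
#' @export
leaderGenes <- function(corr, perNode = 1L, signed = FALSE) {
  r <- corr$r
  out <- list()
  for (i in seq_len(nrow(r))) {
    key <- if (signed) r[i, ] else abs(r[i, ])
    ord <- order(key, decreasing = TRUE)
    sel <- ord[seq_len(min(perNode, ncol(r)))]
    out[[rownames(r)[i]]] <- data.frame(gene = colnames(r)[sel],
                                        r = unname(r[i, sel]),
                                        stringsAsFactors = FALSE)
  }
  out
}

#' Full evaluation report for a fitted survival model
#'
#' Bundles risk scoring, concordance, mean-threshold risk groups, KM
#' curves and log-rank test, key-node selection, node-gene correlation,
#' per-node KM analysis and leader genes.
#'
#' @param model a fitted [SavaeModel-class]
#' @param expr normalized samples x genes matrix
#' @param surv survival table
#' @param nKeyNodes nodes to analyse (capped at the latent dimension)
#' @param leadersPerNode leader genes per node
#' @return classed list; see components
#' @export
evaluationReport <- function(model, expr, surv, nKeyNodes = 20L,
                             leadersPerNode = 5L) {
  al <- alignCohort(expr, surv)
  x <- al$expr; sv <- al$surv
  risk <- hazardScore(x, model)
  mu <- encode(x, model)$mu
  rownames(mu) <- rownames(x)
  ci <- concordanceIndex(risk, sv$time, sv$event)
  rg <- assignRiskGroups(risk)
  twoGroups <- nlevels(droplevels(rg$group)) == 2L
  km <- if (twoGroups) kmCurve(sv$time, sv$event, rg$group) else NULL
  lr <- if (twoGroups) logrankTest(sv$time, sv$event, rg$group)
        else list(statistic = NA_real_, pValue = NA_real_)
  kn <- selectKeyNodes(mu, k = min(nKeyNodes, latentDim(model)))
  ng <- nodeGeneCorrelation(mu, x, kn$nodes)
  nk <- nodeKmAnalysis(mu, kn$nodes, sv)
  lg <- leaderGenes(ng, perNode = leadersPerNode)
  structure(list(
    cindex = ci,
    risk = setNames(risk, rownames(x)),
    riskGroups = data.frame(sample = rownames(x),
                            group = as.character(rg$group),
                            risk = risk, stringsAsFactors = FALSE),
    threshold = rg$threshold,
    km = km, logrank = lr,
    keyNodes = kn, nodeGeneCorr = ng, nodeKm = nk, leaderGenes = lg),
    class = "savae_report")
}

#' Write an evaluation report as TSV/JSON files
#'
#' Writes `cindex.tsv`, `groups.tsv`, `km_<group>.tsv`, `logrank.tsv`,
#' `node_gene_corr.tsv`, `node_km.tsv` and `leader_genes.tsv` into a
#' directory.
#'
#' @param report result of [evaluationReport()]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
writeEvaluationReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name)
    data.table::fwrite(df, file.path(dir, name), sep = "\t")
  w(data.frame(cindex = report$cindex, threshold = report$threshold),
    "cindex.tsv")
  w(report$riskGroups, "groups.tsv")
  if (!is.null(report$km))
    for (g in names(report$km)) w(report$km[[g]], paste0("km_", g, ".tsv"))
  w(data.frame(statistic = report$logrank$statistic,
               pValue = report$logrank$pValue), "logrank.tsv")
  corr <- as.data.frame(report$nodeGeneCorr$r)
  corr <- cbind(node = rownames(report$nodeGeneCorr$r), corr)
  w(corr, "node_gene_corr.tsv")
  w(as.data.frame(report$nodeKm), "node_km.tsv")
  lg <- do.call(rbind, lapply(names(report$leaderGenes), function(nm)
    cbind(node = nm, report$leaderGenes[[nm]])))
  w(lg, "leader_genes.tsv")
  invisible(dir)
}
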